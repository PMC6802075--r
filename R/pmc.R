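#' Likelihood ratio between two fits of the same data
#'
#' `delta = 2 (lnL_focal - lnL_alt)`, the likelihood-ratio-statistic
#' convention (the factor 2 cancels in the confidence-interval membership
#' used for classification).
#'
#' @param fit_focal,fit_alt `ou_fit`s of both models to the same data.
#' @return The ratio statistic `delta`.
#' @export
likelihood_ratio <- function(fit_focal, fit_alt) {
  2 * (fit_focal$lnL - fit_alt$lnL)
}

#' Classify an empirical ratio against two bootstrap distributions
#'
#' Pure function of `delta_emp` and the two 95% CIs; boundary values count
#' as inside.
#'
#' @param delta_emp Empirical likelihood ratio.
#' @param ci_focal,ci_alt Numeric length-2 vectors (2.5% and 97.5%
#'   percentiles of the ratio distributions simulated under each model).
#' @return One of `"focal_favored"`, `"both_plausible"`,
#'   `"both_implausible"`, `"alternative_favored"`.
#' @export
classify_delta <- function(delta_emp, ci_focal, ci_alt) {
  inside <- function(ci) delta_emp >= ci[1] && delta_emp <= ci[2]
  in_f <- inside(ci_focal); in_a <- inside(ci_alt)
  if (in_f && !in_a) "focal_favored"
  else if (in_f && in_a) "both_plausible"
  else if (!in_f && !in_a) "both_implausible"
  else "alternative_favored"
}

#' Simulated likelihood-ratio distribution under one generating model
#'
#' The building block of the pairwise comparison: simulates `n_sim` datasets
#' under `gen` (a fitted or specified model), fits both candidate models to
#' every dataset, and returns the per-dataset log-likelihoods, the ratio
#' statistic `delta = 2 (lnL_focal - lnL_alt)`, and both refit parameter
#' tables.
#'
#' @param tree A `phylo` object.
#' @param painting A `regime_painting`.
#' @param gen Generating model: an `ou_fit` or a parameter list as accepted
#'   by [simulate_traits()].
#' @param focal_spec,alt_spec The two `model_spec`s fitted to every dataset.
#' @param n_sim Number of simulated datasets.
#' @param seed Integer seed.
#' @param gen_is_focal Is `gen` the focal model's fit?  (Used only to seed
#'   the refit search at the generating pull strength.)
#' @return List: `delta`, `lnL_focal`, `lnL_alt`, `params_focal`,
#'   `params_alt`.
#' @export
lr_distribution <- function(tree, painting, gen, focal_spec, alt_spec,
                            n_sim, seed, gen_is_focal = TRUE) {
  ctx <- if (is.list(tree) && !inherits(tree, "phylo")) tree else
    tree_ctx(tree)
  lr_distribution_ctx(ctx, painting, gen, focal_spec, alt_spec, n_sim,
                      seed, gen_is_focal)
}

lr_distribution_ctx <- function(ctx, painting, gen, focal_spec, alt_spec,
                                n_sim, seed, gen_is_focal = TRUE) {
  batch <- simulate_traits(ctx$tree, painting, gen, n_datasets = n_sim,
                           seed = seed)
  X <- t(batch$data)                                  # tips x datasets
  fit_one <- function(sp, start_alpha = NULL) {
    if (sp$family == "BM1") {
      r <- fit_bm_batch(ctx, X)
      list(lnL = r$lnL, params = tibble::tibble(X0 = r$x0, sigma2 = r$sigma2))
    } else {
      design <- model_design(ctx$tree, painting, sp)
      grid <- default_alpha_grid(ctx$T)
      if (!is.null(start_alpha) && is.finite(start_alpha))
        grid <- sort(unique(c(grid, start_alpha)))    # generating alpha as a start
      r <- fit_ou_batch(ctx, design, X, alpha_grid = grid)
      pars <- tibble::as_tibble(as.data.frame(r$coef))
      names(pars) <- c(paste0("theta[", sp$optima_names, "]"),
                       if (sp$root_policy == "free") "X0")
      list(lnL = r$lnL,
           params = dplyr::bind_cols(tibble::tibble(alpha = r$alpha,
                                                    sigma2 = r$sigma2), pars))
    }
  }
  gen_alpha <- if (inherits(gen, "ou_fit") && gen$spec$family == "OU")
    gen$alpha else NULL
  f_res <- fit_one(focal_spec, if (gen_is_focal) gen_alpha else NULL)
  a_res <- fit_one(alt_spec, if (!gen_is_focal) gen_alpha else NULL)
  delta <- 2 * (f_res$lnL - a_res$lnL)
  list(delta = delta, lnL_focal = f_res$lnL, lnL_alt = a_res$lnL,
       params_focal = f_res$params, params_alt = a_res$params)
}

#' Pairwise parametric-bootstrap model comparison (phylogenetic Monte Carlo)
#'
#' Fits the focal and alternative model to the data (`delta_emp`), simulates
#' `n_sim` datasets under each fitted model, refits both models to every
#' dataset, and classifies `delta_emp` against the 95% percentile CIs of the
#' two resulting likelihood-ratio distributions.  Refits that fail to
#' converge are dropped when they are at most 1% of a distribution and
#' abort the comparison otherwise.
#'
#' @param tree A `phylo` object.
#' @param painting A `regime_painting`.
#' @param x Residual vector (named or in tip order).
#' @param focal_spec,alt_spec `model_spec`s; `focal_spec` is conventionally
#'   the homoplasy model.
#' @param n_sim Simulated datasets per model (default 5000).
#' @param seed Integer seed.
#' @param ci_type `"two_sided"` (default, 2.5/97.5 percentiles) or
#'   `"upper"` (0/95).
#' @return A `pmc_result`: `delta_emp`, both ratio distributions and CIs,
#'   the four-way classification, refit parameter tables, and bookkeeping.
#' @export
pmc_compare <- function(tree, painting, x, focal_spec, alt_spec,
                        n_sim = 5000, seed = 1L,
                        ci_type = c("two_sided", "upper")) {
  ci_type <- match.arg(ci_type)
  ctx <- tree_ctx(tree)
  x <- align_trait_vector(x, ctx$tips)
  fit_f <- assemble_fit(ctx, painting, x, focal_spec)
  fit_a <- assemble_fit(ctx, painting, x, alt_spec)
  delta_emp <- likelihood_ratio(fit_f, fit_a)

  dist_f <- lr_distribution_ctx(ctx, painting, fit_f, focal_spec, alt_spec,
                                n_sim, seed, gen_is_focal = TRUE)
  dist_a <- lr_distribution_ctx(ctx, painting, fit_a, focal_spec, alt_spec,
                                n_sim, seed + 1L, gen_is_focal = FALSE)

  clean <- function(d, label) {
    bad <- !is.finite(d$delta)
    if (sum(bad) > 0.01 * length(d$delta))
      stop("more than 1% non-convergent refits under the ", label,
           " model (", sum(bad), "/", length(d$delta), ")", call. = FALSE)
    list(delta = d$delta[!bad], dropped = sum(bad))
  }
  cf <- clean(dist_f, "focal"); ca <- clean(dist_a, "alternative")
  probs <- if (ci_type == "two_sided") c(0.025, 0.975) else c(0, 0.95)
  ci_f <- unname(quantile(cf$delta, probs, type = 7))
  ci_a <- unname(quantile(ca$delta, probs, type = 7))

  structure(list(
    focal = focal_spec$name, alternative = alt_spec$name,
    fit_focal = fit_f, fit_alt = fit_a, delta_emp = delta_emp,
    dist_focal = cf$delta, dist_alt = ca$delta,
    ci_focal = ci_f, ci_alt = ci_a,
    classification = classify_delta(delta_emp, ci_f, ci_a),
    refits_focal = dist_f$params_focal,     # focal model fit to focal sims
    refits_alt = dist_a$params_alt,         # alt model fit to alt sims
    dropped = c(focal = cf$dropped, alternative = ca$dropped),
    n_sim = n_sim, seed = seed, ci_type = ci_type),
    class = "pmc_result")
}

#' @export
print.pmc_result <- function(x, ...) {
  cat("PMC: ", x$focal, " vs ", x$alternative, "\n", sep = "")
  cat("  delta_emp = ", signif(x$delta_emp, 6), "\n", sep = "")
  cat("  95% CI under ", x$focal, ": [", signif(x$ci_focal[1], 5), ", ",
      signif(x$ci_focal[2], 5), "]\n", sep = "")
  cat("  95% CI under ", x$alternative, ": [", signif(x$ci_alt[1], 5), ", ",
      signif(x$ci_alt[2], 5), "]\n", sep = "")
  cat("  classification: ", x$classification, "\n", sep = "")
  invisible(x)
}

#' @method glance pmc_result
#' @export
glance.pmc_result <- function(x, ...) {
  tibble::tibble(focal = x$focal, alternative = x$alternative,
                 delta_emp = x$delta_emp,
                 ci_focal_lo = x$ci_focal[1], ci_focal_hi = x$ci_focal[2],
                 ci_alt_lo = x$ci_alt[1], ci_alt_hi = x$ci_alt[2],
                 classification = x$classification, n_sim = x$n_sim)
}

#' Bootstrap confidence intervals for fitted parameters
#'
#' Percentile 95% CIs for each parameter of a model, from refits of the
#' model to data simulated under itself; a parameter is flagged reliable
#' when its empirical estimate falls inside its own bootstrap CI.
#'
#' @param refits Tibble of per-refit parameter estimates (e.g. the
#'   `refits_focal` element of a `pmc_result`), at least 100 rows.
#' @param fit The empirical `ou_fit` of the same model.
#' @return Tibble: `parameter`, `estimate`, `ci_lo`, `ci_hi`, `reliable`.
#' @export
parameter_cis <- function(refits, fit) {
  if (nrow(refits) < 100)
    stop("need at least 100 refits for bootstrap CIs (got ", nrow(refits),
         ")", call. = FALSE)
  est <- setNames(fit_param_values(fit), fit_param_names(fit))
  common <- intersect(names(est), names(refits))
  purrr::map_dfr(common, function(pn) {
    v <- refits[[pn]]
    v <- v[is.finite(v)]
    ci <- unname(quantile(v, c(0.025, 0.975), type = 7))
    tibble::tibble(parameter = pn, estimate = unname(est[pn]),
                   ci_lo = ci[1], ci_hi = ci[2],
                   reliable = est[pn] >= ci[1] && est[pn] <= ci[2])
  })
}

#' Plot a pairwise model comparison
#'
#' The two simulated likelihood-ratio distributions with the empirical
#' ratio marked, mirroring the standard phylogenetic-Monte-Carlo display.
#'
#' @param object A `pmc_result`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pmc_result
#' @export
autoplot.pmc_result <- function(object, bins = 40, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(delta = object$dist_focal, model = object$focal),
    tibble::tibble(delta = object$dist_alt, model = object$alternative))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, fill = .data$model)) +
    ggplot2::geom_histogram(alpha = 0.55, bins = bins,
                            position = "identity") +
    ggplot2::geom_vline(xintercept = object$delta_emp, linetype = "dotted",
                        linewidth = 0.8) +
    ggplot2::labs(x = expression(delta), y = "simulated datasets",
                  subtitle = paste0("delta_emp = ",
                                    signif(object$delta_emp, 5), "  (",
                                    object$classification, ")")) +
    ggplot2::theme_minimal()
}
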