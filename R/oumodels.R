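#' Specify a trait-evolution hypothesis model
#'
#' A model is single-rate Brownian motion (`BM1`) or a multi-optimum
#' Ornstein-Uhlenbeck process with one pull parameter `alpha`, one diffusion
#' `sigma2`, and `k` distinct optima mapped onto the painted regimes.  Under
#' the default root policy the ancestral state equals the optimum of the
#' root (background) regime, so an OU model has `p = 2 + k` free parameters;
#' with a free root state `p = 3 + k`.  BM1 has `p = 2` (`X0`, `sigma2`).
#'
#' @param name Model label.
#' @param family `"BM1"` or `"OU"`.
#' @param optima_map Named integer vector mapping each regime label to an
#'   optimum index `1..k` (OU only).
#' @param optima_names Labels for the `k` optima (defaults to `theta_1..k`).
#' @param root_policy `"root_regime"` (root state equals the root regime's
#'   optimum) or `"free"` (X0 estimated).
#' @return A `model_spec`.
#' @export
model_spec <- function(name, family = c("OU", "BM1"), optima_map = NULL,
                       optima_names = NULL,
                       root_policy = c("root_regime", "free")) {
  family <- match.arg(family)
  root_policy <- match.arg(root_policy)
  if (family == "OU") {
    if (is.null(optima_map) || is.null(names(optima_map)))
      stop("OU models need a named regime -> optimum map", call. = FALSE)
    k <- max(optima_map)
    if (!setequal(unique(optima_map), seq_len(k)))
      stop("optimum indices must be 1..k", call. = FALSE)
    if (is.null(optima_names)) optima_names <- paste0("theta_", seq_len(k))
    if (length(optima_names) != k) stop("need one name per optimum", call. = FALSE)
    p <- 2L + k + (root_policy == "free")
  } else {
    k <- 0L; optima_map <- NULL; optima_names <- character(0); p <- 2L
  }
  structure(list(name = name, family = family, optima_map = optima_map,
                 optima_names = optima_names, k = k,
                 root_policy = root_policy, p = p),
            class = "model_spec")
}

#' The six-hypothesis model set
#'
#' Builds the standard comparison set for two derived-regime clades on a
#' background regime: `BM1` (non-adaptive drift), `OU1` (one shared optimum),
#' `OU2_shared` (both derived clades share one novel optimum — the
#' trait-optimum homoplasy hypothesis), `OU2_onlyB` (clade A retains the
#' background optimum, clade B departs), `OU2_onlyA` (the reverse), and
#' `OU3` (each clade with its own optimum).  The list order is the
#' deterministic tie-break order used in scoring.
#'
#' @param background,cladeA,cladeB Regime labels as used in the painting.
#' @param root_policy Root-state policy passed to every OU spec.
#' @return Named list of six `model_spec`s.
#' @export
hypothesis_models <- function(background = "background", cladeA = "cladeA",
                              cladeB = "cladeB",
                              root_policy = c("root_regime", "free")) {
  root_policy <- match.arg(root_policy)
  bg <- background; A <- cladeA; B <- cladeB
  mk <- function(name, map, onames)
    model_spec(name, "OU", map, onames, root_policy)
  list(
    BM1 = model_spec("BM1", "BM1"),
    OU1 = mk("OU1", setNames(c(1L, 1L, 1L), c(bg, A, B)), "global"),
    OU2_shared = mk("OU2_shared", setNames(c(1L, 2L, 2L), c(bg, A, B)),
                    c(bg, "derived")),
    OU2_onlyB = mk("OU2_onlyB", setNames(c(1L, 1L, 2L), c(bg, A, B)),
                   c(paste(bg, A, sep = "+"), B)),
    OU2_onlyA = mk("OU2_onlyA", setNames(c(1L, 2L, 1L), c(bg, A, B)),
                   c(paste(bg, B, sep = "+"), A)),
    OU3 = mk("OU3", setNames(c(1L, 2L, 3L), c(bg, A, B)), c(bg, A, B))
  )
}

#' OU expectation at the tips
#'
#' Expected trait value for each lineage under a multi-optimum OU process:
#' `E_i = X0 exp(-a T_i) + sum_seg theta(seg) (exp(-a(T_i - t_end)) -
#' exp(-a(T_i - t_start)))` over the lineage's regime segments.
#'
#' @param histories Lineage histories (see [lineage_histories()]).
#' @param alpha Pull strength (> 0, per My).
#' @param theta Named vector of optima by regime label.
#' @param x0 Root state.
#' @return Named vector of tip expectations, in the histories' tip order.
#' @export
ou_expectation <- function(histories, alpha, theta, x0) {
  stopifnot(alpha > 0)
  miss <- setdiff(unique(histories$regime), names(theta))
  if (length(miss))
    stop("regime(s) without an optimum: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tips <- unique(histories$tip)
  Ti <- tapply(histories$t_end, histories$tip, max)[tips]
  th <- theta[histories$regime]
  w <- exp(-alpha * (Ti[histories$tip] - histories$t_end)) -
       exp(-alpha * (Ti[histories$tip] - histories$t_start))
  contrib <- tapply(th * w, histories$tip, sum)[tips]
  setNames(as.numeric(x0 * exp(-alpha * Ti) + contrib), tips)
}

#' OU covariance among tips (fixed-root form)
#'
#' `V_ij = sigma2/(2 alpha) exp(-alpha (T_i + T_j - 2 t_a)) (1 -
#' exp(-2 alpha t_a))` with `t_a` the height of the pair's MRCA above the
#' root.  This is the non-stationary (fixed root state) formulation.
#'
#' @param tree A `phylo` object.
#' @param alpha Pull strength (> 0).
#' @param sigma2 Diffusion variance (> 0).
#' @return Symmetric positive-definite matrix in tip-label order.
#' @export
ou_covariance <- function(tree, alpha, sigma2) {
  stopifnot(is.finite(alpha), alpha > 0, is.finite(sigma2), sigma2 > 0)
  ta <- ape::vcv(tree) + root_edge_length(tree)
  depths <- diag(ta)
  S <- outer(depths, depths, "+") - 2 * ta
  -sigma2 / (2 * alpha) * exp(-alpha * S) * expm1(-2 * alpha * ta)
}

#' BM covariance among tips
#'
#' `V_ij = sigma2 * t_a(i, j)`, the shared path length from the root scaled
#' by the diffusion rate; `V_ii = sigma2 * T_i`.
#'
#' @param tree A `phylo` object.
#' @param sigma2 Diffusion variance (> 0).
#' @return Covariance matrix in tip-label order.
#' @export
bm_covariance <- function(tree, sigma2) {
  stopifnot(is.finite(sigma2), sigma2 > 0)
  sigma2 * (ape::vcv(tree) + root_edge_length(tree))
}

#' Multivariate-normal log-likelihood
#'
#' @param x Observed trait vector.
#' @param E Expectation vector.
#' @param V Covariance matrix (must be positive definite).
#' @return `lnL = -(n/2) log(2 pi) - log|V|/2 - (x-E)' V^-1 (x-E) / 2`.
#' @export
loglik <- function(x, E, V) {
  n <- length(x)
  stopifnot(length(E) == n, all(dim(V) == n))
  cc <- tryCatch(chol(V), error = function(e) {
    ev <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
    stop("covariance not positive definite (smallest eigenvalue ",
         signif(ev, 4), ")", call. = FALSE)
  })
  z <- backsolve(cc, x - E, transpose = TRUE)
  -n / 2 * log(2 * pi) - sum(log(diag(cc))) - sum(z^2) / 2
}

#' Schwarz information criterion
#'
#' `SIC = -2 lnL + p log(n)`; lower values indicate higher model support.
#'
#' @param lnL Maximized log-likelihood.
#' @param p Number of estimated parameters (>= 1).
#' @param n Number of species (>= 2).
#' @return The SIC value.
#' @export
sic <- function(lnL, p, n) {
  stopifnot(p >= 1, n >= 2)
  -2 * lnL + p * log(n)
}

#' Phylogenetic half-life
#'
#' `t_1/2 = log(2) / alpha`: half the expected time for a lineage to move to
#' a new optimum after entering a novel selective regime.
#'
#' @param alpha Pull strength (> 0).
#' @return Half-life in My.
#' @export
half_life <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be > 0", call. = FALSE)
  log(2) / alpha
}

# ---- internal fitting machinery ------------------------------------------

# Per-tree precomputation shared by every fit on the same tree.
tree_ctx <- function(tree) {
  ta <- ape::vcv(tree) + root_edge_length(tree)
  depths <- diag(ta)
  list(tree = tree, ta = ta, depths = depths, T = max(depths),
       n = length(depths), tips = tree$tip.label)
}

# Segment table for the optimum design matrix, in tree tip order.
model_design <- function(tree, painting, spec) {
  if (spec$family == "BM1") return(NULL)
  miss <- setdiff(unique(painting$regime), names(spec$optima_map))
  if (length(miss))
    stop("painting regime(s) not mapped to an optimum: ",
         paste(miss, collapse = ", "), call. = FALSE)
  hist <- lineage_histories(tree, painting)
  tip_idx <- match(hist$tip, tree$tip.label) - 1L
  opt_idx <- spec$optima_map[hist$regime] - 1L
  root_regime <- painting$regime[which.min(painting$start)]
  root_opt <- if (spec$root_policy == "root_regime")
    spec$optima_map[[attr(painting, "background") %||% root_regime]] - 1L
  else -1L
  list(seg_tip = as.integer(tip_idx), seg_opt = as.integer(opt_idx),
       seg_start = hist$t_start, seg_end = hist$t_end,
       k = spec$k, root_opt = as.integer(root_opt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_alpha_grid <- function(T, n_starts = 7) {
  # deterministic multi-starts spanning half-lives from 0.01 T to 10 T
  thalf <- exp(seq(log(10 * T), log(0.01 * T), length.out = n_starts))
  log(2) / thalf
}

alpha_bounds <- function(T) c(lower = log(2) / (100 * T), upper = 1e4 / T)

# Fit the OU model to every column of X (n x m).  The grid stage shares one
# Cholesky per start alpha across datasets; each dataset is then refined by
# Brent search between the neighbouring grid points.  The tolerance is on
# log(alpha); the lnL error it leaves is quadratic in it, far below 1e-6.
fit_ou_batch <- function(ctx, design, X, alpha_grid = NULL, tol = 1e-5) {
  X <- as.matrix(X)
  if (is.null(alpha_grid)) alpha_grid <- default_alpha_grid(ctx$T)
  alpha_grid <- sort(alpha_grid)
  bounds <- alpha_bounds(ctx$T)
  r <- ou_fit_batch_cpp(X, ctx$ta, ctx$depths, design$seg_tip,
                        design$seg_opt, design$seg_start, design$seg_end,
                        design$k, design$root_opt, alpha_grid,
                        bounds[["lower"]], bounds[["upper"]], tol)
  list(alpha = as.numeric(r$alpha), sigma2 = as.numeric(r$sigma2),
       lnL = as.numeric(r$lnL), coef = r$coef,
       boundary = as.logical(r$boundary))
}

# BM fit: GLS root state + profiled rate, no optimization needed.  The
# Cholesky of the (parameter-free) BM shape matrix is cached in ctx.
fit_bm_batch <- function(ctx, X) {
  X <- as.matrix(X)
  if (is.null(ctx$bm_chol)) {
    cc <- chol(ctx$ta)
    ctx$bm_chol <- t(cc)
    ctx$bm_logdet <- 2 * sum(log(diag(cc)))
  }
  m <- ncol(X)
  out <- list(x0 = numeric(m), sigma2 = numeric(m), lnL = numeric(m))
  for (j in seq_len(m)) {
    r <- bm_profile_chol_cpp(ctx$bm_chol, ctx$bm_logdet, X[, j])
    out$x0[j] <- as.numeric(r$coef)
    out$sigma2[j] <- r$sigma2
    out$lnL[j] <- r$lnL
  }
  out
}

#' Fit a BM or OU model by maximum likelihood
#'
#' OU fitting is a deterministic multi-start search over `log(alpha)` (seven
#' starts spanning half-lives from `0.01 T` to `10 T`, Brent-refined), with
#' the optima profiled out by generalized least squares and `sigma2` by its
#' closed-form ML value at each alpha.  BM1 is fitted in closed form.  An
#' `alpha` estimate at the search bounds (`log(2)/(100 T)` to `1e4 / T`) is
#' flagged, not silently accepted.
#'
#' @param tree A `phylo` object.
#' @param painting A `regime_painting` (ignored for BM1; a uniform painting
#'   suffices for OU1).
#' @param x Trait residual vector, named by species or in tip order.
#' @param spec A `model_spec`.
#' @param alpha_grid Optional vector of start values for alpha.
#' @return An `ou_fit`: parameters, `lnL`, `SIC`, `t_half` and convergence
#'   diagnostics.
#' @export
fit_model <- function(tree, painting, x, spec, alpha_grid = NULL) {
  ctx <- tree_ctx(tree)
  x <- align_trait_vector(x, ctx$tips)
  assemble_fit(ctx, painting, x, spec, alpha_grid)
}

align_trait_vector <- function(x, tips) {
  if (!is.null(names(x))) {
    miss <- setdiff(tips, names(x))
    if (length(miss))
      stop("trait values missing for tip(s): ", paste(head(miss, 5), collapse = ", "),
           call. = FALSE)
    x <- x[tips]
  } else if (length(x) != length(tips)) {
    stop("trait vector length does not match tip count", call. = FALSE)
  }
  as.numeric(x)
}

assemble_fit <- function(ctx, painting, x, spec, alpha_grid = NULL) {
  n <- ctx$n
  if (spec$family == "BM1") {
    r <- fit_bm_batch(ctx, matrix(x, ncol = 1))
    fit <- list(spec = spec, alpha = NA_real_, sigma2 = r$sigma2,
                theta = setNames(numeric(0), character(0)), x0 = r$x0,
                lnL = r$lnL, n = n, p = spec$p,
                sic = sic(r$lnL, spec$p, n), t_half = NA_real_,
                convergence = list(status = "ok", n_starts = 1L))
  } else {
    design <- model_design(ctx$tree, painting, spec)
    r <- fit_ou_batch(ctx, design, matrix(x, ncol = 1), alpha_grid)
    if (!is.finite(r$lnL[1]))
      return(structure(list(spec = spec, alpha = NA_real_, sigma2 = NA_real_,
                            theta = NULL, x0 = NA_real_, lnL = -Inf, n = n,
                            p = spec$p, sic = Inf, t_half = NA_real_,
                            convergence = list(status = "failed",
                                               n_starts = length(r$alpha))),
                       class = "ou_fit"))
    theta <- setNames(r$coef[1, seq_len(spec$k)], spec$optima_names)
    x0 <- if (spec$root_policy == "free") r$coef[1, spec$k + 1] else
      theta[[design$root_opt + 1L]]
    fit <- list(spec = spec, alpha = r$alpha[1], sigma2 = r$sigma2[1],
                theta = theta, x0 = x0, lnL = r$lnL[1], n = n, p = spec$p,
                sic = sic(r$lnL[1], spec$p, n),
                t_half = half_life(r$alpha[1]),
                convergence = list(
                  status = if (r$boundary[1]) "boundary" else "ok",
                  n_starts = length(alpha_grid %||% default_alpha_grid(ctx$T))))
  }
  structure(fit, class = "ou_fit")
}

#' @export
print.ou_fit <- function(x, ...) {
  cat("Model ", x$spec$name, " (", x$spec$family, "): lnL = ",
      signif(x$lnL, 7), ", SIC = ", signif(x$sic, 7), ", p = ", x$p,
      ", n = ", x$n, "\n", sep = "")
  if (x$spec$family == "OU") {
    cat("  alpha = ", signif(x$alpha, 5), " /My  (t1/2 = ",
        signif(x$t_half, 4), " My), sigma2 = ", signif(x$sigma2, 5), "\n",
        sep = "")
    cat("  optima: ", paste(names(x$theta), signif(x$theta, 5), sep = " = ",
                            collapse = ", "), "\n", sep = "")
  } else {
    cat("  X0 = ", signif(x$x0, 5), ", sigma2 = ", signif(x$sigma2, 5), "\n",
        sep = "")
  }
  if (x$convergence$status != "ok")
    cat("  [convergence: ", x$convergence$status, "]\n", sep = "")
  invisible(x)
}

#' @method tidy ou_fit
#' @export
tidy.ou_fit <- function(x, ...) {
  tibble::tibble(term = fit_param_names(x),
                 estimate = fit_param_values(x))
}

#' @method glance ou_fit
#' @export
glance.ou_fit <- function(x, ...) {
  tibble::tibble(model = x$spec$name, family = x$spec$family,
                 logLik = x$lnL, SIC = x$sic, p = x$p, n = x$n,
                 alpha = x$alpha, sigma2 = x$sigma2, t_half = x$t_half,
                 convergence = x$convergence$status)
}

fit_param_names <- function(fit) {
  if (fit$spec$family == "BM1") c("X0", "sigma2")
  else c("alpha", "sigma2",
         if (length(fit$theta)) paste0("theta[", names(fit$theta), "]"),
         if (fit$spec$root_policy == "free") "X0")
}

fit_param_values <- function(fit) {
  if (fit$spec$family == "BM1") c(fit$x0, fit$sigma2)
  else c(fit$alpha, fit$sigma2, unname(fit$theta),
         if (fit$spec$root_policy == "free") fit$x0)
}

#' Serialize a fit to a JSON record
#'
#' @param fit An `ou_fit`.
#' @param path Optional file to write.
#' @return JSON string (invisibly when written).
#' @export
fit_to_json <- function(fit, path = NULL) {
  rec <- list(model = fit$spec$name, family = fit$spec$family,
              parameters = as.list(setNames(fit_param_values(fit),
                                            fit_param_names(fit))),
              lnL = fit$lnL, SIC = fit$sic, t_half = fit$t_half,
              n = fit$n, p = fit$p, convergence = fit$convergence)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
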