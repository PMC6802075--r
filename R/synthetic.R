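#' Generate a clade-structured ultrametric study tree
#'
#' Simulates a pure-birth background tree and grafts two monophyletic
#' derived clades onto background branches, each with a stem branch whose
#' base sits at the requested stem age; the whole tree is scaled to the
#' exact depth.  Emulates a sampling design with one paraphyletic
#' background group and two nested derived-regime clades.
#'
#' @param n_bg Background tips (>= 2).
#' @param n_cladeA,n_cladeB Tips in the two derived clades (>= 2 each).
#' @param depth Tree depth in My.
#' @param stem_ages Named numeric: ages (My before present) of the base of
#'   each clade's stem branch.
#' @param crown_frac Crown age of each derived clade as a fraction of its
#'   stem age.
#' @param seed Integer seed (same seed, same Newick string).
#' @return List: `tree` (`phylo`), `groups` (tibble `species`, `group`).
#' @export
generate_tree <- function(n_bg = 76, n_cladeA = 43, n_cladeB = 6,
                          depth = 70,
                          stem_ages = c(cladeA = 24.5, cladeB = 31.3),
                          crown_frac = 0.7, seed = 1L) {
  stopifnot(n_bg >= 2, n_cladeA >= 2, n_cladeB >= 2, depth > 0,
            all(stem_ages < depth), crown_frac > 0, crown_frac < 1)
  set.seed(seed)
  scale_to <- function(tr, d) {
    tr$edge.length <- tr$edge.length * d / max(node_heights(tr))
    tr
  }
  bg <- scale_to(ape::rphylo(n_bg, birth = 0.1, death = 0), depth)
  bg$tip.label <- sprintf("bg_%03d", seq_len(n_bg))
  tree <- bg
  for (cl in c("cladeA", "cladeB")) {
    n_cl <- if (cl == "cladeA") n_cladeA else n_cladeB
    stem <- stem_ages[[cl]]
    crown <- crown_frac * stem
    sub <- scale_to(ape::rphylo(n_cl, birth = 0.3, death = 0), crown)
    sub$tip.label <- sprintf("%s_%03d", sub("clade", "c", cl), seq_len(n_cl))
    sub$root.edge <- stem - crown
    h_attach <- depth - stem
    hh <- node_heights(tree)
    bg_only <- vapply(seq_len(nrow(tree$edge)), function(e) {
      nd <- descendant_nodes(tree, tree$edge[e, 2])
      tips <- nd[nd <= ape::Ntip(tree)]
      all(startsWith(tree$tip.label[tips], "bg_"))
    }, TRUE)
    cand <- which(bg_only &
                  hh[tree$edge[, 1]] < h_attach &
                  hh[tree$edge[, 2]] > h_attach)
    if (!length(cand))
      stop("no background branch spans the stem age for ", cl,
           " (", stem, " My): impossible configuration", call. = FALSE)
    e <- cand[sample.int(length(cand), 1)]
    pos <- hh[tree$edge[e, 2]] - h_attach
    tree <- ape::bind.tree(tree, sub, where = tree$edge[e, 2],
                           position = pos)
  }
  groups <- tibble::tibble(
    species = tree$tip.label,
    group = dplyr::case_when(
      startsWith(tree$tip.label, "cA_") ~ "cladeA",
      startsWith(tree$tip.label, "cB_") ~ "cladeB",
      TRUE ~ "background"))
  list(tree = tree, groups = groups)
}

#' Configure one synthetic trait
#'
#' Defaults describe a strongly informative adaptive trait: OU residual with
#' a 2 My half-life, stationary SD 0.1 on the natural-log scale, derived
#' optima 4 stationary SDs below the background, a common allometric slope
#' of 1/3 on ln body mass, and one specimen per species.
#'
#' @param name Trait id.
#' @param model Generating model name (one of `names(hypothesis_models())`).
#' @param t_half OU half-life in My (ignored for BM1).
#' @param stationary_sd Stationary SD `sqrt(sigma2 / (2 alpha))` of the OU
#'   residual; for BM1, interpreted as the SD accrued over the tree depth.
#' @param theta Named optima on the residual scale, by regime
#'   (`background`, `cladeA`, `cladeB`); must be consistent with `model`.
#' @param slope,intercept Allometric line: species mean ln-trait =
#'   `intercept + slope * ln_mass + residual`.
#' @param specimen_sd SD of specimen measurements around the species mean.
#' @param n_specimens Specimens per species.
#' @return A `trait_config` list.
#' @export
trait_config <- function(name = "trait1", model = "OU2_shared", t_half = 2,
                         stationary_sd = 0.1,
                         theta = c(background = 0, cladeA = -0.4,
                                   cladeB = -0.4),
                         slope = 1 / 3, intercept = 0, specimen_sd = 0.05,
                         n_specimens = 1) {
  stopifnot(t_half > 0, stationary_sd > 0, specimen_sd >= 0,
            n_specimens >= 1)
  structure(list(name = name, model = model, t_half = t_half,
                 stationary_sd = stationary_sd, theta = theta, slope = slope,
                 intercept = intercept, specimen_sd = specimen_sd,
                 n_specimens = n_specimens),
            class = "trait_config")
}

# generating-model parameters on the residual scale, tree depth needed for
# the BM1 rate convention
config_params <- function(cfg, depth) {
  if (cfg$model == "BM1") {
    list(family = "BM1", sigma2 = cfg$stationary_sd^2 / depth, x0 = 0)
  } else {
    alpha <- log(2) / cfg$t_half
    list(family = "OU", alpha = alpha,
         sigma2 = 2 * alpha * cfg$stationary_sd^2, theta = cfg$theta,
         x0 = unname(cfg$theta["background"]))
  }
}

#' Generate body masses and specimen-level traits on a painted tree
#'
#' Ln body mass evolves as BM on the tree plus constant group offsets (so
#' groups differ in mass range); each species' mean ln-trait is the
#' allometric line plus an OU/BM residual simulated under the trait's
#' generating model; specimens are drawn Normal around the species mean.
#'
#' @param tree A `phylo` object.
#' @param groups Tibble `species`, `group` (as from [generate_tree()]).
#' @param painting A `regime_painting` for `tree`.
#' @param configs List of [trait_config()]s.
#' @param seed Integer seed.
#' @param mass_sigma2 BM rate of ln body mass (per My).
#' @param mass_x0 Root ln body mass.
#' @param mass_offsets Named group offsets added to ln body mass.
#' @return List: `traits` (specimen-level tibble), `mass` (named ln-mass
#'   vector), `residuals` (species x trait matrix of the true generating
#'   residuals), `params` (per-trait generating parameters).
#' @export
generate_traits <- function(tree, groups, painting, configs,
                            seed = 1L, mass_sigma2 = 0.02, mass_x0 = 6,
                            mass_offsets = c(background = 0, cladeA = 1,
                                             cladeB = 0)) {
  if (inherits(configs, "trait_config")) configs <- list(configs)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, length(configs) + 1L)
  depth <- max(node_heights(tree))
  mass_batch <- simulate_traits(tree, painting,
                                list(family = "BM1", sigma2 = mass_sigma2,
                                     x0 = mass_x0),
                                n_datasets = 1, seed = sub[1])
  ln_mass <- drop(mass_batch$data) +
    mass_offsets[groups$group[match(tree$tip.label, groups$species)]]
  ln_mass <- setNames(as.numeric(ln_mass), tree$tip.label)

  resid_mat <- matrix(NA_real_, length(ln_mass), length(configs),
                      dimnames = list(tree$tip.label,
                                      vapply(configs, `[[`, "", "name")))
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    pp <- config_params(cfg, depth)
    resid <- drop(simulate_traits(tree, painting, pp, 1,
                                  seed = sub[i + 1])$data)
    resid_mat[, i] <- resid
    sp_mean <- cfg$intercept + cfg$slope * ln_mass + resid
    set.seed(sub[i + 1] + 1L)
    rows[[i]] <- tidyr::expand_grid(species = tree$tip.label,
                                    specimen = seq_len(cfg$n_specimens)) |>
      dplyr::mutate(trait = cfg$name,
                    value = rnorm(dplyr::n(),
                                  mean = sp_mean[.data$species],
                                  sd = cfg$specimen_sd))
  }
  list(traits = dplyr::bind_rows(rows)[c("species", "specimen", "trait",
                                         "value")],
       mass = ln_mass, residuals = resid_mat,
       params = lapply(configs, function(cfg)
         c(list(name = cfg$name), config_params(cfg, depth),
           list(slope = cfg$slope, intercept = cfg$intercept,
                specimen_sd = cfg$specimen_sd))))
}

#' Generate a complete synthetic study
#'
#' A full synthetic analogue of a two-fossorial-clade comparative study:
#' study tree with two monophyletic derived clades, stem-shift regime
#' painting, ln body masses, and specimen-level ln traits with known
#' generating parameters.  Optionally, `n_bg_extra` extra background
#' species are present in the trait and mass tables but excluded from the
#' study tree, so the allometric regression runs on more species than the
#' model fits (as when a trait dataset is richer than the pruned
#' phylogeny).  Fully reproducible from the master seed.
#'
#' @param n_bg,n_cladeA,n_cladeB Retained group sizes.
#' @param n_bg_extra Extra background species dropped after the regression.
#' @param depth,stem_ages,crown_frac Tree shape (see [generate_tree()]).
#' @param configs List of [trait_config()]s.
#' @param seed Master seed.
#' @param ... Passed to [generate_traits()] (mass model settings).
#' @return A `synthetic_study`: `tree` (study tree), `tree_full`, `groups`
#'   (with `retained` flag), `painting`, `mass`, `traits`, `residuals`
#'   (true generating residuals for retained species), `params`, `seed`.
#' @export
synthetic_study <- function(n_bg = 76, n_cladeA = 43, n_cladeB = 6,
                            n_bg_extra = 0, depth = 70,
                            stem_ages = c(cladeA = 24.5, cladeB = 31.3),
                            crown_frac = 0.7,
                            configs = list(trait_config()), seed = 1L, ...) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 2L)
  gt <- generate_tree(n_bg + n_bg_extra, n_cladeA, n_cladeB, depth,
                      stem_ages, crown_frac, seed = sub[1])
  groups <- gt$groups
  bg_tips <- groups$species[groups$group == "background"]
  dropped <- if (n_bg_extra > 0)
    sort(sample(bg_tips, n_bg_extra)) else character(0)
  groups$retained <- !(groups$species %in% dropped)
  painting_full <- paint_regimes(gt$tree, list(
    regime_clade(groups$species[groups$group == "cladeA"], "cladeA"),
    regime_clade(groups$species[groups$group == "cladeB"], "cladeB")),
    background = "background")
  td <- generate_traits(gt$tree, groups, painting_full, configs,
                        seed = sub[2], ...)
  tree <- prune_tree(gt$tree, groups$species[groups$retained])
  painting <- paint_regimes(tree, list(
    regime_clade(intersect(tree$tip.label,
                           groups$species[groups$group == "cladeA"]),
                 "cladeA"),
    regime_clade(intersect(tree$tip.label,
                           groups$species[groups$group == "cladeB"]),
                 "cladeB")),
    background = "background")
  structure(list(tree = tree, tree_full = gt$tree, groups = groups,
                 painting = painting, mass = td$mass, traits = td$traits,
                 residuals = td$residuals[tree$tip.label, , drop = FALSE],
                 params = td$params, configs = configs, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  sz <- table(x$groups$group[x$groups$retained])
  cat("synthetic_study: ", ape::Ntip(x$tree), " retained species (",
      paste(names(sz), sz, sep = " = ", collapse = ", "), "), ",
      length(x$params), " trait(s), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Fit the generating model back to a synthetic trait
#'
#' Runs the study's own data through the allometric regression (on the full
#' species set), prunes to the study tree, fits the trait's generating
#' model, and reports estimates against the known truth.
#'
#' @param study A `synthetic_study`.
#' @param trait Trait id (default: the first configured trait).
#' @return Tibble: `parameter`, `truth`, `estimate`, `bias`, `rel_error`,
#'   plus the fit in `attr(, "fit")`.
#' @export
recover_parameters <- function(study, trait = NULL) {
  cfgs <- study$configs
  if (is.null(trait)) trait <- cfgs[[1]]$name
  cfg <- cfgs[[vapply(cfgs, `[[`, "", "name") == trait]]
  af <- fit_allometry(study$traits, study$mass, trait, n_perm = 0)
  x <- residual_matrix(list(af), study$tree$tip.label)[, 1]
  spec <- hypothesis_models()[[cfg$model]]
  fit <- fit_model(study$tree, study$painting, x, spec)
  pp <- config_params(cfg, max(node_heights(study$tree)))
  truth <- if (pp$family == "BM1") c(X0 = 0, sigma2 = pp$sigma2) else {
    th <- setNames(pp$theta[names(spec$optima_map)], names(spec$optima_map))
    opt_truth <- vapply(seq_len(spec$k), function(k)
      unname(th[which(spec$optima_map == k)[1]]), 0)
    # residuals are centred by the regression; optima are identified up to
    # that common shift, so compare them after centring both sides
    c(alpha = pp$alpha, sigma2 = pp$sigma2,
      setNames(opt_truth, paste0("theta[", spec$optima_names, "]")))
  }
  est <- setNames(fit_param_values(fit), fit_param_names(fit))
  is_th <- startsWith(names(truth), "theta[")
  if (sum(is_th) > 1) {
    truth[is_th] <- truth[is_th] - mean(truth[is_th])
    eth <- startsWith(names(est), "theta[")
    est[eth] <- est[eth] - mean(est[eth])
  }
  common <- intersect(names(truth), names(est))
  out <- tibble::tibble(parameter = common,
                        truth = unname(truth[common]),
                        estimate = unname(est[common]))
  out$bias <- out$estimate - out$truth
  out$rel_error <- ifelse(out$truth != 0, out$bias / out$truth, NA_real_)
  attr(out, "fit") <- fit
  out
}
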