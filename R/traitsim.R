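#' Simulate tip traits under a fitted or specified model
#'
#' Draws datasets exactly from the model's multivariate-normal distribution
#' at the tips.  The default route applies the Cholesky factor of the model
#' covariance to standard-normal draws; the `"recursive"` route simulates
#' the process segment by segment along the tree in preorder and is retained
#' as an independent check (the two are equal in distribution).
#'
#' @param tree A `phylo` object.
#' @param painting A `regime_painting` (ignored for BM).
#' @param params An `ou_fit`, or a list with `family` (`"OU"`/`"BM1"`),
#'   `sigma2`, and for OU `alpha`, `theta` (named by regime) and `x0`;
#'   for BM `x0`.
#' @param n_datasets Number of datasets to draw.
#' @param seed Integer seed; the batch is reproducible given
#'   (seed, parameters, tree).
#' @param method `"cholesky"` (default) or `"recursive"`.
#' @return A `sim_batch`: list with `data` (`n_datasets` x `n_tips` matrix,
#'   columns named by tip), `params`, `seed`, `method`.
#' @export
simulate_traits <- function(tree, painting, params, n_datasets = 1,
                            seed = 1L, method = c("cholesky", "recursive")) {
  method <- match.arg(method)
  stopifnot(n_datasets >= 1)
  pp <- normalize_params(params, painting)
  set.seed(seed)
  data <- if (method == "cholesky")
    sim_mvn(tree, painting, pp, n_datasets)
  else
    sim_recursive(tree, painting, pp, n_datasets)
  colnames(data) <- tree$tip.label
  structure(list(data = data, params = pp, seed = seed, method = method,
                 tips = tree$tip.label),
            class = "sim_batch")
}

normalize_params <- function(params, painting) {
  if (inherits(params, "ou_fit")) {
    spec <- params$spec
    if (spec$family == "BM1")
      return(list(family = "BM1", sigma2 = params$sigma2, x0 = params$x0))
    theta_regime <- setNames(params$theta[spec$optima_map],
                             names(spec$optima_map))
    return(list(family = "OU", alpha = params$alpha, sigma2 = params$sigma2,
                theta = theta_regime, x0 = params$x0))
  }
  stopifnot(is.list(params), !is.null(params$family), params$sigma2 > 0)
  if (params$family == "OU") stopifnot(params$alpha > 0,
                                       !is.null(params$theta))
  params
}

sim_mvn <- function(tree, painting, pp, m) {
  n <- ape::Ntip(tree)
  if (pp$family == "BM1") {
    E <- rep(pp$x0, n)
    V <- bm_covariance(tree, pp$sigma2)
  } else {
    hist <- lineage_histories(tree, painting)
    E <- ou_expectation(hist, pp$alpha, pp$theta, pp$x0)[tree$tip.label]
    V <- ou_covariance(tree, pp$alpha, pp$sigma2)
  }
  Z <- matrix(rnorm(m * n), m, n)
  sweep(Z %*% chol(V), 2, E, "+")
}

sim_recursive <- function(tree, painting, pp, m) {
  n <- ape::Ntip(tree)
  nnode <- max(tree$edge)
  pt <- as.data.frame(painting)
  state <- matrix(NA_real_, m, nnode)
  x_root <- rep(pp$x0, m)
  re <- root_edge_length(tree)
  if (re > 0) {   # evolve along the retained basal path first
    if (pp$family == "BM1") {
      x_root <- x_root + rnorm(m, 0, sqrt(pp$sigma2 * re))
    } else {
      th <- pp$theta[[attr(painting, "background")]]
      vv <- pp$sigma2 / (2 * pp$alpha) * (1 - exp(-2 * pp$alpha * re))
      x_root <- th + (x_root - th) * exp(-pp$alpha * re) + rnorm(m, 0, sqrt(vv))
    }
  }
  state[, n + 1L] <- x_root
  # preorder: parents always precede children in ape's cladewise edge order
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; chl <- ord$edge[e, 2]
    eid <- which(tree$edge[, 1] == par & tree$edge[, 2] == chl)
    xs <- state[, par]
    if (pp$family == "BM1") {
      dt <- tree$edge.length[eid]
      xs <- xs + rnorm(m, 0, sqrt(pp$sigma2 * dt))
    } else {
      seg <- pt[pt$edge == eid, ]
      seg <- seg[order(seg$start), ]
      for (s in seq_len(nrow(seg))) {
        dt <- seg$end[s] - seg$start[s]
        th <- pp$theta[[seg$regime[s]]]
        decay <- exp(-pp$alpha * dt)
        vv <- pp$sigma2 / (2 * pp$alpha) * (1 - exp(-2 * pp$alpha * dt))
        xs <- th + (xs - th) * decay + rnorm(m, 0, sqrt(vv))
      }
    }
    state[, chl] <- xs
  }
  state[, seq_len(n), drop = FALSE]
}

#' @export
print.sim_batch <- function(x, ...) {
  cat("sim_batch: ", nrow(x$data), " dataset(s) x ", ncol(x$data),
      " tips under ", x$params$family, " (seed ", x$seed, ", ", x$method,
      ")\n", sep = "")
  invisible(x)
}

#' Write a simulation batch as a wide table
#'
#' @param batch A `sim_batch`.
#' @param path Output file (comma-separated; `dataset_id` then one column
#'   per species).
#' @return The path, invisibly.
#' @export
write_sim_batch <- function(batch, path) {
  tab <- tibble::as_tibble(batch$data)
  tab <- dplyr::bind_cols(tibble::tibble(dataset_id = seq_len(nrow(tab))), tab)
  readr::write_csv(tab, path)
  invisible(path)
}

#' Read a simulation batch written by [write_sim_batch()]
#'
#' @param path File to read.
#' @return Matrix of datasets by species.
#' @export
read_sim_batch <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  as.matrix(tab[setdiff(names(tab), "dataset_id")])
}
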