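# Shared fixtures and independent oracles.  The oracles deliberately avoid
# the package's closed-form code paths: expectations and covariances are
# built by numerical integration of the OU kernel along root-to-tip paths,
# and the Gaussian density is evaluated through determinant/solve instead of
# a Cholesky factorization.

tri_tree <- function() read_time_tree("((A:1,B:1):1,C:2);")

# random ultrametric tree via coalescent, rescaled to a given depth
rand_tree <- function(n, depth = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length * depth / max(node_heights(tr))
  tr
}

# random painting: each of up to two random non-nested clades gets a regime
rand_painting <- function(tree) {
  n <- ape::Ntip(tree)
  clades <- list()
  tips1 <- tree$tip.label[sort(sample.int(n, sample(1:max(1, n %/% 2), 1)))]
  mr <- if (length(tips1) == 1) match(tips1, tree$tip.label) else
    ape::getMRCA(tree, tips1)
  if (mr != n + 1)
    clades <- list(regime_clade(tips1, "r1", include_stem = runif(1) < 0.5))
  tryCatch(paint_regimes(tree, clades, background = "bg"),
           error = function(e) paint_regimes(tree, list(), background = "bg"))
}

# E_i by numerical integration of alpha * theta(t) * exp(-alpha (T_i - t)),
# one quadrature per regime segment (the integrand kinks at the boundaries)
oracle_expectation <- function(histories, alpha, theta, x0) {
  tips <- unique(histories$tip)
  vapply(tips, function(tp) {
    h <- histories[histories$tip == tp, ]
    Ti <- max(h$t_end)
    ig <- sum(vapply(seq_len(nrow(h)), function(s)
      integrate(function(t) alpha * theta[[h$regime[s]]] *
                  exp(-alpha * (Ti - t)),
                h$t_start[s], h$t_end[s], subdivisions = 1000L,
                rel.tol = 1e-12)$value, 0))
    x0 * exp(-alpha * Ti) + ig
  }, 0)
}

# V_ij by numerical integration of the OU kernel over the shared path
oracle_covariance <- function(tree, alpha, sigma2) {
  n <- ape::Ntip(tree)
  hh <- node_heights(tree)
  depths <- hh[seq_len(n)]
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ta <- if (i == j) depths[i] else hh[ape::getMRCA(tree, c(i, j))]
    if (ta == 0) { V[i, j] <- 0; next }
    V[i, j] <- integrate(function(s)
      sigma2 * exp(-alpha * (depths[i] - s)) * exp(-alpha * (depths[j] - s)),
      0, ta, subdivisions = 2000L, rel.tol = 1e-12)$value
  }
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  V
}

# multivariate-normal log-density via determinant/solve (no Cholesky)
oracle_loglik <- function(x, E, V) {
  n <- length(x)
  r <- x - E
  as.numeric(-n / 2 * log(2 * pi) - 0.5 * determinant(V)$modulus -
               0.5 * t(r) %*% solve(V, r))
}

# random OU parameters on a scale matched to a depth-`depth` tree
rand_ou_params <- function(painting, depth) {
  regs <- attr(painting, "regimes")
  list(family = "OU", alpha = exp(runif(1, log(0.2 / depth), log(20 / depth))),
       sigma2 = exp(runif(1, log(0.01), log(1))),
       theta = setNames(rnorm(length(regs)), regs), x0 = rnorm(1))
}

# package lnL for given data/params through the public building blocks
package_loglik <- function(tree, painting, pp, x) {
  hist <- lineage_histories(tree, painting)
  E <- ou_expectation(hist, pp$alpha, pp$theta, pp$x0)[tree$tip.label]
  V <- ou_covariance(tree, pp$alpha, pp$sigma2)
  loglik(x, E, V)
}

# small synthetic study reused by the heavier integration tests
small_study <- function(seed = 1, configs = list(trait_config()), ...) {
  synthetic_study(n_bg = 28, n_cladeA = 14, n_cladeB = 6, depth = 70,
                  configs = configs, seed = seed, ...)
}
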