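test_that("OU expectations match their closed forms", {
  h1 <- tibble::tibble(tip = "x", t_start = 0, t_end = 1, regime = "a")
  expect_equal(unname(ou_expectation(h1, log(2), c(a = 1), 0)), 0.5,
               tolerance = 1e-10)

  h2 <- tibble::tibble(tip = "x", t_start = c(0, 0.5), t_end = c(0.5, 1),
                       regime = c("a", "b"))
  expect_equal(unname(ou_expectation(h2, log(2), c(a = 0, b = 1), 0)),
               1 - 2^(-1 / 2), tolerance = 1e-10)

  # strong pull: the optimum dominates the root state
  expect_lt(abs(unname(ou_expectation(h1, 50, c(a = 1), 3)) - 1), 1e-20)

  expect_error(ou_expectation(h2, log(2), c(a = 0), 0), "without an optimum")
})

test_that("OU and BM covariances match their closed forms", {
  tr <- read_time_tree("((A:0.5,B:0.5):0.5);")
  V <- ou_covariance(tr, log(2), 2 * log(2))
  expect_equal(unname(diag(V)), c(0.75, 0.75), tolerance = 1e-10)
  expect_equal(V[1, 2], 0.25, tolerance = 1e-10)

  star <- read_time_tree("(A:1,B:1,C:1);")
  Vs <- ou_covariance(star, 1, 1)
  expect_true(all(Vs[upper.tri(Vs)] == 0))
  expect_equal(bm_covariance(star, 2), diag(2, 3), ignore_attr = TRUE)

  tr3 <- tri_tree()
  Vb <- bm_covariance(tr3, 1)
  expect_equal(Vb["A", "B"], 1)
  expect_equal(Vb["A", "C"], 0)
  expect_equal(unname(diag(Vb)), c(2, 2, 2))
})

test_that("log-likelihood matches the textbook density and scales quadratically", {
  expect_equal(loglik(0, 0, matrix(1)), -0.5 * log(2 * pi), tolerance = 1e-12)

  set.seed(31)
  tr <- rand_tree(5, depth = 2)
  V <- ou_covariance(tr, 0.8, 0.5)
  E <- rnorm(5)
  x <- rnorm(5)
  expect_equal(loglik(x, E, V), oracle_loglik(x, E, V), tolerance = 1e-10)

  # scaling the deviation by c changes the quadratic term by c^2
  q <- function(c) loglik(E + c * (x - E), E, V) + 5 / 2 * log(2 * pi) +
    0.5 * determinant(V)$modulus[1]
  expect_equal(q(2) / q(1), 4, tolerance = 1e-8)

  expect_error(loglik(c(0, 0), c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "smallest eigenvalue")
})

test_that("package lnL agrees with numerical-integration oracles on random instances", {
  set.seed(17)
  for (i in 1:50) {
    tr <- rand_tree(sample(3:6, 1), depth = runif(1, 0.5, 10))
    p <- rand_painting(tr)
    pp <- rand_ou_params(p, max(node_heights(tr)))
    x <- rnorm(ape::Ntip(tr))
    hist <- lineage_histories(tr, p)
    E_o <- oracle_expectation(hist, pp$alpha, pp$theta, pp$x0)[tr$tip.label]
    V_o <- oracle_covariance(tr, pp$alpha, pp$sigma2)
    expect_equal(package_loglik(tr, p, pp, x), oracle_loglik(x, E_o, V_o),
                 tolerance = 1e-8)
  }
})

test_that("OU collapses to BM in the weak-pull limit", {
  set.seed(23)
  for (i in 1:10) {
    tr <- rand_tree(sample(4:8, 1), depth = runif(1, 1, 5))
    n <- ape::Ntip(tr)
    p <- paint_regimes(tr, list(), background = "bg")
    x <- rnorm(n)
    x0 <- rnorm(1)
    sigma2 <- runif(1, 0.1, 2)
    l_ou <- package_loglik(tr, p, list(alpha = 1e-9, sigma2 = sigma2,
                                       theta = c(bg = x0), x0 = x0), x)
    l_bm <- loglik(x, rep(x0, n), bm_covariance(tr, sigma2))
    expect_lt(abs(l_ou - l_bm), 1e-4)
  }
})

test_that("SIC and half-life follow their definitions", {
  expect_equal(sic(10, 3, 125), -20 + 3 * log(125), tolerance = 1e-12)
  expect_equal(sic(10, 4, 125) - sic(10, 3, 125), log(125))
  expect_error(sic(10, 0, 125))
  expect_equal(half_life(log(2)), 1.0)
  expect_equal(half_life(log(2) / 9.5), 9.5)
  a <- sort(runif(10, 0.01, 5))
  expect_true(all(diff(half_life(a)) < 0))
  expect_error(half_life(0), "alpha")
})

test_that("BM fitting recovers the closed-form ML solution on a star tree", {
  star <- read_time_tree("(A:1,B:1);")
  p <- paint_regimes(star, list(), background = "bg")
  fit <- fit_model(star, p, c(A = 1, B = 3), model_spec("BM1", "BM1"))
  expect_equal(fit$x0, 2, tolerance = 1e-10)
  expect_equal(fit$sigma2, 1, tolerance = 1e-10)  # ML divide-by-n
  expect_equal(fit$p, 2)
  expect_equal(fit$sic, sic(fit$lnL, 2, 2))
})

test_that("profiled GLS optima equal jointly optimized optima", {
  set.seed(41)
  tr <- rand_tree(8, depth = 3)
  p <- paint_regimes(tr, list(regime_clade(tr$tip.label[1:3], "derived")),
                     background = "bg")
  pp <- list(family = "OU", alpha = 0.7, sigma2 = 0.3,
             theta = c(bg = 0, derived = 1), x0 = 0)
  x <- drop(simulate_traits(tr, p, pp, 1, seed = 5)$data)
  spec <- model_spec("OU2", "OU",
                     optima_map = c(bg = 1L, derived = 2L),
                     optima_names = c("bg", "derived"))
  fit <- fit_model(tr, p, x, spec)

  # independent route: joint Nelder-Mead over (log alpha, log sigma2, theta)
  hist <- lineage_histories(tr, p)
  nll <- function(par) {
    a <- exp(par[1]); s2 <- exp(par[2])
    th <- c(bg = par[3], derived = par[4])
    E <- ou_expectation(hist, a, th, par[3])[tr$tip.label]
    -loglik(x, E, ou_covariance(tr, a, s2))
  }
  jo <- optim(c(log(fit$alpha), log(fit$sigma2), fit$theta[["bg"]],
                fit$theta[["derived"]]) + 0.05,
              nll, control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(unname(fit$theta), unname(jo$par[3:4]), tolerance = 1e-4)
  expect_gte(fit$lnL + 1e-6, -jo$value)
})

test_that("the fitted lnL never falls below the generating-parameter lnL", {
  set.seed(53)
  st <- small_study(seed = 2)
  spec <- hypothesis_models()$OU2_shared
  pp <- ouhomoplasy:::config_params(st$configs[[1]], 70)
  X <- simulate_traits(st$tree, st$painting, pp, 20, seed = 9)$data
  for (j in 1:20) {
    fit <- fit_model(st$tree, st$painting, X[j, ], spec)
    l_true <- package_loglik(st$tree, st$painting, pp, as.numeric(X[j, ]))
    expect_gte(fit$lnL, l_true - 1e-6)
  }
})

test_that("OU covariances stay positive definite across the parameter box", {
  set.seed(61)
  trees <- list(rand_tree(20, 5), rand_tree(100, 50), rand_tree(200, 80))
  for (tr in trees)
    for (a in c(1e-6, 0.01, 1, 100))
      for (s2 in c(1e-6, 0.1, 10))
        expect_silent(chol(ou_covariance(tr, a, s2)))
})

test_that("fits serialize to JSON and tidy into parameter tables", {
  st <- small_study(seed = 3)
  fit <- fit_model(st$tree, st$painting, st$residuals[, 1],
                   hypothesis_models()$OU2_shared)
  td <- tidy(fit)
  expect_setequal(td$term, c("alpha", "sigma2", "theta[background]",
                             "theta[derived]"))
  gl <- glance(fit)
  expect_equal(gl$SIC, fit$sic)
  expect_equal(gl$t_half, log(2) / fit$alpha)
  js <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(js$lnL, fit$lnL, tolerance = 1e-12)
  expect_equal(js$parameters$alpha, fit$alpha, tolerance = 1e-12)

  # free-X0 policy adds one (redundant-on-ultrametric-trees) parameter;
  # the achievable maximum lnL is unchanged
  spec_free <- hypothesis_models(root_policy = "free")$OU2_shared
  fit_free <- fit_model(st$tree, st$painting, st$residuals[, 1], spec_free)
  expect_equal(fit_free$p, 5)
  expect_equal(fit_free$lnL, fit$lnL, tolerance = 1e-4)
})
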