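test_that("the likelihood ratio statistic is twice the lnL difference", {
  f1 <- structure(list(lnL = -50), class = "ou_fit")
  f2 <- structure(list(lnL = -53), class = "ou_fit")
  expect_equal(likelihood_ratio(f1, f2), 6)
  expect_equal(likelihood_ratio(f1, f1), 0)
})

test_that("delta classification covers all four branches, boundaries inside", {
  expect_equal(classify_delta(1, c(0, 2), c(5, 8)), "focal_favored")
  expect_equal(classify_delta(6, c(0, 2), c(5, 8)), "alternative_favored")
  expect_equal(classify_delta(1.5, c(0, 2), c(1, 8)), "both_plausible")
  expect_equal(classify_delta(10, c(0, 2), c(5, 8)), "both_implausible")
  expect_equal(classify_delta(2, c(0, 2), c(5, 8)), "focal_favored")
  expect_equal(classify_delta(5, c(0, 2), c(5, 8)), "alternative_favored")
})

test_that("nested models never lose likelihood to their special case", {
  st <- small_study(seed = 12)
  models <- hypothesis_models()
  X <- simulate_traits(st$tree, st$painting,
                       ouhomoplasy:::config_params(st$configs[[1]], 70),
                       10, seed = 3)$data
  for (j in 1:10) {
    f2 <- fit_model(st$tree, st$painting, X[j, ], models$OU2_shared)
    f3 <- fit_model(st$tree, st$painting, X[j, ], models$OU3)
    f1 <- fit_model(st$tree, st$painting, X[j, ], models$OU1)
    expect_gte(likelihood_ratio(f3, f2), -2e-6)   # OU3 nests OU2_shared
    expect_gte(likelihood_ratio(f2, f1), -2e-6)   # OU2_shared nests OU1
  }
})

test_that("pmc comparison is self-consistent and reproducible", {
  st <- small_study(seed = 13)
  models <- hypothesis_models()
  r <- pmc_compare(st$tree, st$painting, st$residuals[, 1],
                   models$OU2_shared, models$BM1, n_sim = 120, seed = 21)
  expect_equal(r$delta_emp,
               2 * (r$fit_focal$lnL - r$fit_alt$lnL), tolerance = 1e-12)
  expect_length(r$dist_focal, 120)
  expect_length(r$dist_alt, 120)
  expect_equal(r$ci_focal,
               unname(quantile(r$dist_focal, c(0.025, 0.975))),
               tolerance = 1e-12)
  expect_equal(r$classification,
               classify_delta(r$delta_emp, r$ci_focal, r$ci_alt))
  expect_equal(unname(r$dropped), c(0, 0))

  r2 <- pmc_compare(st$tree, st$painting, st$residuals[, 1],
                    models$OU2_shared, models$BM1, n_sim = 120, seed = 21)
  expect_identical(r$dist_focal, r2$dist_focal)
  expect_identical(r$classification, r2$classification)

  expect_s3_class(autoplot(r), "ggplot")
  gl <- glance(r)
  expect_equal(gl$classification, r$classification)
})

test_that("a strong homoplasy signal is discriminated from the single-optimum model", {
  st <- small_study(seed = 14)
  models <- hypothesis_models()
  r <- pmc_compare(st$tree, st$painting, st$residuals[, 1],
                   models$OU2_shared, models$OU1, n_sim = 150, seed = 5)
  expect_equal(r$classification, "focal_favored")
})

test_that("bootstrap parameter CIs flag estimates inside their own distribution", {
  st <- small_study(seed = 15)
  models <- hypothesis_models()
  r <- pmc_compare(st$tree, st$painting, st$residuals[, 1],
                   models$OU2_shared, models$BM1, n_sim = 150, seed = 9)
  cis <- parameter_cis(r$refits_focal, r$fit_focal)
  expect_setequal(cis$parameter, c("alpha", "sigma2", "theta[background]",
                                   "theta[derived]"))
  expect_true(all(cis$ci_lo <= cis$ci_hi))
  th <- cis[cis$parameter == "theta[derived]", ]
  expect_true(th$reliable)    # the optimum of the large derived regime

  # an estimate placed at the median of its own bootstrap sample is reliable
  refits <- tibble::tibble(alpha = rexp(200), sigma2 = rexp(200))
  fake <- structure(list(
    spec = list(name = "OU1", family = "OU", root_policy = "root_regime",
                k = 0L),
    alpha = median(refits$alpha), sigma2 = median(refits$sigma2),
    theta = setNames(numeric(0), character(0))), class = "ou_fit")
  cc <- parameter_cis(refits, fake)
  expect_true(all(cc$reliable))

  expect_error(parameter_cis(refits[1:50, ], fake), "at least 100")
})
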