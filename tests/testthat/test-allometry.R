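make_traits <- function(sp, values, trait = "tr") {
  tibble::tibble(species = sp, specimen = 1L, trait = trait, value = values)
}

test_that("an exact allometric line yields exact coefficients and zero residuals", {
  sp <- paste0("s", 1:10)
  mass <- setNames(seq(2, 6, length.out = 10), sp)
  tt <- make_traits(sp, 1 + 2 * mass)
  fit <- fit_allometry(tt, mass, "tr", n_perm = 0)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_true(all(abs(fit$residuals) < 1e-10))
  expect_equal(fit$r_squared, 1)
})

test_that("a mass-independent trait gives a near-zero slope and centred residuals", {
  set.seed(3)
  sp <- paste0("s", 1:100)
  mass <- setNames(rnorm(100, 5, 1), sp)
  y <- rnorm(100)
  fit <- fit_allometry(make_traits(sp, y), mass, "tr", n_perm = 0)
  expect_lt(abs(fit$slope), 0.3)          # within ~3 SEs of zero
  # residuals approximately equal the directly centred trait
  centred <- y - mean(y)
  r <- unname(fit$residuals[sp])          # residuals are named by species
  expect_gt(cor(r, centred), 0.95)
  expect_lt(mean((r - centred)^2) / var(y), 0.05)
})

test_that("OLS normal equations hold on random inputs", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    sp <- paste0("s", seq_len(n))
    mass <- setNames(rnorm(n, 5), sp)
    y <- 0.5 + 0.3 * mass + rnorm(n, 0, 0.3)
    fit <- fit_allometry(make_traits(sp, y), mass, "tr", n_perm = 0)
    expect_lt(abs(sum(fit$residuals)), 1e-9)
    expect_lt(abs(sum(fit$residuals * mass[names(fit$residuals)])), 1e-9)
  }
})

test_that("the permutation test flags a strong allometry and leaves residuals alone", {
  set.seed(5)
  sp <- paste0("s", 1:100)
  mass <- setNames(rnorm(100, 5, 1), sp)
  y <- 1 + 0.8 * mass + rnorm(100, 0, 0.1)
  tt <- make_traits(sp, y)
  f1 <- fit_allometry(tt, mass, "tr", n_perm = 10000, seed = 11)
  expect_lte(f1$p_value, 0.001)
  f2 <- fit_allometry(tt, mass, "tr", n_perm = 100, seed = 12)
  expect_equal(f1$residuals, f2$residuals, tolerance = 1e-12)
  f3 <- fit_allometry(tt, mass, "tr", n_perm = 0)
  expect_true(is.na(f3$p_value))
  expect_equal(f1$residuals, f3$residuals, tolerance = 1e-12)
})

test_that("degenerate inputs error clearly", {
  sp <- paste0("s", 1:5)
  mass <- setNames(rep(3, 5), sp)
  expect_error(fit_allometry(make_traits(sp, rnorm(5)), mass, "tr"),
               "zero variance")
  expect_error(fit_allometry(make_traits(sp, rnorm(5)), mass, "other"),
               "no rows")
  m2 <- setNames(c(1, 2), sp[1:2])
  expect_error(fit_allometry(make_traits(sp, rnorm(5)), m2, "tr"),
               ">= 3 species")
})

test_that("regression runs on the full set; pruning afterwards differs from pruning first", {
  set.seed(21)
  sp <- paste0("s", 1:40)
  mass <- setNames(c(rnorm(30, 4, 0.5), rnorm(10, 8, 0.5)), sp)
  y <- 1 + 0.4 * mass + rnorm(40, 0, 0.2)
  tt <- make_traits(sp, y)
  keep <- sp[1:30]     # drop the heavy species after regression
  full_fit <- fit_allometry(tt, mass, "tr", n_perm = 0)
  after <- residual_matrix(list(full_fit), keep)[, 1]
  pruned_fit <- fit_allometry(tt[tt$species %in% keep, ], mass[keep], "tr",
                              n_perm = 0)
  before <- pruned_fit$residuals[keep]
  expect_gt(max(abs(after - before)), 1e-6)   # the orderings are not equivalent
})

test_that("residual matrices respect species order and report gaps", {
  sp <- paste0("s", 1:8)
  mass <- setNames(rnorm(8, 5), sp)
  t1 <- make_traits(sp, 1 + 0.2 * mass + rnorm(8, 0, 0.1), "t1")
  t2 <- make_traits(sp[1:6], rnorm(6, 2), "t2")
  f1 <- fit_allometry(t1, mass, "t1", n_perm = 0)
  f2 <- fit_allometry(dplyr::bind_rows(t1, t2), mass, "t2", n_perm = 0)
  m <- residual_matrix(list(f1), rev(sp))
  expect_equal(rownames(m), rev(sp))
  expect_equal(colnames(m), "t1")
  expect_error(residual_matrix(list(f1, f2), sp), "s7/t2|s8/t2")
})

test_that("specimen SDs pool across species with replicates", {
  tt <- tibble::tibble(species = rep(c("a", "b", "c"), c(3, 2, 1)),
                       specimen = c(1:3, 1:2, 1),
                       trait = "tr",
                       value = c(1, 2, 3, 5, 7, 9))
  # pooled within-species variance: (sum sq dev) / (df) = (2 + 2) / 3
  expect_equal(pooled_specimen_sd(tt, "tr"), sqrt((2 + 2) / 3))
  one <- tibble::tibble(species = "a", specimen = 1, trait = "tr", value = 1)
  expect_equal(pooled_specimen_sd(one, "tr"), 0)
})

test_that("trait and mass tables round-trip through delimited files", {
  tt <- tibble::tibble(species = c("a", "b", "c"), specimen = 1L,
                       trait = "tr", value = c(1.5, 2.5, 3.5))
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tt, f)
  back <- read_trait_table(f)
  expect_equal(back$value, tt$value)

  fm <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(species = c("a", "b"),
                                  mass_g = c(100, 1000)), fm)
  m <- read_mass_table(fm)
  expect_equal(unname(m), log(c(100, 1000)))
})

test_that("the shipped example study loads through the file readers", {
  ext <- system.file("extdata", package = "ouhomoplasy")
  tree <- read_time_tree(file.path(ext, "example_tree.nwk"))
  traits <- read_trait_table(file.path(ext, "example_traits.csv"))
  mass <- read_mass_table(file.path(ext, "example_mass.csv"))
  grp <- readr::read_csv(file.path(ext, "example_groups.csv"),
                         show_col_types = FALSE)
  expect_setequal(tree$tip.label, grp$species)
  expect_true(all(traits$species %in% names(mass)))
  fit <- fit_allometry(traits, mass, "scapula_EL", n_perm = 0)
  expect_equal(fit$n, ape::Ntip(tree))
  expect_gt(fit$slope, 0)       # generated with a positive allometric slope
})
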