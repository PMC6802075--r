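test_that("Newick reading validates structure and reports depth", {
  tree <- read_time_tree("((A:1,B:1):1,C:2);")
  info <- validate_time_tree(tree)
  expect_equal(info$n_tips, 3)
  expect_equal(info$depth, 2)
  expect_equal(info$depth_spread, 0)

  expect_warning(read_time_tree("((A:1,B:1):1,C:3);"), "not ultrametric")
  tree2 <- suppressWarnings(read_time_tree("((A:1,B:1):1,C:3);"))
  expect_equal(suppressWarnings(validate_time_tree(tree2))$depth_spread, 1.0)

  expect_error(read_time_tree("((A:1,A:1):1,C:2);"), "duplicate tip")
  expect_error(read_time_tree("((A:1,B:1):1"), "malformed|tree file")
  expect_error(read_time_tree("/no/such/file.nwk"), "tree file")
})

test_that("pruning preserves root-to-tip distances and is idempotent", {
  tree <- tri_tree()
  pr <- prune_tree(tree, c("A", "B"))
  expect_equal(sort(pr$tip.label), c("A", "B"))
  expect_equal(unname(node_heights(pr)[seq_len(2)]), c(2, 2))

  expect_identical(prune_tree(tree, tree$tip.label), tree)
  expect_error(prune_tree(tree, c("A", "Z")), "unknown tip name")

  set.seed(42)
  for (i in 1:20) {
    tr <- rand_tree(sample(6:20, 1), depth = runif(1, 1, 50))
    keep <- sample(tr$tip.label, sample(3:5, 1))
    d0 <- node_heights(tr)[match(keep, tr$tip.label)]
    p1 <- prune_tree(tr, keep)
    p2 <- prune_tree(p1, keep)
    expect_equal(ape::write.tree(p1), ape::write.tree(p2))
    expect_equal(node_heights(p1)[match(keep, p1$tip.label)], d0,
                 tolerance = 1e-12)
  }
})

test_that("painting covers the tree and honours stem placement", {
  tree <- tri_tree()
  p <- paint_regimes(tree, list(regime_clade(c("A", "B"), "foss")),
                     background = "arb")
  # stem branch of {A,B} plus both tip branches are foss, C stays background
  foss_edges <- p$edge[p$regime == "foss"]
  expect_length(foss_edges, 3)
  expect_equal(p$regime[p$child == match("C", tree$tip.label)], "arb")
  expect_silent(validate_painting(tree, p))

  p_nostem <- paint_regimes(tree,
                            list(regime_clade(c("A", "B"), "foss",
                                              include_stem = FALSE)),
                            background = "arb")
  expect_length(p_nostem$edge[p_nostem$regime == "foss"], 2)

  expect_error(paint_regimes(tree, list(regime_clade("Z", "x"))),
               "unknown tip")
  expect_error(
    paint_regimes(tree, list(regime_clade(c("A", "B"), "r1"),
                             regime_clade("A", "r2"))),
    "overlapping|nested")
})

test_that("painted segment lengths conserve total tree length", {
  set.seed(7)
  for (i in 1:40) {
    tr <- rand_tree(sample(5:30, 1), depth = runif(1, 1, 100))
    p <- rand_painting(tr)
    expect_lt(abs(sum(p$end - p$start) - sum(tr$edge.length)), 1e-12 *
                max(1, sum(tr$edge.length)))
  }
})

test_that("lineage histories partition each root-to-tip path", {
  tree <- tri_tree()
  p0 <- paint_regimes(tree, list(), background = "bg")
  h0 <- lineage_histories(tree, p0)
  expect_equal(nrow(h0), 3)           # one segment per tip under uniform paint
  expect_true(all(h0$t_start == 0))

  p <- paint_regimes(tree, list(regime_clade(c("A", "B"), "foss",
                                              include_stem = FALSE)),
                     background = "bg")
  h <- lineage_histories(tree, p)
  hA <- h[h$tip == "A", ]
  expect_equal(hA$t_start, c(0, 1))
  expect_equal(hA$t_end, c(1, 2))
  expect_equal(hA$regime, c("bg", "foss"))

  set.seed(11)
  for (i in 1:500) {
    tr <- rand_tree(sample(4:12, 1), depth = runif(1, 0.5, 20))
    pp <- rand_painting(tr)
    hh <- lineage_histories(tr, pp)
    depths <- node_heights(tr)[seq_along(tr$tip.label)]
    for (tp in tr$tip.label) {
      seg <- hh[hh$tip == tp, ]
      expect_equal(seg$t_start[1], 0)
      expect_equal(seg$t_end[nrow(seg)], depths[match(tp, tr$tip.label)],
                   tolerance = 1e-10)
      if (nrow(seg) > 1)
        expect_equal(seg$t_start[-1], seg$t_end[-nrow(seg)],
                     tolerance = 1e-10)
    }
  }
})

test_that("stem ages are measured back from the present", {
  tree <- tri_tree()
  expect_equal(stem_age(tree, c("A", "B")), 2.0)
  expect_equal(stem_age(tree, "C"), 2.0)    # C's parent is the root
  expect_equal(stem_age(tree, "A"), 1.0)
  expect_error(stem_age(tree, c("A", "B", "C")), "no stem")
})

test_that("painting round-trips through the sidecar table and SIMMAP export", {
  tree <- tri_tree()
  p <- paint_regimes(tree, list(regime_clade(c("A", "B"), "foss")),
                     background = "arb")
  f <- withr::local_tempfile(fileext = ".csv")
  write_painting(p, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(back$regime, p$regime)
  expect_equal(back$end - back$start, p$end - p$start)

  smap <- write_simmap(tree, p)
  expect_match(smap, "\\{foss,1\\}")
  expect_match(smap, "\\{arb,2\\}")
})
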