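test_that("outlier flags follow the directional 1.96 rule strictly", {
  mods <- default_modalities()
  duf <- rbind(c(-2.0, +2.0, +3.0, -1.96, 1.96, -1.97))
  colnames(duf) <- c("Left-Hippocampus", "MD_ATR_L", "lh_cuneus",
                     "Right-Hippocampus", "MD_ATR_R", "FA_ATR_L")
  fl <- flag_outliers(duf, mods)
  expect_true(fl[, "Left-Hippocampus"])   # T1 below -1.96
  expect_true(fl[, "MD_ATR_L"])           # MD above +1.96
  expect_false(fl[, "lh_cuneus"])         # wrong direction for T1
  expect_false(fl[, "Right-Hippocampus"]) # boundary is not an outlier
  expect_false(fl[, "MD_ATR_R"])          # boundary is not an outlier
  expect_true(fl[, "FA_ATR_L"])           # FA below -1.96

  bad <- duf; colnames(bad)[1] <- "unknown_region"
  expect_error(flag_outliers(bad, mods), "without a modality spec")
})

test_that("outlier proportions count flags per region", {
  flags <- matrix(FALSE, 10, 2, dimnames = list(NULL, c("a", "b")))
  flags[1:3, 1] <- TRUE
  om <- outlier_proportions(flags, stratum = "s")
  expect_equal(om$proportion, c(0.3, 0))
  expect_equal(om$n, c(10, 10))
  expect_error(outlier_proportions(flags[0, , drop = FALSE]), "empty")
})

test_that("network rates count each subject once per network", {
  parc <- c(r1 = "limbic", r2 = "limbic", r3 = "limbic", r4 = "visual")
  flags <- matrix(FALSE, 4, 4, dimnames = list(NULL, names(parc)))
  flags[1, 1:3] <- TRUE      # 3 limbic regions, one subject
  flags[2, 4] <- TRUE        # visual only
  nr <- network_outlier_rate(flags, parc)
  expect_equal(nr$rate[nr$network == "limbic"], 1 / 4)
  expect_equal(nr$rate[nr$network == "visual"], 1 / 4)

  all_f <- flags; all_f[] <- TRUE
  expect_true(all(network_outlier_rate(all_f, parc)$rate == 1))
  none <- flags; none[] <- FALSE
  expect_true(all(network_outlier_rate(none, parc)$rate == 0))

  # a network's rate is at least any single member region's proportion
  set.seed(8)
  rnd <- matrix(runif(400) < 0.2, 100, 4, dimnames = list(NULL, names(parc)))
  nr2 <- network_outlier_rate(rnd, parc)
  expect_gte(nr2$rate[nr2$network == "limbic"], max(colMeans(rnd[, 1:3])))
})

test_that("permutation p-values hit the stated extremes", {
  parc <- c(r1 = "limbic", r2 = "visual")
  n_perm <- 999
  # cases maximally flagged, controls never: observed beats every null draw
  cases <- matrix(TRUE, 5, 2, dimnames = list(NULL, names(parc)))
  ctrl <- matrix(FALSE, 200, 2, dimnames = list(NULL, names(parc)))
  pt <- permutation_test(cases, ctrl, parc, n_perm = n_perm, seed = 4)
  expect_equal(pt$network$p, rep(1 / (n_perm + 1), 2))

  # observed rate of zero is never exceeded: p = 1 exactly
  pt2 <- permutation_test(ctrl[1:5, ], cases, parc, n_perm = n_perm,
                          seed = 4)
  expect_equal(pt2$network$p, rep(1, 2))

  expect_error(permutation_test(cases[0, , drop = FALSE], ctrl, parc),
               "non-empty")
  expect_warning(permutation_test(cases, ctrl, parc, n_perm = 50, seed = 1),
                 "n_perm")
})

test_that("region-level p-values share the permutation draws coherently", {
  set.seed(5)
  parc <- c(r1 = "limbic", r2 = "limbic")
  flags <- matrix(runif(600) < 0.1, 300, 2, dimnames = list(NULL, names(parc)))
  pt <- permutation_test(flags[1:100, ], flags[101:300, ], parc,
                         n_perm = 500, seed = 6, regions = TRUE)
  expect_identical(pt$region$feature, names(parc))
  expect_true(all(pt$region$p >= 1 / 501 & pt$region$p <= 1))
  expect_equal(pt$region$observed_proportion,
               unname(colMeans(flags[1:100, ])))
})

test_that("null permutation p-values are super-uniform", {
  set.seed(99)
  parc <- stats::setNames(rep(c("limbic", "visual", "default"), each = 4),
                          paste0("r", 1:12))
  ps <- replicate(150, {
    fl <- matrix(rnorm(150 * 12), 150, 12,
                 dimnames = list(NULL, names(parc))) < -1.96
    permutation_test(fl[1:50, ], fl[51:150, ], parc, n_perm = 400,
                     seed = sample.int(1e6, 1))$network$p
  })
  for (a in c(0.01, 0.05, 0.1, 0.25)) {
    # super-uniformity with three-sigma Monte-Carlo slack
    slack <- 3 * sqrt(a * (1 - a) / length(ps))
    expect_lte(mean(ps <= a), a + slack)
  }
})

test_that("fdr_correct matches the Benjamini-Hochberg step-up oracle", {
  expect_equal(fdr_correct(0.03), 0.03)                     # single p
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))                                # hand-derived
  expect_equal(fdr_correct(rep(1, 5)), rep(1, 5))
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))^2
    expect_equal(fdr_correct(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
})

test_that("stronger shifts never reduce affected-region outlier rates", {
  # composition of the z-scoring + directional rule on shifted normals
  set.seed(21)
  mods <- list(T1 = modality_spec("T1", "roi"))
  rates <- vapply(seq(0, 2, by = 0.5), function(shift) {
    duf <- matrix(rnorm(20000, mean = -shift), ncol = 1,
                  dimnames = list(NULL, "roi"))
    mean(flag_outliers(duf, mods))
  }, 0)
  expect_true(all(diff(rates) > 0))
})
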