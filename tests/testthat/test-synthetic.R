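test_that("seeded generation is deterministic and obeys cohort invariants", {
  cfg <- tiny_cfg()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  # one row per subject-visit, no missing feature values
  expect_false(anyDuplicated(a[, c("subject_id", "visit")]) > 0)
  feats <- feature_names(tiny_mods())
  expect_false(anyNA(a[, feats]))

  # super-healthy target-site controls: MMSE > 28, CDR = 0, no e4 alleles
  sh <- a$cohort_label %in% c("finetune", "holdout")
  expect_true(all(a$mmse[sh] > 28))
  expect_true(all(a$cdr[sh] == 0))
  expect_true(all(a$apoe_e4_count[sh] == 0))

  # follow-up visits only where declared, ages advance by one year
  expect_setequal(unique(a$cohort_label[a$visit == 1]),
                  c("holdout", "at_risk"))
  one <- a[a$subject_id == a$subject_id[a$visit == 1][1], ]
  expect_equal(diff(one$age), 1)

  # a different seed changes the data
  cfg2 <- tiny_cfg(seed = 202L)
  expect_false(identical(generate_cohort(cfg2)[, feats], a[, feats]))
})

test_that("configuration errors are caught", {
  expect_error(tiny_cfg(affected_regions = "NoSuchRegion"),
               "affected_regions")
  expect_error(tiny_cfg(noise_sd = 0), "noise_sd")
  expect_error(tiny_cfg(n_at_risk = -1), "cohort sizes")
  expect_error(severity_from_labels(0.3, 30), "cdr")
  expect_error(severity_from_labels(0, 31), "mmse")
})

test_that("null construction: zero effect leaves at-risk like holdout", {
  cfg <- tiny_cfg(effect_size = 0, progression_rate = 0, seed = 33L,
                  n_at_risk = 400, n_holdout = 400)
  co <- generate_cohort(cfg)
  base <- co[co$visit == 0, ]
  feats <- feature_names(tiny_mods())
  pvals <- vapply(feats, function(f) {
    stats::t.test(base[[f]][base$cohort_label == "at_risk"],
                  base[[f]][base$cohort_label == "holdout"])$p.value
  }, 0)
  # 26 tests at alpha = 0.01: expected 0.26 false positives; allow a
  # generous binomial upper bound
  expect_lte(sum(pvals < 0.01), qbinom(0.999, length(feats), 0.01) + 1)
})

test_that("injected effect magnitude matches the difference-of-means oracle", {
  diffs <- vapply(1:20, function(s) {
    cfg <- tiny_cfg(n_at_risk = 500, n_holdout = 500, effect_size = 1,
                    affected_regions = "Left-Hippocampus", seed = 1000L + s,
                    longitudinal = FALSE)
    co <- generate_cohort(cfg)
    sdc <- attr(co, "truth")$sd_control["Left-Hippocampus"]
    (mean(co[co$cohort_label == "at_risk", "Left-Hippocampus"]) -
        mean(co[co$cohort_label == "holdout", "Left-Hippocampus"])) / sdc
  }, 0)
  expect_lt(abs(mean(diffs) + 1), 0.15)  # shift is negative for volumes
})

test_that("disease shift directions follow modality conventions", {
  cfg <- tiny_cfg(n_at_risk = 800, n_holdout = 800, effect_size = 2,
                  seed = 7L, longitudinal = FALSE)
  co <- generate_cohort(cfg)
  ar <- co$cohort_label == "at_risk"; ho <- co$cohort_label == "holdout"
  for (f in c("Left-Hippocampus", "fa1")) {
    expect_lt(mean(co[ar, f]), mean(co[ho, f]))
  }
  expect_gt(mean(co[ar, "md1"]), mean(co[ho, "md1"]))
})

test_that("severity scalar is anchored and monotone", {
  expect_identical(severity_from_labels(0, 30), 0)
  for (m in c(30, 28, 25, 20)) {
    expect_gte(severity_from_labels(0.5, m), severity_from_labels(0, m))
  }
  expect_true(all(diff(severity_from_labels(0, 30:20)) > 0))
  expect_true(all(severity_from_labels(c(0, 0.5, 1, 2, 3), 30) ==
                    cummax(severity_from_labels(c(0, 0.5, 1, 2, 3), 30))))
  expect_true(all(severity_from_labels(3, 0) <= 1))
})

test_that("the injected smooth age effect is recoverable (R^2 > 0.9)", {
  cfg <- simulation_config(n_healthy_train = 2000, n_finetune = 0,
                           n_holdout = 0, n_at_risk = 0,
                           modalities = tiny_mods(), k_shared = 4,
                           affected_regions = tiny_affected(),
                           longitudinal = FALSE, seed = 5L)
  co <- generate_cohort(cfg)
  truth <- attr(co, "truth")
  grid <- data.frame(age = seq(52, 78, length.out = 60))
  for (f in c("gm3", "fa4", "md5")) {
    fit <- mgcv::gam(co[[f]] ~ s(age, bs = "tp", k = 10),
                     data = data.frame(age = co$age))
    recovered <- predict(fit, grid)
    true_curve <- truth$age_amp[f] * normdev:::age_curve(grid$age)
    rc <- recovered - mean(recovered)
    tc <- true_curve - mean(true_curve)
    r2 <- 1 - sum((rc - tc)^2) / sum(tc^2)
    expect_gt(r2, 0.9)
  }
})

test_that("severity couples to CSF biomarkers with constructed signs", {
  co <- generate_cohort(tiny_cfg(n_at_risk = 600, seed = 13L))
  base <- co[co$visit == 0 & co$cohort_label == "at_risk", ]
  sev <- severity_from_labels(base$cdr, base$mmse)
  expect_gt(cor(sev, base$csf_ptau), 0)
  expect_gt(cor(sev, base$csf_ttau), 0)
  expect_lt(cor(sev, base$csf_abeta42), 0)
  expect_lt(cor.test(sev, base$csf_ptau)$p.value, 0.01)
})

test_that("cohort tables round-trip through CSV", {
  co <- generate_cohort(tiny_cfg(n_healthy_train = 30, n_finetune = 20,
                                 n_holdout = 20, n_at_risk = 20))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_identical(names(back), names(co))
  expect_equal(back$age, co$age)
  expect_equal(back[["Left-Hippocampus"]], co[["Left-Hippocampus"]])
})
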