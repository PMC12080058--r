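test_that("zero-epoch training is a no-op and gating works", {
  mods <- tiny_mods()
  m <- dmvae_model(mods, k_shared = 3, k_private = 1, hidden = 16, seed = 2)
  co <- generate_cohort(tiny_cfg(n_healthy_train = 50, n_finetune = 0,
                                 n_holdout = 0, n_at_risk = 0))
  m0 <- dmvae_train(m, co, epochs = 0)
  expect_identical(m0$params, m$params)
  expect_error(dmvae_finetune(m, co), "trained")

  m1 <- dmvae_train(m, co, epochs = 2, batch_size = 64)
  expect_identical(dmvae_finetune(m1, co, epochs = 0), m1)
})

test_that("validation error approaches the generative noise floor", {
  fs <- fidelity_study()
  err <- reconstruction_error(fs$model, fs$validation)
  # in adjusted (z) units the irreducible noise fraction per feature is
  # noise_sd^2 / control-variance
  sdc <- attr(fs$cohort, "truth")$sd_control
  floor <- mean(fs$cfg$noise_sd^2 / sdc^2)
  expect_lt(err, 1.2 * floor)
  # loss history: finite, and non-increasing in trend over 20-epoch windows
  loss <- fs$model$history$loss
  expect_true(all(is.finite(loss)))
  win <- vapply(split(loss, ceiling(seq_along(loss) / 20)), median, 0)
  expect_true(all(diff(win) <= 1e-8))
})

test_that("encoding is deterministic with contractual shapes", {
  study <- small_study()
  h <- study$holdout_adj
  c1 <- dmvae_encode(study$model, h)
  c2 <- dmvae_encode(study$model, h)
  expect_identical(c1, c2)
  expect_equal(dim(c1$shared), c(nrow(h), study$model$k_s))
  expect_equal(dim(c1$private$T1), c(nrow(h), study$model$k_p))
  expect_true(all(is.finite(c1$shared)))
  expect_error(dmvae_encode(study$model,
                            h[, -match("FA_ATR_L", names(h))]),
               "FA_ATR_L")
})

test_that("shared latents align with the generative factors (CCA oracle)", {
  fs <- fidelity_study()
  code <- dmvae_encode(fs$model, fs$train)
  truth <- attr(fs$cohort, "truth")
  is_tr <- fs$cohort$cohort_label == "healthy_train"
  cc <- cancor(code$shared, truth$shared_factors[is_tr, ])
  expect_true(all(cc$cor[seq_len(fs$cfg$k_shared)] > 0.8))
})

test_that("fine-tuning adapts to a site shift without drifting elsewhere", {
  deltas <- vapply(1:3, function(s) {
    cfg <- tiny_cfg(seed = 400L + s, site_shift = 0.4,
                    n_healthy_train = 400, n_finetune = 150,
                    n_holdout = 150, n_at_risk = 0)
    co <- generate_cohort(cfg)
    feats <- feature_names(tiny_mods())
    is_tr <- co$cohort_label == "healthy_train"
    cm_tr <- fit_confound_model(co[is_tr, ], features = feats)
    cm_tg <- fit_confound_model(
      co[co$cohort_label == "finetune" & co$visit == 0, ], features = feats)
    adj <- co
    adj[is_tr, ] <- apply_confound_model(cm_tr, co[is_tr, ])
    adj[!is_tr, ] <- suppressWarnings(
      apply_confound_model(cm_tg, co[!is_tr, ]))
    m <- dmvae_model(tiny_mods(), k_shared = 4, k_private = 2,
                     hidden = 48, seed = s)
    m <- dmvae_train(m, adj[is_tr, ], epochs = 80)
    ho <- adj[adj$cohort_label == "holdout" & adj$visit == 0, ]
    before <- reconstruction_error(m, ho)
    mf <- dmvae_finetune(m, adj[adj$cohort_label == "finetune", ],
                         epochs = 30)
    after <- reconstruction_error(mf, ho)
    after - before
  }, 0)
  expect_lt(median(deltas), 0)

  # fine-tuning on data from the pretraining distribution barely moves the
  # holdout error (no catastrophic drift at the default reduced rate)
  study <- small_study()
  adj <- study$adjusted
  tr <- adj[adj$cohort_label == "healthy_train", ]
  same_site <- tr[1:100, ]
  before <- reconstruction_error(study$pre_finetune, study$holdout_adj)
  m2 <- dmvae_finetune(study$pre_finetune, same_site, epochs = 10)
  after <- reconstruction_error(m2, study$holdout_adj)
  expect_lt(abs(after - before) / before, 0.10)
})

test_that("reconstruction contract: names, order, finiteness", {
  study <- small_study()
  h <- study$holdout_adj
  R <- reconstruction_residuals(study$model, h)
  expect_identical(colnames(R), feature_names(study$model$modalities))
  expect_true(all(is.finite(R)))

  # untrained model on zero input stays finite
  mods0 <- tiny_mods()
  m0 <- dmvae_model(mods0, k_shared = 3, k_private = 1, hidden = 8,
                    seed = 9)
  zero <- generate_cohort(tiny_cfg(n_healthy_train = 2, n_finetune = 0,
                                   n_holdout = 0, n_at_risk = 0))
  zero[, feature_names(mods0)] <- 0
  expect_true(all(is.finite(dmvae_reconstruct(m0, zero))))
})

test_that("at-risk reconstruction error exceeds healthy holdout error", {
  study <- small_study()  # effect_size = 2 in affected regions
  adj <- study$adjusted
  ar <- adj[adj$cohort_label == "at_risk" & adj$visit == 0, ]
  expect_gt(reconstruction_error(study$model, ar),
            reconstruction_error(study$model, study$holdout_adj))
})

test_that("feature names do not affect the fit, only column order does", {
  cfg <- tiny_cfg(n_healthy_train = 120, n_finetune = 0, n_holdout = 0,
                  n_at_risk = 0, seed = 77L)
  co <- generate_cohort(cfg)
  mods <- tiny_mods()
  renamed <- lapply(mods, function(ms) {
    ms$features <- paste0("x_", ms$features); ms
  })
  co2 <- co
  names(co2)[match(feature_names(mods), names(co2))] <-
    paste0("x_", feature_names(mods))
  m1 <- dmvae_train(dmvae_model(mods, 3, 1, hidden = 16, seed = 5),
                    co, epochs = 5, batch_size = 64)
  m2 <- dmvae_train(dmvae_model(renamed, 3, 1, hidden = 16, seed = 5),
                    co2, epochs = 5, batch_size = 64)
  expect_equal(m1$history$loss, m2$history$loss, tolerance = 1e-12)
})

test_that("ablating private codes hurts the private-factor modality most", {
  # modality A carries a strong extra private factor; B is mostly shared
  set.seed(42)
  n <- 1200
  f <- rnorm(n)                      # shared factor
  pa <- rnorm(n)                     # private factor of A
  A <- outer(f, runif(6, 0.5, 1)) + outer(pa, runif(6, 0.8, 1.2)) +
    matrix(rnorm(n * 6, 0, 0.3), n)
  B <- outer(f, runif(6, 0.5, 1)) + matrix(rnorm(n * 6, 0, 0.3), n)
  d <- as.data.frame(scale(cbind(A, B)))
  names(d) <- c(paste0("a", 1:6), paste0("b", 1:6))
  mods <- list(A = modality_spec("T1", paste0("a", 1:6)),
               B = modality_spec("T1", paste0("b", 1:6)))
  m <- dmvae_model(mods, k_shared = 2, k_private = 2, hidden = 32, seed = 8)
  m <- dmvae_train(m, d, epochs = 120, batch_size = 256)

  code <- dmvae_encode(m, d)
  mse <- function(mod_i, private) {
    Z <- cbind(code$shared, private)
    hat <- normdev:::dec_forward(m$params[[mod_i]]$dec, Z)$Xhat
    mean((as.matrix(d[, m$modalities[[mod_i]]$features]) - hat)^2)
  }
  degrade_A <- mse(1, 0 * code$private$A) - mse(1, code$private$A)
  degrade_B <- mse(2, 0 * code$private$B) - mse(2, code$private$B)
  expect_gt(degrade_A, degrade_B)
  expect_gt(degrade_A, 0)
})

test_that("checkpoints round-trip bit-exactly and bad input aborts", {
  study <- small_study()
  path <- tempfile(fileext = ".rds")
  save_normative_model(study$model, path)
  expect_identical(load_normative_model(path), study$model)

  bad <- study$holdout_adj[1:20, ]
  bad[["FA_ATR_L"]][3] <- NA
  expect_error(dmvae_train(study$model, bad, epochs = 1), "diverged")
})
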