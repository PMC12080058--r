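# Shared fixtures, built in code once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Small three-modality layout (26 features) including the hippocampi, so
# disease-effect tests can target a named region.
tiny_mods <- function() {
  list(T1 = modality_spec("T1", c("Left-Hippocampus", "Right-Hippocampus",
                                  paste0("gm", 1:10))),
       FA = modality_spec("FA", paste0("fa", 1:8)),
       MD = modality_spec("MD", paste0("md", 1:6)))
}

tiny_affected <- function() {
  c("Left-Hippocampus", "Right-Hippocampus", "fa1", "fa2", "md1", "md2")
}

# Parcellation for the tiny layout.
tiny_parcellation <- function() {
  stats::setNames(
    c("medial_temporal_lobe", "medial_temporal_lobe",
      rep(c("limbic", "default", "visual", "somatomotor", "frontoparietal"),
          each = 2)),
    c("Left-Hippocampus", "Right-Hippocampus", paste0("gm", 1:10)))
}

tiny_cfg <- function(...) {
  defaults <- list(n_healthy_train = 500, n_finetune = 150,
                   n_holdout = 200, n_at_risk = 200,
                   modalities = tiny_mods(), k_shared = 4, k_private = 2,
                   affected_regions = tiny_affected(), effect_size = 2,
                   seed = 101L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# One fully trained small study on the standard 146-feature layout:
# cohort, confound models, trained + fine-tuned model, holdout reference.
# Built once and cached.
small_study <- function() {
  if (!is.null(.fixtures$study)) return(.fixtures$study)
  cfg <- simulation_config(n_healthy_train = 500, n_finetune = 150,
                           n_holdout = 200, n_at_risk = 200,
                           effect_size = 2, seed = 101L)
  cohort <- generate_cohort(cfg)
  feats <- feature_names(cfg$modalities)
  is_train <- cohort$cohort_label == "healthy_train"
  cm_train <- fit_confound_model(cohort[is_train, ], features = feats,
                                 fit_cohort_id = "healthy_train")
  cm_target <- fit_confound_model(
    cohort[cohort$cohort_label == "finetune" & cohort$visit == 0, ],
    features = feats, fit_cohort_id = "finetune")
  adj <- cohort
  adj[is_train, ] <- apply_confound_model(cm_train, cohort[is_train, ])
  adj[!is_train, ] <- suppressWarnings(
    apply_confound_model(cm_target, cohort[!is_train, ]))
  model <- dmvae_model(cfg$modalities, k_shared = 6, k_private = 2,
                       hidden = 64, seed = 11L)
  model <- dmvae_train(model, adj[is_train, ], epochs = 60,
                       batch_size = 256, lr = 1e-3)
  pre_finetune <- model
  model <- dmvae_finetune(model,
                          adj[adj$cohort_label == "finetune", ],
                          epochs = 30)
  holdout_adj <- adj[adj$cohort_label == "holdout" & adj$visit == 0, ]
  ref <- fit_holdout_reference(model, holdout_adj)
  .fixtures$study <- list(cfg = cfg, cohort = cohort, adjusted = adj,
                          cm_train = cm_train, cm_target = cm_target,
                          model = model, pre_finetune = pre_finetune,
                          reference = ref, holdout_adj = holdout_adj)
  .fixtures$study
}

# Linear-Gaussian fidelity study: no site shift, so the holdout cohort is
# an in-distribution validation set for the training-site model. Cached.
fidelity_study <- function() {
  if (!is.null(.fixtures$fidelity)) return(.fixtures$fidelity)
  cfg <- simulation_config(n_healthy_train = 2000, n_finetune = 0,
                           n_holdout = 300, n_at_risk = 0, site_shift = 0,
                           longitudinal = FALSE, seed = 31L)
  co <- generate_cohort(cfg)
  feats <- feature_names(cfg$modalities)
  is_tr <- co$cohort_label == "healthy_train"
  cm <- fit_confound_model(co[is_tr, ], features = feats)
  adj_tr <- apply_confound_model(cm, co[is_tr, ])
  adj_val <- suppressWarnings(apply_confound_model(cm, co[!is_tr, ]))
  m <- dmvae_model(cfg$modalities, k_shared = 10, k_private = 2,
                   hidden = 64, seed = 3L)
  m <- dmvae_train(m, adj_tr, epochs = 150, batch_size = 256)
  .fixtures$fidelity <- list(cfg = cfg, cohort = co, model = m,
                             train = adj_tr, validation = adj_val)
  .fixtures$fidelity
}

# Hand-written Benjamini-Hochberg step-up, the independent oracle.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (i in seq(m, 1)) {
    running_min <- min(running_min, p[o[i]] * m / i)
    adj[o[i]] <- running_min
  }
  pmin(adj, 1)
}

# Textbook Welch statistic, the independent oracle.
welch_oracle <- function(a, b) {
  v1 <- var(a) / length(a); v2 <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
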