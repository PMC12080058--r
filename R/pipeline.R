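# Three-stage workflow orchestration: train on healthy controls, fine-tune
# to the target site's controls, then score holdout and at-risk cohorts and
# run the downstream outlier/network/biomarker analyses. Every artifact is
# written to the output directory together with a manifest (config hash,
# seed, file hashes, stage timings) so a rerun with the same config and
# seed reproduces all deterministic outputs.

#' Build a pipeline run configuration
#'
#' @param cohort Either a cohort `data.frame` (e.g. from
#'   [generate_cohort()]) or a path to a cohort CSV. `NULL` means simulate
#'   with `sim_config`.
#' @param sim_config A [simulation_config()] used when `cohort` is `NULL`.
#' @param parcellation Path to a region-network mapping file, or a named
#'   vector as from [read_parcellation()].
#' @param k_shared,k_private,hidden Model architecture.
#' @param epochs,finetune_epochs Training/fine-tuning epochs.
#' @param lr,finetune_lr Learning rates for the two phases.
#' @param batch_size Minibatch size.
#' @param outlier_z Outlier threshold on |D_uf| (default 1.96).
#' @param alpha Significance level (default 0.05).
#' @param n_perm Label permutations for the network tests (default 10000).
#' @param basis_dim Age-spline basis dimension for confound removal.
#' @param visit_policy `"baseline"` or `"latest"`: which visit feeds the
#'   cross-sectional analyses (the longitudinal analysis always uses both).
#' @param seed Integer master seed.
#' @param out_dir Output directory for artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = NULL, sim_config = simulation_config(),
                       parcellation = NULL,
                       k_shared = 10, k_private = 2, hidden = 64,
                       epochs = 100, finetune_epochs = 30,
                       lr = 1e-3, finetune_lr = 1e-4, batch_size = 256,
                       outlier_z = 1.96, alpha = 0.05, n_perm = 10000,
                       basis_dim = 10, visit_policy = c("latest",
                                                        "baseline"),
                       seed = 1L, out_dir = tempfile("normdev_run")) {
  stopifnot(outlier_z > 0, alpha > 0, n_perm > 0)
  visit_policy <- match.arg(visit_policy)
  if (is.character(cohort) && !file.exists(cohort)) {
    stop("cohort file does not exist: ", cohort)
  }
  parc_is_path <- is.character(parcellation) &&
    length(parcellation) == 1 && is.null(names(parcellation))
  if (parc_is_path && !file.exists(parcellation)) {
    stop("parcellation file does not exist: ", parcellation)
  }
  structure(list(cohort = cohort, sim_config = sim_config,
                 parcellation = parcellation, k_shared = k_shared,
                 k_private = k_private, hidden = hidden, epochs = epochs,
                 finetune_epochs = finetune_epochs, lr = lr,
                 finetune_lr = finetune_lr, batch_size = batch_size,
                 outlier_z = outlier_z, alpha = alpha, n_perm = n_perm,
                 basis_dim = basis_dim, visit_policy = visit_policy,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(vals$sim_config)) {
    vals$sim_config <- do.call(simulation_config, vals$sim_config)
  }
  do.call(run_config, vals)
}

pick_visit <- function(cohort, policy) {
  split_rows <- split(seq_len(nrow(cohort)), cohort$subject_id)
  keep <- vapply(split_rows, function(ix) {
    v <- cohort$visit[ix]
    ix[if (policy == "baseline") which.min(v) else which.max(v)]
  }, 0L)
  cohort[sort(keep), , drop = FALSE]
}

#' Run the full normative-modelling pipeline
#'
#' Executes: (optional) simulation, per-site confound fitting and
#' application, model training on healthy-site controls, fine-tuning on
#' target-site controls, holdout reference fitting, deviation scoring,
#' stratified outlier maps, network permutation tests, effect sizes,
#' age-adjusted biomarker correlations, and longitudinal paired tests.
#' Artifacts (delimited tables, model checkpoints, manifest) are written
#' to `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`model`,
#'   `reference`, `deviations`, `outlier_maps`, `network_tests`,
#'   `correlations`, `effect_sizes`, `longitudinal`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }
  path <- function(f) file.path(config$out_dir, f)

  cohort <- stage("load", {
    if (is.null(config$cohort)) {
      sc <- config$sim_config
      sc$seed <- config$seed
      generate_cohort(sc)
    } else if (is.character(config$cohort)) {
      read_cohort(config$cohort)
    } else {
      config$cohort
    }
  })
  write_cohort(cohort, path("cohort.csv"))
  mods <- attr(cohort, "modalities")
  if (is.null(mods)) mods <- default_modalities()

  parc <- config$parcellation
  if (is.null(parc)) {
    parc <- read_parcellation()
  } else if (is.character(parc) && length(parc) == 1 && is.null(names(parc))) {
    parc <- read_parcellation(parc)
  }

  # Confound removal: one model per site, z-scored against that site's
  # fine-tuning/training controls.
  adjusted <- stage("confound", {
    is_train <- cohort$cohort_label == "healthy_train"
    is_ft <- cohort$cohort_label == "finetune"
    cm_train <- fit_confound_model(cohort[is_train & cohort$visit == 0, ],
                                   features = feature_names(mods),
                                   basis_dim = config$basis_dim,
                                   fit_cohort_id = "healthy_train")
    cm_target <- fit_confound_model(cohort[is_ft & cohort$visit == 0, ],
                                    features = feature_names(mods),
                                    basis_dim = config$basis_dim,
                                    fit_cohort_id = "finetune")
    save_confound_model(cm_train, path("confound_train.rds"))
    save_confound_model(cm_target, path("confound_target.rds"))
    adj <- cohort
    adj[is_train, ] <- apply_confound_model(cm_train, cohort[is_train, ])
    adj[!is_train, ] <- apply_confound_model(cm_target, cohort[!is_train, ])
    adj
  })

  model <- stage("train", {
    m <- dmvae_model(mods, k_shared = config$k_shared,
                     k_private = config$k_private, hidden = config$hidden,
                     seed = config$seed)
    dmvae_train(m, adjusted[adjusted$cohort_label == "healthy_train", ],
                epochs = config$epochs, batch_size = config$batch_size,
                lr = config$lr, seed = config$seed)
  })
  model <- stage("finetune", {
    dmvae_finetune(model,
                   adjusted[adjusted$cohort_label == "finetune", ],
                   epochs = config$finetune_epochs,
                   batch_size = config$batch_size,
                   lr = config$finetune_lr, seed = config$seed + 1L)
  })
  save_normative_model(model, path("model.rds"))

  holdout_adj <- adjusted[adjusted$cohort_label == "holdout" &
                            adjusted$visit == 0, ]
  ref <- stage("reference", fit_holdout_reference(model, holdout_adj))
  saveRDS(ref, path("reference.rds"))

  score_rows <- adjusted$cohort_label %in% c("holdout", "at_risk")
  deviations <- stage("deviate", {
    compute_deviations(model, ref, adjusted[score_rows, ],
                       exclude_self = TRUE)
  })
  devs <- cbind(adjusted[score_rows,
                         intersect(cohort_meta_cols(), names(adjusted))],
                deviations[, c("d_ml", feature_names(mods))])
  write_deviations(deviations, path("deviations.csv"))

  cross <- pick_visit(devs, config$visit_policy)
  flags <- flag_outliers(as.matrix(cross[, feature_names(mods)]), mods,
                         threshold = config$outlier_z)

  # Stratified outlier maps: holdout plus CDR and MMSE strata of at-risk.
  omap <- stage("outliers", {
    strata <- c(list(holdout = cross$cohort_label == "holdout"),
                lapply(c(`CDR=0` = 0, `CDR=0.5` = 0.5), function(v)
                  cross$cohort_label == "at_risk" & cross$cdr == v),
                list(`MMSE=30` = cross$cohort_label == "at_risk" &
                       cross$mmse == 30,
                     `MMSE=28-29` = cross$cohort_label == "at_risk" &
                       cross$mmse %in% 28:29,
                     `MMSE=26-27` = cross$cohort_label == "at_risk" &
                       cross$mmse %in% 26:27,
                     `MMSE=21-25` = cross$cohort_label == "at_risk" &
                       cross$mmse %in% 21:25))
    maps <- lapply(names(strata), function(s) {
      rows <- strata[[s]]
      if (!any(rows)) return(NULL)
      outlier_proportions(flags[rows, , drop = FALSE], stratum = s)
    })
    do.call(rbind, maps)
  })
  utils::write.csv(omap, path("outlier_maps.csv"), row.names = FALSE)

  net <- stage("networks", {
    ctrl_flags <- flags[cross$cohort_label == "holdout", , drop = FALSE]
    strata <- list(`MMSE=30` = cross$mmse == 30,
                   `MMSE=28-29` = cross$mmse %in% 28:29,
                   `MMSE=26-27` = cross$mmse %in% 26:27,
                   `MMSE=21-25` = cross$mmse %in% 21:25)
    tests <- lapply(names(strata), function(s) {
      rows <- cross$cohort_label == "at_risk" & strata[[s]]
      if (sum(rows) < 2) return(NULL)
      pt <- permutation_test(flags[rows, , drop = FALSE], ctrl_flags,
                             parc, n_perm = config$n_perm,
                             seed = config$seed + 17L)
      cbind(stratum = s, pt$network)
    })
    do.call(rbind, tests)
  })
  utils::write.csv(net, path("network_tests.csv"), row.names = FALSE)

  correlations <- stage("correlations", {
    ar <- cross[cross$cohort_label == "at_risk", ]
    ar <- add_ptau_abeta_ratio(ar)
    ctrl <- add_ptau_abeta_ratio(
      cohort[cohort$cohort_label %in% c("finetune", "holdout") &
               cohort$visit == 0, ])
    bio <- c("csf_ptau", "csf_ttau", "csf_abeta42", "ptau_abeta42_ratio")
    ar_adj <- age_adjust(ar, ctrl, biomarkers = bio)
    tab <- deviation_correlations(ar_adj$d_ml, ar_adj)
    tab$bonferroni_threshold <- bonferroni_threshold(config$alpha,
                                                     nrow(tab))
    tab
  })
  utils::write.csv(correlations, path("dml_correlations.csv"),
                   row.names = FALSE)

  effects <- stage("effects", {
    base <- pick_visit(devs, "baseline")
    hold <- base[base$cohort_label == "holdout", ]
    groups <- list(`apoe=0` = 0L, `apoe=1` = 1L, `apoe=2` = 2L)
    rows <- lapply(names(groups), function(g) {
      sub <- base[base$cohort_label == "at_risk" &
                    base$apoe_e4_count == groups[[g]], ]
      if (nrow(sub) < 2) return(NULL)
      data.frame(subgroup = g, feature = feature_names(mods),
                 d = vapply(feature_names(mods), function(f)
                   cohens_d(sub[[f]], hold[[f]]), 0),
                 n = nrow(sub), row.names = NULL,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  utils::write.csv(effects, path("effect_sizes.csv"), row.names = FALSE)

  longitudinal <- stage("longitudinal", {
    rows <- lapply(c("at_risk", "holdout"), function(g) {
      d <- devs[devs$cohort_label == g, c("subject_id", "visit", "d_ml")]
      wide <- merge(d[d$visit == 0, c("subject_id", "d_ml")],
                    d[d$visit == 1, c("subject_id", "d_ml")],
                    by = "subject_id", suffixes = c("_0", "_1"))
      if (nrow(wide) < 2) return(NULL)
      pt <- paired_t(wide$d_ml_0, wide$d_ml_1)
      data.frame(cohort = g, t = pt$t, df = pt$df, p = pt$p, n = pt$n,
                 mean_change = pt$mean_diff, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  utils::write.csv(longitudinal, path("longitudinal.csv"),
                   row.names = FALSE)

  manifest <- list(
    seed = config$seed,
    config_hash = unname(config_hash(config)),
    created = format(t_start, "%Y-%m-%d %H:%M:%S"),
    stage_seconds = timings,
    files = as.list(tools::md5sum(list.files(config$out_dir,
                                             full.names = TRUE))))
  writeLines(yaml::as.yaml(manifest), path("manifest.yaml"))

  invisible(list(model = model, reference = ref, deviations = devs,
                 outlier_maps = omap, network_tests = net,
                 correlations = correlations, effect_sizes = effects,
                 longitudinal = longitudinal, manifest = manifest,
                 out_dir = config$out_dir))
}

config_hash <- function(config) {
  cfg <- config[setdiff(names(config), c("out_dir", "cohort"))]
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(cfg, digits.d = 10)), f)
  tools::md5sum(f)
}
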