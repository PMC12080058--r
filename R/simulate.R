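#' Simulation configuration for synthetic multi-modal cohorts
#'
#' Defines the generative model for a synthetic study: a large healthy
#' training cohort, a target-site fine-tuning cohort, a healthy holdout
#' cohort, and an "at-risk" cohort whose features carry regionally focused
#' deviations that scale with drawn clinical severity (CDR/MMSE) and, at
#' follow-up visits, progress over time. Features arise from shared latent
#' factors common to all modalities, per-modality private factors, a smooth
#' nonlinear age effect, linear sex and intracranial-volume effects, an
#' additive site offset for target-site cohorts, and Gaussian noise.
#'
#' All amplitudes (`effect_size`, `progression_rate`, `site_shift`,
#' `beta_age`) are expressed in control-standard-deviation units of each
#' feature, so they are comparable across features. Features are generated on
#' an arbitrary standardized scale, not in physical units.
#'
#' @param n_healthy_train,n_finetune,n_holdout,n_at_risk Cohort sizes.
#' @param modalities Named list of [modality_spec()]; defaults to the 82/32/32
#'   T1/FA/MD layout.
#' @param k_shared Number of shared latent factors.
#' @param k_private Private latent factors per modality.
#' @param age_range Length-2 numeric, simulated age range in years.
#' @param beta_age Amplitude of the nonlinear age effect (control-sd units
#'   across the age range; sign follows the modality's ageing direction).
#' @param beta_sex,beta_icv Linear sex and ICV effect sizes (ICV affects T1
#'   volumes only).
#' @param noise_sd Residual Gaussian noise standard deviation (> 0).
#' @param affected_regions Feature names receiving the disease effect.
#' @param effect_size Mean at-risk deviation in affected regions, in
#'   control-sd units; individual shifts scale with the severity scalar.
#' @param progression_rate Added deviation per follow-up visit (control-sd
#'   units), at-risk rows only.
#' @param site_shift Additive per-feature offset (control-sd units) applied
#'   to the fine-tune, holdout and at-risk cohorts, emulating a domain gap
#'   between the training site and the target site.
#' @param longitudinal If `TRUE`, holdout and at-risk subjects get a second
#'   visit 12 months after baseline.
#' @param seed Integer seed; identical seeds give bit-identical tables.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_healthy_train = 2000,
                              n_finetune = 200,
                              n_holdout = 200,
                              n_at_risk = 600,
                              modalities = default_modalities(),
                              k_shared = 6,
                              k_private = 2,
                              age_range = c(50, 80),
                              beta_age = 0.8,
                              beta_sex = 0.3,
                              beta_icv = 2,
                              noise_sd = 0.6,
                              affected_regions = default_affected_regions(),
                              effect_size = 1,
                              progression_rate = 0.75,
                              site_shift = 0.3,
                              longitudinal = TRUE,
                              seed = 1L) {
  counts <- c(n_healthy_train, n_finetune, n_holdout, n_at_risk)
  if (any(counts < 0)) stop("cohort sizes must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  feats <- feature_names(modalities)
  missing <- setdiff(affected_regions, feats)
  if (length(missing) > 0) {
    stop("affected_regions not in declared feature list: ",
         paste(missing, collapse = ", "))
  }
  structure(list(n_healthy_train = n_healthy_train, n_finetune = n_finetune,
                 n_holdout = n_holdout, n_at_risk = n_at_risk,
                 modalities = modalities, k_shared = k_shared,
                 k_private = k_private, age_range = age_range,
                 beta_age = beta_age, beta_sex = beta_sex,
                 beta_icv = beta_icv, noise_sd = noise_sd,
                 affected_regions = affected_regions,
                 effect_size = effect_size,
                 progression_rate = progression_rate,
                 site_shift = site_shift, longitudinal = longitudinal,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default disease-affected regions
#'
#' Medial-temporal grey-matter structures plus fornix/stria-terminalis and
#' hippocampal-cingulum tracts — the regional pattern typical of early
#' Alzheimer-type neurodegeneration.
#'
#' @return Character vector of feature names.
#' @export
default_affected_regions <- function() {
  c("Left-Hippocampus", "Right-Hippocampus",
    "Left-Amygdala", "Right-Amygdala",
    "lh_entorhinal", "rh_entorhinal",
    "lh_parahippocampal", "rh_parahippocampal",
    "lh_middletemporal", "rh_middletemporal",
    "lh_inferiortemporal", "rh_inferiortemporal",
    "FA_FX_ST_L", "FA_FX_ST_R", "FA_CGH_L", "FA_CGH_R",
    "MD_FX_ST_L", "MD_FX_ST_R", "MD_CGH_L", "MD_CGH_R")
}

#' Severity scalar from clinical labels
#'
#' Maps a Clinical Dementia Rating (0, 0.5, 1, 2, 3) and a Mini-Mental State
#' Examination score (30 down to 0) to a single non-negative severity scalar
#' in \[0, 1\]: `(2 * CDR + (30 - MMSE) / 10) / 9`. The blend is monotone
#' non-decreasing in CDR, non-increasing in MMSE, and 0 for a cognitively
#' normal subject (CDR = 0, MMSE = 30).
#'
#' @param cdr CDR global score(s), in `{0, 0.5, 1, 2, 3}`.
#' @param mmse MMSE total score(s), integer 0-30.
#' @return Numeric vector of severity values in \[0, 1\].
#' @export
severity_from_labels <- function(cdr, mmse) {
  if (!all(cdr %in% c(0, 0.5, 1, 2, 3))) {
    stop("cdr values must be in {0, 0.5, 1, 2, 3}")
  }
  if (any(mmse < 0 | mmse > 30 | mmse != round(mmse))) {
    stop("mmse values must be integers in [0, 30]")
  }
  (2 * cdr + (30 - mmse) / 10) / 9
}

# Smooth population ageing curve: linear drift plus a logistic acceleration
# after age ~62. Increasing in age; per-feature sign is set by modality.
age_curve <- function(age) {
  0.04 * (age - 65) + stats::plogis((age - 62) / 5) - 0.5
}

# Run expr with a private, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic multi-modal cohort table
#'
#' Draws a full study population from the generative model declared in a
#' [simulation_config()]: one row per subject-visit, with covariates,
#' clinical labels, CSF biomarkers, and one column per imaging feature.
#' Ground truth (shared factors, loadings, control standard deviations,
#' injected age curve, severity scalars) is attached as attribute `"truth"`
#' for validation.
#'
#' @param config A [simulation_config()].
#' @return A `data.frame` (one row per subject-visit) with columns
#'   `subject_id`, `visit`, `cohort_label`, `age`, `sex`, `icv`, `cdr`,
#'   `mmse`, `apoe_e4_count`, `csf_ptau`, `csf_ttau`, `csf_abeta42`,
#'   followed by all feature columns.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  mods <- cfg$modalities
  feats <- feature_names(mods)
  p <- length(feats)
  mod_of <- spec_for_features(feats, mods)
  mod_names <- vapply(mods, `[[`, "", "name")[mod_of]
  ks <- cfg$k_shared
  kp <- cfg$k_private

  n <- c(healthy_train = cfg$n_healthy_train, finetune = cfg$n_finetune,
         holdout = cfg$n_holdout, at_risk = cfg$n_at_risk)
  N <- sum(n)
  cohort <- rep(names(n), n)

  # Fixed population-level structure ---------------------------------------
  mu <- stats::rnorm(p)
  L <- matrix(stats::rnorm(p * ks, sd = sqrt(0.36 / ks)), p, ks)
  P <- matrix(stats::rnorm(p * kp, sd = sqrt(0.20 / max(kp, 1))), p, kp)
  sd_control <- sqrt(rowSums(L^2) + rowSums(P^2) + cfg$noise_sd^2)

  # Ageing direction: decline for volumes/FA, increase for MD.
  dir_age <- ifelse(mod_names == "MD", 1, -1)
  age_amp <- dir_age * cfg$beta_age * stats::runif(p, 0.5, 1.5) * sd_control
  sex_eff <- cfg$beta_sex * stats::runif(p, -1, 1) * sd_control
  icv_eff <- ifelse(mod_names == "T1",
                    cfg$beta_icv * stats::runif(p, 0.5, 1.5) * sd_control, 0)
  site_off <- cfg$site_shift * stats::rnorm(p) * sd_control
  dir_disease <- ifelse(mod_names == "MD", 1, -1)
  affected <- feats %in% cfg$affected_regions

  # Subject-level draws -----------------------------------------------------
  age0 <- stats::runif(N, cfg$age_range[1], cfg$age_range[2])
  sex <- stats::rbinom(N, 1, 0.5)
  icv <- stats::rnorm(N, 1.5, 0.15)
  F_shared <- matrix(stats::rnorm(N * ks), N, ks)
  F_private <- lapply(mods, function(m) matrix(stats::rnorm(N * kp), N, kp))

  # Clinical labels ---------------------------------------------------------
  cdr <- numeric(N)
  mmse <- rep(30L, N)
  apoe <- integer(N)
  healthy <- cohort != "at_risk"
  mmse[healthy] <- sample(c(29L, 30L), sum(healthy), TRUE, c(0.4, 0.6))
  is_train <- cohort == "healthy_train"
  apoe[is_train] <- sample(0:2, sum(is_train), TRUE, c(0.72, 0.26, 0.02))
  ar <- which(cohort == "at_risk")
  if (length(ar) > 0) {
    cdr[ar] <- sample(c(0, 0.5, 1), length(ar), TRUE, c(0.64, 0.34, 0.02))
    deficit <- pmin(stats::rpois(length(ar), 1.2 + 3 * cdr[ar]), 20L)
    mmse[ar] <- 30L - as.integer(deficit)
    apoe[ar] <- sample(0:2, length(ar), TRUE, c(0.48, 0.46, 0.06))
  }
  sev <- severity_from_labels(cdr, mmse)
  sev_bar <- mean(sev[ar])
  if (!is.finite(sev_bar) || sev_bar <= 0) sev_bar <- 1

  # CSF biomarkers, coupled to severity ------------------------------------
  csf_ptau <- pmax(1, 16.7 + 50 * sev + stats::rnorm(N, 0, 7))
  csf_ttau <- pmax(10, 198 + 500 * sev + stats::rnorm(N, 0, 70))
  csf_abeta42 <- pmax(150, 1555 - 3500 * sev + stats::rnorm(N, 0, 600))

  # Assemble subject-visit rows ---------------------------------------------
  visits <- rep(0L, N)
  idx <- seq_len(N)
  if (cfg$longitudinal) {
    fu <- which(cohort %in% c("holdout", "at_risk"))
    idx <- c(idx, fu)
    visits <- c(visits, rep(1L, length(fu)))
  }
  ord <- order(idx, visits)
  idx <- idx[ord]; visits <- visits[ord]
  age <- age0[idx] + visits  # 12 months per visit

  target_site <- cohort[idx] %in% c("finetune", "holdout", "at_risk")
  at_risk_row <- cohort[idx] == "at_risk"
  sev_row <- sev[idx]

  X <- F_shared[idx, , drop = FALSE] %*% t(L)
  for (m in seq_along(mods)) {
    jm <- which(mod_of == m)
    X[, jm] <- X[, jm] +
      F_private[[m]][idx, , drop = FALSE] %*% t(P[jm, , drop = FALSE])
  }
  X <- X + outer(age_curve(age), age_amp) +
    outer(sex[idx], sex_eff) + outer(icv[idx] - 1.5, icv_eff) +
    rep(1, length(idx)) %o% mu
  X[target_site, ] <- X[target_site, ] +
    rep(1, sum(target_site)) %o% site_off

  # Disease effect: severity-scaled baseline shift plus per-visit progression
  # in affected regions, at-risk rows only. Severity multipliers are
  # normalized by the at-risk mean so `effect_size` is the cohort-mean shift.
  shift_dir <- dir_disease * sd_control * affected
  if (any(at_risk_row)) {
    mult <- cfg$effect_size * sev_row[at_risk_row] / sev_bar +
      cfg$progression_rate * visits[at_risk_row]
    X[at_risk_row, ] <- X[at_risk_row, ] + outer(mult, shift_dir)
  }
  X <- X + matrix(stats::rnorm(length(idx) * p, sd = cfg$noise_sd),
                  length(idx), p)
  colnames(X) <- feats

  out <- data.frame(
    subject_id = sprintf("S%05d", idx),
    visit = visits,
    cohort_label = cohort[idx],
    age = age,
    sex = sex[idx],
    icv = icv[idx],
    cdr = cdr[idx],
    mmse = mmse[idx],
    apoe_e4_count = apoe[idx],
    csf_ptau = csf_ptau[idx],
    csf_ttau = csf_ttau[idx],
    csf_abeta42 = csf_abeta42[idx],
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(X))
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    shared_factors = F_shared[idx, , drop = FALSE],
    loadings = L, private_loadings = P,
    sd_control = stats::setNames(sd_control, feats),
    age_amp = stats::setNames(age_amp, feats),
    severity = sev_row, site_offsets = stats::setNames(site_off, feats),
    affected = stats::setNames(affected, feats))
  attr(out, "modalities") <- mods
  out
}

#' Write / read a cohort table as delimited text
#'
#' @param cohort A cohort `data.frame` as returned by [generate_cohort()].
#' @param path File path (CSV, UTF-8, header row).
#' @return `read_cohort()` returns the cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  fileEncoding = "UTF-8")
}

# Extract the feature matrix for given feature names from a cohort table.
cohort_features <- function(cohort, features) {
  missing <- setdiff(features, names(cohort))
  if (length(missing) > 0) {
    stop("cohort table lacks feature columns: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  as.matrix(cohort[, features, drop = FALSE])
}
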