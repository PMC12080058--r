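#' @importFrom mgcv smoothCon s magic PredictMat
NULL

# Metadata columns of a cohort table; everything else is a feature.
cohort_meta_cols <- function() {
  c("subject_id", "visit", "cohort_label", "age", "sex", "icv", "cdr",
    "mmse", "apoe_e4_count", "csf_ptau", "csf_ttau", "csf_abeta42")
}

#' Fit a confound-removal model on a control cohort
#'
#' For every feature, fits a penalized least-squares model
#' `feature ~ spline(age) + sex + ICV` with a low-rank thin-plate regression
#' spline basis for age and GCV-selected smoothing, jointly with the linear
#' terms. Residual mean and standard deviation on the fitting cohort are
#' stored so that downstream cohorts can be expressed as z-scores relative
#' to these controls.
#'
#' One model is fitted per dataset/site (keyed by `fit_cohort_id`) and never
#' shared across sites.
#'
#' @param controls Control cohort `data.frame` with `age`, `sex`, `icv` and
#'   feature columns.
#' @param features Feature columns to model; defaults to every non-metadata
#'   column.
#' @param basis_dim Dimension of the thin-plate spline basis for age.
#' @param fit_cohort_id Identifier of the fitting cohort/site.
#' @return An object of class `confound_model`.
#' @export
fit_confound_model <- function(controls,
                               features = setdiff(names(controls),
                                                  cohort_meta_cols()),
                               basis_dim = 10,
                               fit_cohort_id = "controls") {
  stopifnot(is.data.frame(controls), nrow(controls) > 0)
  need <- c("age", "sex", "icv")
  if (!all(need %in% names(controls))) {
    stop("controls must contain columns age, sex, icv")
  }
  if (nrow(controls) < basis_dim + 3) {
    stop("need at least basis_dim + 3 rows to fit the confound model")
  }
  Y <- cohort_features(controls, features)

  const <- apply(Y, 2, stats::sd) == 0
  if (any(const)) {
    warning("excluding constant features: ",
            paste(features[const], collapse = ", "))
    features <- features[!const]
    Y <- Y[, !const, drop = FALSE]
    if (ncol(Y) == 0) stop("no non-constant features left to fit")
  }

  sm <- mgcv::smoothCon(mgcv::s(age, bs = "tp", k = basis_dim),
                        data = data.frame(age = controls$age),
                        absorb.cons = TRUE)[[1]]
  X <- cbind(`(Intercept)` = 1, sex = controls$sex, icv = controls$icv,
             sm$X)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient confound design (constant covariate?)")
  }

  p_lin <- 3L
  coefs <- matrix(NA_real_, ncol(X), ncol(Y),
                  dimnames = list(colnames(X), colnames(Y)))
  sp <- numeric(ncol(Y))
  for (j in seq_len(ncol(Y))) {
    fit <- mgcv::magic(Y[, j], X, sp = -1, S = sm$S, off = p_lin + 1L,
                       gcv = TRUE)
    coefs[, j] <- fit$b
    sp[j] <- fit$sp
  }
  res <- Y - X %*% coefs
  control_mean <- colMeans(res)
  control_sd <- apply(res, 2, stats::sd)  # sample (n-1) sd
  bad <- control_sd <= 0
  if (any(bad)) {
    warning("rejecting features with zero residual sd: ",
            paste(features[bad], collapse = ", "))
    keep <- !bad
    features <- features[keep]
    coefs <- coefs[, keep, drop = FALSE]
    sp <- sp[keep]
    control_mean <- control_mean[keep]
    control_sd <- control_sd[keep]
  }
  structure(list(smooth = sm, features = features, coefficients = coefs,
                 sp = sp, control_mean = control_mean,
                 control_sd = control_sd,
                 age_range = range(controls$age), basis_dim = basis_dim,
                 n_fit = nrow(controls), fit_cohort_id = fit_cohort_id),
            class = "confound_model")
}

#' @export
print.confound_model <- function(x, ...) {
  cat(sprintf(paste0("<confound_model> %d features, age spline k=%d ",
                     "(ages %.1f-%.1f), fit on '%s' (n=%d)\n"),
              length(x$features), x$basis_dim, x$age_range[1],
              x$age_range[2], x$fit_cohort_id, x$n_fit))
  invisible(x)
}

# Design matrix for new covariates; ages beyond the fitted range use a
# linear extension of the spline beyond the boundary knots.
confound_design <- function(model, data) {
  r <- model$age_range
  age <- data$age
  clamped <- pmin(pmax(age, r[1]), r[2])
  Xs <- mgcv::PredictMat(model$smooth, data.frame(age = clamped))
  below <- age < r[1]; above <- age > r[2]
  if (any(below) || any(above)) {
    warning(sprintf("%d age value(s) outside the fitted range [%g, %g]; %s",
                    sum(below) + sum(above), r[1], r[2],
                    "using linear spline extension"))
    h <- max(1e-4, diff(r) * 1e-4)
    slope_at <- function(a) {
      (mgcv::PredictMat(model$smooth, data.frame(age = a)) -
         mgcv::PredictMat(model$smooth, data.frame(age = a - h))) / h
    }
    if (any(below)) {
      Xs[below, ] <- Xs[below, , drop = FALSE] +
        outer(age[below] - r[1], drop(slope_at(r[1] + h)))
    }
    if (any(above)) {
      Xs[above, ] <- Xs[above, , drop = FALSE] +
        outer(age[above] - r[2], drop(slope_at(r[2])))
    }
  }
  cbind(`(Intercept)` = 1, sex = data$sex, icv = data$icv, Xs)
}

#' Apply a fitted confound model
#'
#' Replaces each feature by its covariate-adjusted z-score: the residual
#' from the control-fitted prediction, centred on the control residual mean
#' and scaled by the control residual standard deviation.
#'
#' @param model A [fit_confound_model()] result.
#' @param data Cohort `data.frame` containing `age`, `sex`, `icv` and the
#'   model's feature columns.
#' @return `data` with feature columns replaced by adjusted z-scores.
#' @export
apply_confound_model <- function(model, data) {
  stopifnot(inherits(model, "confound_model"))
  Y <- cohort_features(data, model$features)
  X <- confound_design(model, data)
  res <- Y - X %*% model$coefficients
  z <- sweep(sweep(res, 2, model$control_mean), 2, model$control_sd, `/`)
  for (f in model$features) data[[f]] <- unname(z[, f])
  data
}

#' Save / load a confound model
#'
#' Serialized as a single self-describing file; a load round-trip restores
#' the model bit-exactly.
#'
#' @param model A `confound_model`.
#' @param path File path.
#' @export
save_confound_model <- function(model, path) {
  stopifnot(inherits(model, "confound_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_confound_model
#' @export
load_confound_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "confound_model"))
  model
}
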