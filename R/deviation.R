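# Deviation metrics referenced to the holdout control cohort.
#
# Both metrics are measured against untouched holdout controls rather than
# against the training data, so that deviation caused by residual model
# misfit (which affects holdout controls and clinical subjects alike) is
# absorbed into the reference statistics.

#' Fit the holdout reference for deviation scoring
#'
#' Estimates, from a holdout control cohort: the mean and covariance of the
#' shared latent posterior means (for the multivariate latent deviation
#' D_ml), and the per-feature mean and standard deviation of reconstruction
#' residuals (for the univariate feature deviation D_uf). The latent
#' covariance is ridge-regularized with `lambda = 1e-6 * trace / k_shared`
#' to guarantee invertibility.
#'
#' @param model A trained `normative_model`.
#' @param holdout Confound-adjusted holdout control cohort; must have more
#'   than `k_shared + 2` rows.
#' @param id Identifier recorded for provenance.
#' @return An object of class `holdout_reference`.
#' @export
fit_holdout_reference <- function(model, holdout, id = "holdout") {
  stopifnot(inherits(model, "normative_model"))
  ks <- model$k_s
  if (nrow(holdout) <= ks + 2) {
    stop("holdout too small: need more than k_shared + 2 subjects")
  }
  Z <- dmvae_encode(model, holdout)$shared
  mu_z <- colMeans(Z)
  sigma_z <- stats::cov(Z)
  lambda <- 1e-6 * sum(diag(sigma_z)) / ks
  sigma_z <- sigma_z + diag(lambda, ks)
  ch <- tryCatch(chol(sigma_z), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < sqrt(.Machine$double.eps))) {
    stop("degenerate latent covariance on the holdout cohort")
  }
  R <- reconstruction_residuals(model, holdout)
  mu_r <- colMeans(R)
  sd_r <- apply(R, 2, stats::sd)
  if (any(sd_r <= 0)) {
    stop("zero residual standard deviation on the holdout cohort")
  }
  structure(list(mu_z = mu_z, sigma_z = sigma_z, chol_z = ch,
                 mu_r = mu_r, sd_r = sd_r, id = id,
                 n = nrow(holdout), k_s = ks,
                 member_ids = as.character(holdout$subject_id), codes = Z),
            class = "holdout_reference")
}

#' @export
print.holdout_reference <- function(x, ...) {
  cat(sprintf(
    "<holdout_reference> '%s': n=%d, k_shared=%d, %d features\n",
    x$id, x$n, x$k_s, length(x$mu_r)))
  invisible(x)
}

#' Multivariate latent deviation from raw latent codes
#'
#' The Mahalanobis distance of each row of `Z` from the holdout latent
#' distribution: `sqrt((z - mu)' Sigma^{-1} (z - mu))`. Exposed separately
#' from [compute_dml()] so the metric can be applied to any latent matrix.
#'
#' @param Z Numeric matrix (subjects x k_shared) of shared latent codes.
#' @param ref A [fit_holdout_reference()] result (or any list with `mu_z`
#'   and `chol_z`).
#' @return Non-negative numeric vector, one value per row of `Z`.
#' @export
latent_dml <- function(Z, ref) {
  Z <- as.matrix(Z)
  if (ncol(Z) != length(ref$mu_z)) {
    stop("latent dimension mismatch with the reference")
  }
  D <- sweep(Z, 2, ref$mu_z)
  # solve against the Cholesky factor: ||L^-T d||^2 = d' Sigma^-1 d
  W <- backsolve(ref$chol_z, t(D), transpose = TRUE)
  sqrt(colSums(W^2))
}

#' Aggregate multivariate latent deviation (D_ml)
#'
#' Encodes each subject-visit row, combines the per-modality shared
#' posteriors, and measures the Mahalanobis distance of the shared code
#' from the holdout controls' latent distribution. Larger values mean a
#' brain pattern further from the healthy norm.
#'
#' A subject drawn from the reference cohort sits closer to a mean and
#' covariance that were estimated partly from that subject, so in-sample
#' distances are slightly deflated relative to new subjects. With
#' `exclude_self = TRUE`, any row whose `subject_id` belongs to the
#' reference cohort is scored against a reference re-estimated without that
#' subject (leave-one-subject-out), removing the deflation — important when
#' reference subjects are compared against their own follow-up visits.
#'
#' @param model A trained `normative_model`.
#' @param ref A [fit_holdout_reference()] result.
#' @param data Confound-adjusted cohort `data.frame`.
#' @param exclude_self Score reference-cohort members leave-one-subject-out
#'   (requires a `subject_id` column in `data`).
#' @return Non-negative numeric vector of D_ml values, one per row.
#' @export
compute_dml <- function(model, ref, data, exclude_self = FALSE) {
  stopifnot(inherits(ref, "holdout_reference"))
  Z <- dmvae_encode(model, data)$shared
  d <- latent_dml(Z, ref)
  if (exclude_self) {
    member <- which(as.character(data$subject_id) %in% ref$member_ids)
    for (i in member) {
      keep <- ref$member_ids != as.character(data$subject_id[i])
      Zk <- ref$codes[keep, , drop = FALSE]
      sigma <- stats::cov(Zk)
      sigma <- sigma + diag(1e-6 * sum(diag(sigma)) / ref$k_s, ref$k_s)
      loo <- list(mu_z = colMeans(Zk), chol_z = chol(sigma))
      d[i] <- latent_dml(Z[i, , drop = FALSE], loo)
    }
  }
  d
}

#' Per-feature univariate deviation (D_uf)
#'
#' Signed z-score of each feature's reconstruction residual against the
#' holdout controls' residual distribution:
#' `(residual - mu_r) / sd_r`. Because residuals are input minus
#' reconstruction, volume or FA loss relative to the norm gives a more
#' negative D_uf, while MD increase gives a more positive one.
#'
#' @inheritParams compute_dml
#' @return Numeric matrix (subjects x features) of D_uf values.
#' @export
compute_duf <- function(model, ref, data) {
  stopifnot(inherits(ref, "holdout_reference"))
  R <- reconstruction_residuals(model, data)
  if (!identical(colnames(R), names(ref$mu_r))) {
    stop("feature mismatch between model output and reference")
  }
  sweep(sweep(R, 2, ref$mu_r), 2, ref$sd_r, `/`)
}

#' Compute both deviation metrics for a cohort
#'
#' @inheritParams compute_dml
#' @return A `data.frame` with `subject_id`, `visit`, `d_ml`, and one D_uf
#'   column per feature (named as the feature), with the reference id
#'   recorded as an attribute.
#' @export
compute_deviations <- function(model, ref, data, exclude_self = FALSE) {
  duf <- compute_duf(model, ref, data)
  out <- data.frame(subject_id = data$subject_id, visit = data$visit,
                    d_ml = compute_dml(model, ref, data,
                                       exclude_self = exclude_self),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(duf, check.names = FALSE))
  attr(out, "reference_id") <- ref$id
  out
}

#' Write a deviation table as delimited text
#'
#' @param deviations Result of [compute_deviations()].
#' @param path CSV file path.
#' @export
write_deviations <- function(deviations, path) {
  utils::write.csv(deviations, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
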