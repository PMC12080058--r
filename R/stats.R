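# Group-level inference: age-adjusted biomarker correlations, multiplicity
# control, effect sizes, and group/longitudinal t-tests. All tests are
# two-sided; missing data are handled by pairwise-complete deletion with the
# n actually used reported alongside every estimate.

#' Age-adjust biomarkers with control-fitted coefficients
#'
#' Fits, on the control cohort only, a linear regression of each biomarker
#' on age, and removes that fitted age effect (slope and intercept) from all
#' rows — controls and cases alike. Cases whose true age slope differs from
#' the controls' therefore retain a residual age association, by design.
#'
#' @param data `data.frame` containing `age` and the biomarker columns.
#' @param controls Control `data.frame` with the same columns (>= 3
#'   complete rows per biomarker).
#' @param biomarkers Character vector of biomarker column names.
#' @return `data` with the biomarker columns replaced by residuals.
#' @export
age_adjust <- function(data, controls,
                       biomarkers = c("csf_ptau", "csf_ttau",
                                      "csf_abeta42")) {
  stopifnot(nrow(controls) > 0, "age" %in% names(data),
            all(biomarkers %in% names(data)),
            all(biomarkers %in% names(controls)))
  for (b in biomarkers) {
    ok <- stats::complete.cases(controls[[b]], controls$age)
    if (sum(ok) < 3) stop("need >= 3 complete control rows for ", b)
    fit <- stats::lm(controls[[b]][ok] ~ controls$age[ok])
    beta <- stats::coef(fit)
    data[[b]] <- data[[b]] - (beta[1] + beta[2] * data$age)
  }
  data
}

#' Pearson correlation with sample size
#'
#' Pearson correlation between a deviation score and a (typically
#' age-adjusted) target variable, with pairwise deletion of missing values
#' and the number of complete pairs reported.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p` (two-sided), `n`.
#' @export
correlate <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 complete pairs")
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, m >= 1)
  alpha / m
}

#' Cohen's d effect size (pooled standard deviation)
#'
#' `d = (mean(group) - mean(controls)) / s_pooled`, with the pooled
#' standard deviation using n-1 weighting. With D_uf as the input, a
#' positive d means the subgroup has higher D_uf than controls and a
#' negative d lower (e.g. regional volume loss).
#'
#' @param group,controls Numeric vectors (each length >= 2).
#' @return Cohen's d.
#' @export
cohens_d <- function(group, controls) {
  n1 <- length(group); n2 <- length(controls)
  if (n1 < 2 || n2 < 2) stop("both groups need >= 2 observations")
  sp <- sqrt(((n1 - 1) * stats::var(group) +
                (n2 - 1) * stats::var(controls)) / (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  (mean(group) - mean(controls)) / sp
}

#' Welch's unequal-variance t-test
#'
#' @param a,b Numeric vectors.
#' @return List with `t`, `df` (Welch-Satterthwaite), `p` (two-sided),
#'   `n` (c(length(a), length(b)) after NA removal).
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = c(length(a), length(b)))
}

#' Paired t-test between baseline and follow-up
#'
#' One-sample t-test on the within-subject differences
#' `followup - baseline`, two-sided.
#'
#' @param baseline,followup Numeric vectors of matched pairs.
#' @return List with `t`, `df`, `p`, `n` (complete pairs),
#'   `mean_diff`.
#' @export
paired_t <- function(baseline, followup) {
  stopifnot(length(baseline) == length(followup))
  ok <- stats::complete.cases(baseline, followup)
  d <- followup[ok] - baseline[ok]
  if (length(d) < 2) stop("need at least 2 complete pairs")
  if (stats::var(d) == 0) {
    if (all(d == 0)) {  # no change at all: t = 0 by continuity
      return(list(t = 0, df = length(d) - 1, p = 1, n = length(d),
                  mean_diff = 0))
    }
    stop("zero variance of paired differences")
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = length(d), mean_diff = mean(d))
}

#' Correlate a deviation score with biomarkers and cognition
#'
#' Convenience wrapper producing the tidy table the analysis reports:
#' one row per target variable with the Pearson r, two-sided p, and the
#' number of complete pairs used (pairwise deletion, so n varies by
#' target).
#'
#' @param score Numeric deviation score (e.g. D_ml), aligned with `data`
#'   rows.
#' @param data `data.frame` holding the target columns.
#' @param targets Character vector of target column names.
#' @return data.frame with `variable`, `r`, `p`, `n`.
#' @export
deviation_correlations <- function(score, data,
                                   targets = c("csf_ptau", "csf_ttau",
                                               "csf_abeta42",
                                               "ptau_abeta42_ratio",
                                               "cdr", "mmse")) {
  rows <- lapply(targets, function(v) {
    ct <- correlate(score, data[[v]])
    data.frame(variable = v, r = ct$r, p = ct$p, n = ct$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Add the p-tau/abeta42 ratio column
#'
#' @param data `data.frame` with `csf_ptau` and `csf_abeta42`.
#' @return `data` with a `ptau_abeta42_ratio` column (NA when either
#'   concentration is missing).
#' @export
add_ptau_abeta_ratio <- function(data) {
  data$ptau_abeta42_ratio <- data$csf_ptau / data$csf_abeta42
  data
}
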