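# Directional outlier flagging and group-level outlier statistics.
#
# A region is an outlier for a subject when its D_uf crosses 1.96 in the
# direction of expected disease-related change: below -1.96 for grey-matter
# volumes and FA (loss), above +1.96 for MD (increase). 1.96 is the 2.5%
# tail of the standard normal, so a calibrated D_uf yields ~2.5% outliers
# per region among controls.

#' Flag directional outliers in a D_uf matrix
#'
#' @param duf Numeric matrix (subjects x features) of D_uf values, or a
#'   vector for a single subject.
#' @param modalities Named list of [modality_spec()] covering every feature
#'   (the spec's `outlier_tail` sets the direction).
#' @param threshold Outlier threshold on |D_uf| (default 1.96). The
#'   inequality is strict: a value exactly at the threshold is not an
#'   outlier.
#' @return Logical matrix of the same shape as `duf`.
#' @export
flag_outliers <- function(duf, modalities = default_modalities(),
                          threshold = 1.96) {
  if (is.null(dim(duf))) duf <- matrix(duf, 1, dimnames = list(NULL, names(duf)))
  feats <- colnames(duf)
  if (is.null(feats)) stop("duf must have feature column names")
  idx <- spec_for_features(feats, modalities)
  tails <- vapply(modalities, `[[`, "", "outlier_tail")[idx]
  flags <- matrix(FALSE, nrow(duf), ncol(duf),
                  dimnames = dimnames(duf))
  lower <- tails == "lower"
  flags[, lower] <- duf[, lower, drop = FALSE] < -threshold
  flags[, !lower] <- duf[, !lower, drop = FALSE] > threshold
  flags
}

#' Per-region outlier proportions for a stratum
#'
#' @param flags Logical matrix (subjects x features) from [flag_outliers()],
#'   already restricted to the stratum's rows.
#' @param stratum Label for the stratum (e.g. `"CDR=0.5"`).
#' @return An object of class `outlier_map`: data.frame with `stratum`,
#'   `feature`, `proportion`, `n`.
#' @export
outlier_proportions <- function(flags, stratum = "all") {
  if (nrow(flags) == 0) stop("empty stratum")
  out <- data.frame(stratum = stratum, feature = colnames(flags),
                    proportion = colMeans(flags), n = nrow(flags),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("outlier_map", class(out))
  out
}

# Subject x network matrix: TRUE when the subject is an outlier in at least
# one region assigned to the network.
network_hits <- function(flags, parcellation) {
  feats <- intersect(colnames(flags), names(parcellation))
  if (length(feats) == 0) stop("parcellation covers none of the features")
  nets <- sort(unique(parcellation[feats]))
  hits <- vapply(nets, function(nw) {
    member <- feats[parcellation[feats] == nw]
    rowSums(flags[, member, drop = FALSE]) > 0
  }, logical(nrow(flags)))
  if (is.null(dim(hits))) hits <- matrix(hits, 1, dimnames = list(NULL, nets))
  hits
}

#' Network-level outlier rates
#'
#' For each network, the proportion of subjects in the stratum whose D_uf
#' crossed the threshold in at least one region assigned to that network
#' (each subject counts once per network however many member regions are
#' flagged).
#'
#' @inheritParams outlier_proportions
#' @param parcellation Named character vector `network[feature]`, e.g. from
#'   [read_parcellation()]. Features absent from the parcellation are
#'   ignored.
#' @return data.frame with `stratum`, `network`, `rate`, `n`.
#' @export
network_outlier_rate <- function(flags, parcellation, stratum = "all") {
  if (nrow(flags) == 0) stop("empty stratum")
  hits <- network_hits(flags, parcellation)
  data.frame(stratum = stratum, network = colnames(hits),
             rate = colMeans(hits), n = nrow(flags),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group-label permutation test for outlier rates
#'
#' Tests whether case outlier rates (network-level, and optionally
#' per-region) exceed what random assignment of the case/control labels
#' would produce. Group labels are permuted `n_perm` times; the empirical
#' p-value uses add-one smoothing with ties counted as exceeding
#' (conservative): `p = (1 + #permuted rate >= observed) / (n_perm + 1)`.
#'
#' @param case_flags,control_flags Logical outlier matrices
#'   (subjects x features) for the two groups.
#' @param parcellation Named character vector `network[feature]`.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed for the permutation draws.
#' @param regions If `TRUE`, also return per-region permutation p-values
#'   computed from the same permutation draws.
#' @return List with `network`: data.frame (`network`, `observed_rate`,
#'   `p`, `p_fdr`) and, when requested, `region`: data.frame (`feature`,
#'   `observed_proportion`, `p`, `p_fdr`).
#' @export
permutation_test <- function(case_flags, control_flags, parcellation,
                             n_perm = 10000, seed = 1L, regions = FALSE) {
  if (nrow(case_flags) == 0 || nrow(control_flags) == 0) {
    stop("both groups must be non-empty")
  }
  if (n_perm < 100) warning("n_perm < 100 gives very coarse p-values")
  flags <- rbind(case_flags, control_flags)
  n_case <- nrow(case_flags)
  n <- nrow(flags)

  hits <- network_hits(flags, parcellation)
  obs_net <- colMeans(hits[seq_len(n_case), , drop = FALSE])

  perm_idx <- with_seed(seed, {
    lapply(seq_len(n_perm), function(i) sample.int(n, n_case))
  })
  null_net <- vapply(perm_idx, function(ix)
    colMeans(hits[ix, , drop = FALSE]), numeric(ncol(hits)))
  if (is.null(dim(null_net))) null_net <- matrix(null_net, 1)
  p_net <- (1 + rowSums(null_net >= obs_net)) / (n_perm + 1)

  out <- list(network = data.frame(
    network = colnames(hits), observed_rate = obs_net, p = p_net,
    p_fdr = fdr_correct(p_net), row.names = NULL,
    stringsAsFactors = FALSE))

  if (regions) {
    obs_reg <- colMeans(case_flags)
    null_reg <- vapply(perm_idx, function(ix)
      colMeans(flags[ix, , drop = FALSE]), numeric(ncol(flags)))
    if (is.null(dim(null_reg))) null_reg <- matrix(null_reg, 1)
    p_reg <- (1 + rowSums(null_reg >= obs_reg)) / (n_perm + 1)
    out$region <- data.frame(feature = colnames(flags),
                             observed_proportion = obs_reg, p = p_reg,
                             p_fdr = fdr_correct(p_reg), row.names = NULL,
                             stringsAsFactors = FALSE)
  }
  out
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values: monotone, capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
fdr_correct <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
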