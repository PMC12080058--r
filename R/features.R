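#' Modality specification
#'
#' Declares a named block of features belonging to one imaging modality and
#' the tail in which disease-related change is expected. Grey-matter volumes
#' (T1) and fractional anisotropy (FA) decrease with neurodegeneration, so
#' their outlier tail is the lower one; mean diffusivity (MD) increases, so
#' its tail is the upper one.
#'
#' @param name Modality name, one of `"T1"`, `"FA"`, `"MD"`.
#' @param features Character vector of feature (column) names.
#' @param outlier_tail `"lower"` or `"upper"`. Defaults to the conventional
#'   direction for the named modality.
#' @return An object of class `modality_spec`.
#' @export
modality_spec <- function(name, features,
                          outlier_tail = c(T1 = "lower", FA = "lower",
                                           MD = "upper")[[name]]) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(features), length(features) > 0L)
  outlier_tail <- match.arg(outlier_tail, c("lower", "upper"))
  structure(list(name = name, features = features,
                 outlier_tail = outlier_tail),
            class = "modality_spec")
}

#' @export
print.modality_spec <- function(x, ...) {
  cat(sprintf("<modality_spec> %s: %d features, %s-tail outliers\n",
              x$name, length(x$features), x$outlier_tail))
  invisible(x)
}

# Desikan-Killiany cortical parcels used per hemisphere (33, excluding the
# temporal pole, giving the conventional 66-region cortical set).
dk_cortical_parcels <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal",
    "transversetemporal")
}

# Subcortical grey-matter structures (8 per hemisphere, 16 total).
aseg_subcortical <- function() {
  structs <- c("Thalamus", "Caudate", "Putamen", "Pallidum", "Hippocampus",
               "Amygdala", "Accumbens-area", "VentralDC")
  c(paste0("Left-", structs), paste0("Right-", structs))
}

# White-matter tract labels (JHU-style): 15 bilateral pairs plus the forceps
# minor and major, 32 tracts in total.
wm_tracts <- function() {
  pairs <- c("ATR", "CST", "CGC", "CGH", "FX_ST", "IFOF", "ILF", "SLF",
             "UNC", "PTR", "ACR", "SCR", "PCR", "EC", "SS")
  c(as.vector(t(outer(pairs, c("_L", "_R"), paste0))), "FMI", "FMA")
}

#' Default modality specifications
#'
#' The standard feature layout: 82 T1 grey-matter volumes (66 cortical
#' Desikan-Killiany parcels + 16 subcortical structures), and FA and MD
#' values for 32 white-matter tracts.
#'
#' @return Named list of three [modality_spec()] objects (`T1`, `FA`, `MD`).
#' @export
default_modalities <- function() {
  cortical <- c(paste0("lh_", dk_cortical_parcels()),
                paste0("rh_", dk_cortical_parcels()))
  t1 <- c(cortical, aseg_subcortical())
  fa <- paste0("FA_", wm_tracts())
  md <- paste0("MD_", wm_tracts())
  list(T1 = modality_spec("T1", t1),
       FA = modality_spec("FA", fa),
       MD = modality_spec("MD", md))
}

#' All feature names of a modality list
#'
#' @param modalities List of [modality_spec()] objects.
#' @return Character vector of all feature names, in modality order.
#' @export
feature_names <- function(modalities) {
  unlist(lapply(modalities, `[[`, "features"), use.names = FALSE)
}

# Look up which modality spec covers a feature; errors if uncovered.
spec_for_features <- function(features, modalities) {
  idx <- rep(NA_integer_, length(features))
  for (m in seq_along(modalities)) {
    idx[features %in% modalities[[m]]$features] <- m
  }
  if (anyNA(idx)) {
    stop("features without a modality spec: ",
         paste(features[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Read a region-to-network parcellation mapping
#'
#' Reads a two-column delimited file (feature name, network label) assigning
#' each grey-matter region to one of the seven Yeo cortical functional
#' networks or, for subcortical structures, to the medial temporal lobe,
#' Thalamus or Basal Ganglia group.
#'
#' @param path Path to a tab- or comma-delimited file with columns
#'   `feature` and `network`. Defaults to the mapping bundled with the
#'   package (an approximate majority-overlap Desikan-Killiany-to-Yeo
#'   crosswalk).
#' @return Named character vector: `network[feature]`.
#' @export
read_parcellation <- function(path = system.file("extdata",
                                                 "dk_yeo7_parcellation.tsv",
                                                 package = "normdev")) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("feature", "network") %in% names(tab))) {
    stop("parcellation file must have columns 'feature' and 'network'")
  }
  if (anyDuplicated(tab$feature)) {
    stop("duplicate feature in parcellation file")
  }
  stats::setNames(tab$network, tab$feature)
}
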