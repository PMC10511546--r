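# Desikan-Killiany parcellation labels and the morphometric feature panel.

.dk_base <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula"
)

#' Desikan-Killiany cortical region labels
#'
#' The 68 cortical regions (34 per hemisphere) of the Desikan-Killiany
#' atlas, prefixed `lh_` / `rh_`, in the fixed order used throughout the
#' package (all lexicographic edge orderings refer to this order).
#'
#' @return Character vector of length 68.
#' @export
dk_regions <- function() {
  c(paste0("lh_", .dk_base), paste0("rh_", .dk_base))
}

#' Morphometric feature names
#'
#' The seven Freesurfer-style regional morphometry features used to build
#' feature sets and morphometric similarity networks.
#'
#' @return Character vector of length 7.
#' @export
morph_features <- function() {
  c("surface_area", "curvature_index", "folding_index", "gaussian_curvature",
    "mean_curvature", "cortical_thickness", "cortical_volume")
}

#' Spatial QA metric names
#'
#' Six spatial anatomical image-quality metrics attached to each subject.
#' `efc` (entropy focus criterion) is the motion proxy used by the
#' Brainage-delta bias screen. The `higher_better` attribute records each
#' metric's quality orientation before within-site re-signing.
#'
#' @return Character vector of length 6 with a logical `higher_better`
#'   attribute.
#' @export
qa_metrics <- function() {
  m <- c("cnr", "efc", "fber", "fwhm", "qi1", "snr")
  attr(m, "higher_better") <-
    c(cnr = TRUE, efc = FALSE, fber = TRUE, fwhm = FALSE, qi1 = FALSE,
      snr = TRUE)
  m
}

# column names of the wide morphometry layout: <region>__<feature>
.morph_columns <- function() {
  feats <- morph_features()
  regs <- dk_regions()
  as.vector(vapply(feats, function(f) paste0(regs, "__", f),
                   character(length(regs))))
}
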