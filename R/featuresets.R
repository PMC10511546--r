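# Assembly of the ten feature sets used for Brainage modelling: the seven
# individual morphometric features (68 regional values each), all
# individual features concatenated (476), MSN nodal strength (68), MSN
# edge weights (2278), plus arbitrary combinations.

#' Names of the canonical feature sets
#'
#' @return Character vector of the ten feature-set names.
#' @export
feature_set_names <- function() {
  c(morph_features(), "all_individual", "msn_nodal_strength",
    "msn_edge_weights")
}

#' Assemble a named feature set
#'
#' Builds the subjects x n_features design matrix for one feature set:
#' 68 columns for a single morphometric feature or MSN nodal strength,
#' 476 for all individual features, 2278 for MSN edge weights, and the
#' concatenation of the parts for `"combined"`.
#'
#' @param name One of [feature_set_names()] or `"combined"`.
#' @param morphometry Wide (harmonised) morphometry tibble.
#' @param msns Named list of `msn_graph` (required for MSN-based sets),
#'   as returned by [build_cohort_msns()].
#' @param parts For `name = "combined"`: character vector of set names to
#'   concatenate, e.g. `c("cortical_thickness", "cortical_volume",
#'   "msn_edge_weights")`.
#' @param masked_edges Use mask-zeroed edge weights (after density
#'   thresholding) instead of raw weights for `msn_edge_weights`.
#' @return Numeric matrix, rows ordered and named as
#'   `morphometry$subject_id`.
#' @export
assemble_feature_set <- function(name, morphometry, msns = NULL,
                                 parts = NULL, masked_edges = FALSE) {
  ids <- morphometry$subject_id
  if (name %in% morph_features()) {
    cols <- paste0(dk_regions(), "__", name)
    x <- as.matrix(morphometry[cols])
  } else if (name == "all_individual") {
    x <- as.matrix(morphometry[.morph_columns()])
  } else if (name %in% c("msn_nodal_strength", "msn_edge_weights")) {
    if (is.null(msns)) stop("MSN graphs required for feature set ", name,
                            call. = FALSE)
    if (!all(ids %in% names(msns))) {
      stop("missing MSN graph for some subjects", call. = FALSE)
    }
    if (name == "msn_nodal_strength") {
      x <- t(vapply(ids, function(s) msns[[s]]$strength, numeric(68)))
      colnames(x) <- dk_regions()
    } else {
      x <- t(vapply(ids, function(s) {
        vectorize_edges(msns[[s]], masked = masked_edges)
      }, numeric(2278)))
    }
  } else if (name == "combined") {
    if (is.null(parts) || length(parts) < 2) {
      stop("combined feature set needs >= 2 part names", call. = FALSE)
    }
    x <- do.call(cbind, lapply(parts, function(p) {
      assemble_feature_set(p, morphometry, msns,
                           masked_edges = masked_edges)
    }))
  } else {
    stop("unknown feature set: ", name, call. = FALSE)
  }
  rownames(x) <- ids
  x
}
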