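# Morphometric similarity networks: per-subject correlation graphs over
# the 68 Desikan-Killiany regions, built from region-wise z-scored feature
# profiles, with optional density thresholding and degree/strength metrics.

#' Z-score morphometric features across regions
#'
#' Demeans and SD-scales each feature column across the 68 regions of one
#' subject's region-by-feature matrix, so that the length-7 regional
#' profiles are comparable across features before correlation.
#'
#' @param values Numeric 68 x 7 matrix (regions x features).
#' @param subject_id Optional id used in error messages.
#' @return Matrix of the same shape; each column has mean 0, SD 1.
#' @export
zscore_across_regions <- function(values, subject_id = NULL) {
  values <- as.matrix(values)
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(values)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("zero SD across regions for feature %s%s",
                 paste(bad, collapse = ", "),
                 if (is.null(subject_id)) "" else
                   paste0(" (subject ", subject_id, ")")),
         call. = FALSE)
  }
  scale(values, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' Build a subject's morphometric similarity network
#'
#' Edges are Pearson correlations between the z-scored length-7 feature
#' vectors of every pair of regions. The graph starts unthresholded: the
#' mask keeps every off-diagonal edge and each node's degree is 67.
#'
#' @param normalized 68 x 7 matrix from [zscore_across_regions()].
#' @param subject_id Optional subject identifier carried on the graph.
#' @return Object of class `msn_graph` with fields `weights` (symmetric
#'   correlation matrix, unit diagonal), `mask`, `density`, `degree`,
#'   `strength`, `global_strength`.
#' @export
build_msn <- function(normalized, subject_id = NULL) {
  normalized <- as.matrix(normalized)
  p <- nrow(normalized)
  row_sd <- apply(normalized, 1, stats::sd)
  if (any(row_sd == 0)) {
    bad <- rownames(normalized)[row_sd == 0]
    if (is.null(bad)) bad <- which(row_sd == 0)
    stop("zero-variance region feature vector: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  w <- stats::cor(t(normalized))
  mask <- matrix(TRUE, p, p)
  diag(mask) <- FALSE
  dimnames(mask) <- dimnames(w)
  g <- structure(list(
    subject_id = subject_id,
    weights = w,
    mask = mask,
    density = "unthresholded",
    degree = NULL, strength = NULL, global_strength = NULL
  ), class = "msn_graph")
  s <- nodal_strength(g)
  g$degree <- s$degree
  g$strength <- s$strength
  g$global_strength <- s$global_strength
  g
}

# lexicographic (i < j, ordered by i then j) upper-triangle index pairs
.edge_pairs <- function(p) {
  i <- rep(seq_len(p - 1), times = (p - 1):1)
  j <- unlist(lapply(seq_len(p - 1), function(k) (k + 1):p))
  cbind(i = i, j = j)
}

#' Vectorise MSN edge weights
#'
#' Upper-triangle (i < j) edge weights in fixed lexicographic region
#' order: (1,2), (1,3), ..., (1,p), (2,3), ... For the 68-region atlas the
#' vector has length 68*67/2 = 2278.
#'
#' @param g An `msn_graph`.
#' @param masked If `TRUE`, edges removed by thresholding are set to 0.
#' @return Named numeric vector of length p(p-1)/2.
#' @export
vectorize_edges <- function(g, masked = FALSE) {
  w <- g$weights
  p <- nrow(w)
  pairs <- .edge_pairs(p)
  v <- w[pairs]
  if (masked) v[!g$mask[pairs]] <- 0
  if (!is.null(rownames(w))) {
    names(v) <- paste(rownames(w)[pairs[, 1]], rownames(w)[pairs[, 2]],
                      sep = "--")
  }
  v
}

#' Reassemble a weight matrix from a vectorised edge list
#'
#' Inverse of [vectorize_edges()] (unit diagonal).
#'
#' @param v Edge vector of length p(p-1)/2.
#' @return Symmetric p x p matrix.
#' @export
edges_to_matrix <- function(v) {
  p <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (p != round(p)) stop("edge vector length is not p(p-1)/2",
                          call. = FALSE)
  pairs <- .edge_pairs(p)
  w <- diag(1, p)
  w[pairs] <- v
  w[pairs[, c(2, 1)]] <- v
  w
}

#' Threshold an MSN at a target edge density
#'
#' Retains the `round(density * n_edges)` edges of largest absolute
#' weight (signed weights are kept; `round` is round-half-even). Ties are
#' broken deterministically by (|w| descending, then i, then j). Degree is
#' recomputed as the surviving-edge count; strengths are recomputed when
#' every node keeps at least one edge, otherwise set to `NA` (use
#' [nodal_strength()] to turn that into an error).
#'
#' @param g An `msn_graph`.
#' @param density Proportion of edges to keep, in (0, 1].
#' @return A new `msn_graph` with the mask applied.
#' @export
threshold_by_density <- function(g, density) {
  if (!is.numeric(density) || length(density) != 1 ||
      density <= 0 || density > 1) {
    stop("density must lie in (0, 1]", call. = FALSE)
  }
  p <- nrow(g$weights)
  pairs <- .edge_pairs(p)
  w <- g$weights[pairs]
  m <- as.integer(round(density * nrow(pairs)))
  ord <- order(-abs(w), pairs[, 1], pairs[, 2])
  keep <- ord[seq_len(m)]
  mask <- matrix(FALSE, p, p)
  mask[pairs[keep, , drop = FALSE]] <- TRUE
  mask[pairs[keep, c(2, 1), drop = FALSE]] <- TRUE
  dimnames(mask) <- dimnames(g$weights)
  out <- g
  out$mask <- mask
  out$density <- density
  out$degree <- rowSums(mask)
  if (all(out$degree >= 1)) {
    s <- nodal_strength(out)
    out$strength <- s$strength
    out$global_strength <- s$global_strength
  } else {
    out$strength <- rep(NA_real_, p)
    out$global_strength <- NA_real_
  }
  out
}

#' Normalised nodal strength and global strength
#'
#' Strength of node i is the sum of its surviving edge weights divided by
#' its degree (its mean surviving edge weight); global strength is the
#' mean nodal strength across the network.
#'
#' @param g An `msn_graph`.
#' @return List with `degree`, `strength`, `global_strength`.
#' @export
nodal_strength <- function(g) {
  degree <- rowSums(g$mask)
  if (any(degree == 0)) {
    bad <- rownames(g$mask)[degree == 0]
    if (is.null(bad)) bad <- which(degree == 0)
    stop("zero-degree node(s) after thresholding: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  strength <- rowSums(g$weights * g$mask) / degree
  list(degree = degree, strength = strength,
       global_strength = mean(strength))
}

#' Build MSNs for every subject of a morphometry table
#'
#' @param morphometry Wide (harmonised) morphometry tibble.
#' @return Named list of `msn_graph`, one per subject, in table order.
#' @export
build_cohort_msns <- function(morphometry) {
  graphs <- lapply(morphometry$subject_id, function(s) {
    m <- subject_matrix(morphometry, s)
    build_msn(zscore_across_regions(m, subject_id = s), subject_id = s)
  })
  names(graphs) <- morphometry$subject_id
  graphs
}

#' Export one MSN as a square CSV and an edge-list TSV
#'
#' @param g An `msn_graph`.
#' @param matrix_path,edges_path Output file paths (either may be `NULL`).
#' @return Invisibly, the edge-list tibble.
#' @export
write_msn <- function(g, matrix_path = NULL, edges_path = NULL) {
  if (!is.null(matrix_path)) {
    utils::write.csv(as.data.frame(g$weights), matrix_path)
  }
  pairs <- .edge_pairs(nrow(g$weights))
  edges <- tibble::tibble(
    region_i = rownames(g$weights)[pairs[, 1]],
    region_j = rownames(g$weights)[pairs[, 2]],
    weight = g$weights[pairs],
    surviving = g$mask[pairs]
  )
  if (!is.null(edges_path)) {
    utils::write.table(edges, edges_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(edges)
}
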