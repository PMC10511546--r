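# Radial-basis kernels and Gram-matrix machinery shared by the GPR and
# RVR age models. Conventions follow the common R kernel-method usage:
# rbfdot k(x, x') = exp(-sigma ||x - x'||^2), laplacedot
# k(x, x') = exp(-sigma ||x - x'||); both satisfy k(x, x) = 1.

#' Kernel specification
#'
#' @param name `"laplacedot"` (Laplace radial basis) or `"rbfdot"`
#'   (Gaussian radial basis).
#' @param sigma Positive bandwidth, or `"auto"` to resolve it with the
#'   median heuristic on the training inputs at fit time.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(name = c("laplacedot", "rbfdot"), sigma = "auto") {
  name <- match.arg(name)
  if (!identical(sigma, "auto")) {
    if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
      stop("sigma must be a positive number or \"auto\"", call. = FALSE)
    }
  }
  structure(list(name = name, sigma = sigma), class = "kernel_spec")
}

#' Evaluate a kernel on a pair of vectors
#'
#' @param spec A [kernel_spec()] with numeric `sigma`.
#' @param x,y Equal-length numeric vectors.
#' @return Scalar similarity in (0, 1].
#' @export
eval_kernel <- function(spec, x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (identical(spec$sigma, "auto")) {
    stop("sigma is unresolved; fit a model or supply a numeric sigma",
         call. = FALSE)
  }
  d2 <- sum((x - y)^2)
  switch(spec$name,
         rbfdot = exp(-spec$sigma * d2),
         laplacedot = exp(-spec$sigma * sqrt(d2)))
}

# squared Euclidean cross-distances, clipped at 0 for numerical safety
.sqdist <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  pmax(d2, 0)
}

#' Gram / cross-kernel matrix
#'
#' @param spec A [kernel_spec()] with numeric `sigma`.
#' @param X,Y Row-wise input matrices (`Y` defaults to `X`).
#' @return `nrow(X)` x `nrow(Y)` kernel matrix.
#' @export
kernel_matrix <- function(spec, X, Y = X) {
  if (identical(spec$sigma, "auto")) {
    stop("sigma is unresolved; resolve it with median_heuristic_sigma()",
         call. = FALSE)
  }
  d2 <- .sqdist(as.matrix(X), as.matrix(Y))
  switch(spec$name,
         rbfdot = exp(-spec$sigma * d2),
         laplacedot = exp(-spec$sigma * sqrt(d2)))
}

#' Median-heuristic kernel bandwidth
#'
#' sigma = 1 / median(||x - x'||^2) over pairs of training rows for the
#' Gaussian kernel, and 1 / median(||x - x'||) for the Laplace kernel.
#' For large n a deterministic evenly spaced subsample of rows (no RNG)
#' caps the pair count.
#'
#' @param spec A [kernel_spec()].
#' @param X Training input matrix.
#' @param max_rows Upper bound on rows entering the pairwise median.
#' @return The spec with `sigma` resolved to a number.
#' @export
median_heuristic_sigma <- function(spec, X, max_rows = 256) {
  if (!identical(spec$sigma, "auto")) return(spec)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need >= 2 rows to resolve sigma", call. = FALSE)
  idx <- if (n > max_rows) unique(round(seq(1, n, length.out = max_rows)))
  else seq_len(n)
  d2 <- .sqdist(X[idx, , drop = FALSE], X[idx, , drop = FALSE])
  d2 <- d2[upper.tri(d2)]
  med <- switch(spec$name,
                rbfdot = stats::median(d2),
                laplacedot = stats::median(sqrt(d2)))
  if (med <= 0) med <- mean(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) {
    stop("degenerate inputs: all pairwise distances are zero",
         call. = FALSE)
  }
  spec$sigma <- 1 / med
  spec
}

# column standardisation helpers shared by both models
.fit_standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1   # constant column / single row
  list(center = ctr, scale = scl)
}
.apply_standardizer <- function(std, X) {
  sweep(sweep(X, 2, std$center), 2, std$scale, "/")
}
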