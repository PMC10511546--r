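# Kernel age-regression models: Gaussian process regression (dual-weight
# form) and relevance vector regression (sparse Bayesian learning over
# the kernel basis).

#' Fit a Gaussian process regression age model
#'
#' Inputs are column-standardised with training means/SDs, the kernel
#' bandwidth is resolved by the median heuristic when `sigma = "auto"`,
#' and the response is standardised to zero mean and unit variance (so
#' predictions revert to the training mean, not to zero, away from the
#' data and in the large-noise limit). The dual weights
#' `alpha = (K + noise_var I)^{-1} ytilde` are obtained by a Cholesky
#' solve with a small jitter on the Gram diagonal; the posterior mean at
#' new inputs is `ybar + ysd * k(X*, X) alpha`.
#'
#' `noise_var` is expressed on the unit-variance response scale; the
#' default of 1 (noise variance equal to the unit prior variance of the
#' kernel, which has k(x, x) = 1) matches the default regularisation of
#' the kernel toolkits this literature uses and keeps the model well
#' away from interpolation.
#'
#' @param X Training inputs (subjects x features).
#' @param y Training ages (years).
#' @param kernel A [kernel_spec()].
#' @param noise_var Observation noise variance on the standardised
#'   response scale, added to the Gram diagonal.
#' @param jitter Extra diagonal jitter for numerical stability.
#' @param standardize Column-standardise inputs (default `TRUE`).
#' @return Object of class `gpr_model`.
#' @export
fit_gpr <- function(X, y, kernel = kernel_spec("rbfdot"),
                    noise_var = 1, jitter = 1e-8,
                    standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 1 || length(y) != n) stop("X and y sizes disagree", call. = FALSE)
  std <- if (standardize) .fit_standardizer(X) else NULL
  Xs <- if (standardize) .apply_standardizer(std, X) else X
  kernel <- median_heuristic_sigma(kernel, Xs)
  K <- kernel_matrix(kernel, Xs)
  A <- K + diag(noise_var + jitter, n)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    stop("Gram matrix not positive definite after jitter", call. = FALSE)
  }
  ybar <- mean(y)
  ysd <- stats::sd(y)
  if (is.na(ysd) || ysd == 0) ysd <- 1      # constant / single-point y
  alpha <- backsolve(ch, forwardsolve(t(ch), (y - ybar) / ysd))
  structure(list(
    algorithm = "GPR",
    kernel = kernel,
    Xtrain = Xs,
    std = std,
    ybar = ybar,
    ysd = ysd,
    alpha = as.numeric(alpha),
    noise_var = noise_var
  ), class = c("gpr_model", "kernel_age_model"))
}

#' Fit a relevance vector regression age model
#'
#' Sparse Bayesian regression over the kernel basis (one basis function
#' per training point): iterates the per-weight precision and noise
#' updates of the evidence framework, pruning basis functions whose
#' precision exceeds `prune_threshold`. The retained (relevance) vectors
#' are a subset of the training set.
#'
#' @inheritParams fit_gpr
#' @param max_iter Maximum update iterations.
#' @param tol Convergence tolerance on the maximum relative change of
#'   the active log-precisions.
#' @param prune_threshold Precision above which a basis function is
#'   removed.
#' @return Object of class `rvr_model` with fields `relevance_idx`
#'   (indices into the training set), `mu` (posterior mean weights) and
#'   `beta` (noise precision).
#' @export
fit_rvr <- function(X, y, kernel = kernel_spec("rbfdot"),
                    max_iter = 1000, tol = 1e-6, prune_threshold = 1e9,
                    standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2 || length(y) != n) stop("need n >= 2 with matching y",
                                    call. = FALSE)
  std <- if (standardize) .fit_standardizer(X) else NULL
  Xs <- if (standardize) .apply_standardizer(std, X) else X
  kernel <- median_heuristic_sigma(kernel, Xs)
  Phi_full <- kernel_matrix(kernel, Xs)        # n x n basis matrix

  active <- seq_len(n)
  alpha <- rep(1e-2, n)                        # per-weight precisions
  beta <- 1 / max(0.1 * stats::var(y), 1e-8)   # noise precision
  mu <- rep(0, n)
  for (it in seq_len(max_iter)) {
    Phi <- Phi_full[, active, drop = FALSE]
    A <- diag(alpha[active], length(active)) + beta * crossprod(Phi)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) {
      A <- A + diag(1e-8 * mean(diag(A)), nrow(A))
      ch <- chol(A)
    }
    Sigma <- chol2inv(ch)
    mu_act <- beta * (Sigma %*% crossprod(Phi, y))
    gamma <- 1 - alpha[active] * diag(Sigma)
    alpha_new <- pmin(gamma / pmax(mu_act^2, 1e-300), 1e12)
    resid <- y - Phi %*% mu_act
    beta_new <- max((n - sum(gamma)) / max(sum(resid^2), 1e-300), 1e-12)

    rel <- max(abs(log(alpha_new) - log(alpha[active])))
    alpha[active] <- alpha_new
    beta <- beta_new
    keep <- alpha[active] < prune_threshold
    if (!any(keep)) stop("RVR degenerate: no basis function retained",
                         call. = FALSE)
    active <- active[keep]
    if (rel < tol) break
  }
  Phi <- Phi_full[, active, drop = FALSE]
  A <- diag(alpha[active], length(active)) + beta * crossprod(Phi)
  Sigma <- chol2inv(chol(A + diag(1e-10, nrow(A))))
  mu_act <- as.numeric(beta * (Sigma %*% crossprod(Phi, y)))

  structure(list(
    algorithm = "RVR",
    kernel = kernel,
    Xtrain = Xs,
    std = std,
    relevance_idx = active,
    mu = mu_act,
    alpha = alpha[active],
    beta = beta,
    iterations = it
  ), class = c("rvr_model", "kernel_age_model"))
}

#' Predict ages from a fitted kernel model
#'
#' @param model A `gpr_model` or `rvr_model`.
#' @param X New inputs with the training column layout.
#' @return Numeric vector of predicted ages (empty for empty input).
#' @export
predict_age <- function(model, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0) return(numeric(0))
  if (ncol(X) != ncol(model$Xtrain)) {
    stop("input columns do not match the training layout", call. = FALSE)
  }
  Xs <- if (is.null(model$std)) X else .apply_standardizer(model$std, X)
  if (inherits(model, "gpr_model")) {
    Kstar <- kernel_matrix(model$kernel, Xs, model$Xtrain)
    out <- model$ybar + model$ysd * as.numeric(Kstar %*% model$alpha)
  } else {
    Kstar <- kernel_matrix(model$kernel, Xs,
                           model$Xtrain[model$relevance_idx, , drop = FALSE])
    out <- as.numeric(Kstar %*% model$mu)
  }
  if (any(!is.finite(out))) stop("non-finite prediction", call. = FALSE)
  out
}

#' @export
predict.gpr_model <- function(object, newdata, ...) {
  predict_age(object, newdata)
}

#' @export
predict.rvr_model <- function(object, newdata, ...) {
  predict_age(object, newdata)
}

#' Fit either algorithm by name
#'
#' Convenience dispatcher used by the selection grid and the resampling
#' and permutation stages.
#'
#' @param algorithm `"GPR"` or `"RVR"`.
#' @param X,y Training inputs and ages.
#' @param kernel_name `"laplacedot"` or `"rbfdot"`.
#' @param ... Passed on to [fit_gpr()] / [fit_rvr()].
#' @return A fitted kernel age model.
#' @export
fit_age_model <- function(algorithm = c("GPR", "RVR"), X, y,
                          kernel_name = c("laplacedot", "rbfdot"), ...) {
  algorithm <- match.arg(algorithm)
  kernel_name <- match.arg(kernel_name)
  k <- kernel_spec(kernel_name)
  dots <- list(...)
  dots <- dots[!vapply(dots, is.null, logical(1))]   # NULL = use default
  fn <- if (algorithm == "GPR") fit_gpr else fit_rvr
  do.call(fn, c(list(X = X, y = y, kernel = k), dots))
}

#' Save / load a fitted kernel age model
#'
#' Serialises a fitted `gpr_model` or `rvr_model` to full-precision JSON
#' (standardisation parameters, resolved kernel, training inputs and
#' weights), so a model can be stored alongside the run manifest and
#' reloaded for later prediction.
#'
#' @param model A fitted kernel age model.
#' @param path JSON file path.
#' @return `write_age_model` returns `path` invisibly; `read_age_model`
#'   returns the model.
#' @export
write_age_model <- function(model, path) {
  obj <- unclass(model)
  obj$kernel <- unclass(obj$kernel)
  obj$class <- class(model)[1]
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname write_age_model
#' @export
read_age_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$class
  obj$class <- NULL
  obj$Xtrain <- as.matrix(obj$Xtrain)
  obj$kernel <- structure(as.list(obj$kernel), class = "kernel_spec")
  if (!is.null(obj$std)) obj$std <- lapply(obj$std, as.numeric)
  structure(obj, class = c(cls, "kernel_age_model"))
}
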