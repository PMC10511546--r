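# Model evaluation: MAE and predicted R^2, algorithm/kernel selection on
# the internal validation cohort, resampling confidence intervals and
# permutation-based null-hypothesis testing.

#' Mean absolute error
#'
#' @param pred,obs Equal-length numeric vectors.
#' @return Mean of |pred - obs| (years).
#' @export
mae <- function(pred, obs) {
  if (length(pred) == 0) stop("empty input", call. = FALSE)
  if (length(pred) != length(obs)) stop("length mismatch", call. = FALSE)
  mean(abs(pred - obs))
}

#' Predicted R-squared
#'
#' 1 - MSE(pred, obs) / MSE(obs, mean), i.e. one minus the normalised
#' mean squared error. Zero is the mean-only model; negative values mean
#' the model predicts worse than the mean. By default the normalising
#' mean is the evaluation cohort's own mean, which is exactly what makes
#' "predicting the mean" score 0; an externally supplied mean (e.g. the
#' training mean) can be passed instead.
#'
#' @param pred,obs Equal-length numeric vectors, `n >= 2`.
#' @param norm_mean Mean used in the denominator (default `mean(obs)`).
#' @return Dimensionless value `<= 1`.
#' @export
predicted_r2 <- function(pred, obs, norm_mean = mean(obs)) {
  if (length(pred) != length(obs)) stop("length mismatch", call. = FALSE)
  if (length(obs) < 2) stop("need n >= 2", call. = FALSE)
  denom <- mean((obs - norm_mean)^2)
  if (denom == 0) stop("observed values are constant", call. = FALSE)
  1 - mean((pred - obs)^2) / denom
}

#' Select algorithm and kernel on the internal validation cohort
#'
#' For each feature set, picks the algorithm x kernel cell with the
#' highest validation predicted R^2; ties are broken by lower MAE, then
#' by the fixed order GPR before RVR and laplacedot before rbfdot.
#'
#' @param grid Tibble with columns `feature_set`, `algorithm`, `kernel`,
#'   `mae`, `pred_r2` (the validation metrics); every feature set must
#'   have all four algorithm x kernel cells.
#' @return Tibble, one row per feature set, with the chosen cell.
#' @export
select_model <- function(grid) {
  need <- c("feature_set", "algorithm", "kernel", "mae", "pred_r2")
  if (!all(need %in% names(grid))) {
    stop("grid needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(grid, grid$feature_set), function(g) {
    cells <- interaction(g$algorithm, g$kernel)
    if (length(unique(cells)) < 4) {
      stop("missing algorithm x kernel cells for feature set ",
           g$feature_set[1], call. = FALSE)
    }
    ord <- order(-g$pred_r2, g$mae,
                 match(g$algorithm, c("GPR", "RVR")),
                 match(g$kernel, c("laplacedot", "rbfdot")))
    g[ord[1], , drop = FALSE]
  })
  dplyr::bind_rows(out)
}

#' Evaluate one fitted model on one cohort
#'
#' @param model Fitted kernel age model.
#' @param X,y Evaluation inputs and observed ages.
#' @return Tibble with `mae` and `pred_r2`.
#' @export
eval_metrics <- function(model, X, y) {
  p <- predict_age(model, X)
  tibble::tibble(mae = mae(p, y), pred_r2 = predicted_r2(p, y))
}

#' Resampling robustness of a feature-set model
#'
#' Repeats the full split -> train -> test cycle over fresh
#' age-stratified partitions (the algorithm and kernel stay fixed at the
#' selected cell) and summarises the test predicted R^2 with its mean
#' and percentile 95% CI.
#'
#' @param X Full-cohort feature matrix (rows named by subject id).
#' @param ages Full-cohort ages, aligned with `X`.
#' @param algorithm,kernel_name The fixed model cell.
#' @param n_partitions Number of random partitions.
#' @param seed Base seed; partition p uses `seed + p`.
#' @param train_frac,bin_width,collapse_below Split parameters, as in
#'   [stratified_undersample()].
#' @param ... Passed to [fit_age_model()].
#' @return List of class `robustness_result`: `mean_pred_r2`, `ci`
#'   (percentile 2.5/97.5), `values`, `n_partitions`, `n_effective`.
#' @export
resample_performance <- function(X, ages, algorithm, kernel_name,
                                 n_partitions = 100, seed = 1L,
                                 train_frac = 0.75, bin_width = 0.5,
                                 collapse_below = 9, ...) {
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  vals <- rep(NA_real_, n_partitions)
  for (p in seq_len(n_partitions)) {
    res <- tryCatch({
      sp <- stratified_undersample(ids, ages, train_frac = train_frac,
                                   bin_width = bin_width,
                                   collapse_below = collapse_below,
                                   seed = seed + p)
      tr <- sp$partition == "train"
      m <- fit_age_model(algorithm, X[tr, , drop = FALSE], ages[tr],
                         kernel_name, ...)
      predicted_r2(predict_age(m, X[!tr, , drop = FALSE]), ages[!tr])
    }, error = function(e) {
      warning("partition ", p, " failed: ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
    vals[p] <- res
  }
  ok <- vals[!is.na(vals)]
  if (length(ok) == 0) stop("all partitions failed", call. = FALSE)
  ci <- if (length(ok) > 1) {
    stats::quantile(ok, c(0.025, 0.975), names = FALSE)
  } else {
    warning("single partition: degenerate CI", call. = FALSE)
    c(ok, ok)
  }
  structure(list(
    mean_pred_r2 = mean(ok),
    ci = ci,
    values = vals,
    n_partitions = n_partitions,
    n_effective = length(ok),
    seed = seed
  ), class = "robustness_result")
}

#' Permutation null-hypothesis test of a feature-set model
#'
#' Holds the train/test split fixed, permutes the training ages only,
#' retrains, and evaluates each null model on the untouched test cohort
#' against the true test ages. The p-value uses the add-one estimator
#' p = (1 + #\{null R^2 >= observed\}) / (1 + n_perm), so it is never
#' exactly zero.
#'
#' @param X,ages Full-cohort feature matrix and ages.
#' @param split Split tibble fixing the train/test partition.
#' @param observed Observed statistic (the mean resampled predicted
#'   R^2 from [resample_performance()]).
#' @param algorithm,kernel_name The fixed model cell.
#' @param n_perm Number of permutations.
#' @param seed Base seed; permutation b uses `seed + b`.
#' @param ... Passed to [fit_age_model()].
#' @return List: `p_value`, `null_r2`, `observed`, `n_perm`.
#' @export
permutation_nhst <- function(X, ages, split, observed, algorithm,
                             kernel_name, n_perm = 1000, seed = 1L, ...) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  ids <- rownames(X)
  tr <- ids %in% split_ids(split, "train")
  te <- ids %in% split_ids(split, "test")
  Xtr <- X[tr, , drop = FALSE]
  Xte <- X[te, , drop = FALSE]
  ytr <- ages[tr]
  yte <- ages[te]
  null_r2 <- vapply(seq_len(n_perm), function(b) {
    yperm <- withr::with_seed(seed + b, sample(ytr))
    m <- fit_age_model(algorithm, Xtr, yperm, kernel_name, ...)
    predicted_r2(predict_age(m, Xte), yte)
  }, numeric(1))
  p <- (1 + sum(null_r2 >= observed)) / (1 + n_perm)
  list(p_value = p, null_r2 = null_r2, observed = observed,
       n_perm = n_perm)
}
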