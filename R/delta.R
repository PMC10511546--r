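# Brainage delta (predicted minus chronological age) and screens for
# age, sex, motion (EFC) and IQ associations. Delta is kept SIGNED:
# the age-bias analyses (overestimation in younger children,
# underestimation in older adolescents, hence negative delta-age
# correlations) are only expressible with signed deltas.

#' Compute Brainage delta for a test cohort
#'
#' delta = predicted - actual, per subject, with developmental-period
#' banding for reporting: childhood (5-11), early adolescence (11-14),
#' middle adolescence (14-17).
#'
#' @param subject_id Subject ids.
#' @param actual Chronological ages (years).
#' @param predicted Model-predicted ages (years).
#' @return Tibble `subject_id`, `actual_age`, `predicted_age`, `delta`,
#'   `age_band`, with a `summary` attribute (mean, sd, median of delta).
#' @export
compute_delta <- function(subject_id, actual, predicted) {
  if (length(actual) != length(predicted) ||
      length(subject_id) != length(actual)) {
    stop("length mismatch between ids, actual and predicted",
         call. = FALSE)
  }
  band <- cut(actual, breaks = c(-Inf, 11, 14, Inf), right = FALSE,
              labels = c("childhood", "early_adolescence",
                         "middle_adolescence"))
  out <- tibble::tibble(
    subject_id = subject_id,
    actual_age = actual,
    predicted_age = predicted,
    delta = predicted - actual,
    age_band = as.character(band)
  )
  attr(out, "summary") <- c(mean = mean(out$delta),
                            sd = stats::sd(out$delta),
                            median = stats::median(out$delta))
  out
}

#' First-order partial correlation
#'
#' Correlation of `x` and `y` controlling for one covariate, via the
#' standard pairwise-correlation formula
#' r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2));
#' the Spearman variant applies the same formula to ranks. The p-value
#' comes from the t transform with n - 3 degrees of freedom. Rows with
#' a missing value in any of the three variables are dropped pairwise.
#'
#' @param x,y Numeric vectors.
#' @param control Numeric covariate to partial out.
#' @param method `"pearson"` or `"spearman"`.
#' @return List: `estimate`, `p_value`, `n`, `method`.
#' @export
partial_correlation <- function(x, y, control,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y, control)
  x <- x[ok]; y <- y[ok]; z <- control[ok]
  n <- length(x)
  if (n < 4) stop("need n >= 4 complete observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0) {
    stop("zero-variance input to partial correlation", call. = FALSE)
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y); z <- rank(z)
  }
  rxy <- stats::cor(x, y)
  rxz <- stats::cor(x, z)
  ryz <- stats::cor(y, z)
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- max(min(r, 1), -1)
  tstat <- r * sqrt((n - 3) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 3)
  list(estimate = r, p_value = p, n = n, method = method)
}

#' Sex bias test on Brainage delta
#'
#' Ordinary least squares `delta ~ sex + actual age`; reports the sex
#' coefficient's t statistic and two-sided p-value.
#'
#' @param delta Signed Brainage deltas.
#' @param sex Factor/character with both levels present ("F"/"M").
#' @param age Actual ages (covariate).
#' @return List: `statistic`, `p_value`, `estimate` (sex coefficient,
#'   years), `n`.
#' @export
sex_bias_test <- function(delta, sex, age) {
  ok <- stats::complete.cases(delta, sex, age)
  delta <- delta[ok]; sex <- factor(sex[ok]); age <- age[ok]
  if (nlevels(droplevels(sex)) < 2) {
    stop("both sexes must be present", call. = FALSE)
  }
  if (length(delta) < 5) stop("need n >= 5", call. = FALSE)
  fit <- stats::lm(delta ~ sex + age)
  co <- summary(fit)$coefficients
  sex_row <- grep("^sex", rownames(co))[1]
  list(statistic = co[sex_row, "t value"],
       p_value = co[sex_row, "Pr(>|t|)"],
       estimate = co[sex_row, "Estimate"],
       n = length(delta))
}

#' Screen Brainage delta against covariates across models
#'
#' For every feature-set model's delta table: Pearson and Spearman
#' partial correlations of delta with the motion proxy (EFC) and with
#' IQ, controlling actual age (subjects with missing IQ dropped
#' pairwise, per-row n reported), the plain Pearson correlation of
#' delta with actual age (the age-bias check itself), and a
#' linear-model sex test controlling age. With ten models this yields
#' 50 continuous rows plus 10 sex rows; a single Bonferroni threshold
#' (default 0.05 / 60 = 0.000833) is applied across the whole screen.
#'
#' @param deltas Named list of delta tibbles (one per feature-set
#'   model), each as returned by [compute_delta()].
#' @param covariates Tibble with `subject_id`, `efc`, `iq`, `sex`.
#' @param alpha Family-wise error rate before Bonferroni division.
#' @param n_tests Bonferroni denominator.
#' @return Tibble: `covariate`, `feature_set`, `method`, `n`,
#'   `estimate`, `p_value`, `significant`; attribute `mean_r` holds the
#'   mean Pearson r per continuous covariate across models.
#' @export
covariate_screen <- function(deltas, covariates, alpha = 0.05,
                             n_tests = 60) {
  need <- c("subject_id", "efc", "iq", "sex")
  missing_cols <- setdiff(need, names(covariates))
  if (length(missing_cols) > 0) {
    stop("covariates table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  thr <- alpha / n_tests
  rows <- list()
  for (fs in names(deltas)) {
    d <- deltas[[fs]]
    cov <- covariates[match(d$subject_id, covariates$subject_id), ]
    for (cv in c("efc", "iq")) {
      for (meth in c("pearson", "spearman")) {
        pc <- partial_correlation(d$delta, cov[[cv]], d$actual_age,
                                  method = meth)
        rows[[length(rows) + 1]] <- tibble::tibble(
          covariate = if (cv == "efc") "motion_efc" else "iq",
          feature_set = fs, method = meth, n = pc$n,
          estimate = pc$estimate, p_value = pc$p_value)
      }
    }
    ct <- stats::cor.test(d$delta, d$actual_age)
    rows[[length(rows) + 1]] <- tibble::tibble(
      covariate = "age", feature_set = fs, method = "pearson",
      n = length(d$delta), estimate = unname(ct$estimate),
      p_value = ct$p.value)
    st <- sex_bias_test(d$delta, cov$sex, d$actual_age)
    rows[[length(rows) + 1]] <- tibble::tibble(
      covariate = "sex", feature_set = fs, method = "lm", n = st$n,
      estimate = st$statistic, p_value = st$p_value)
  }
  out <- dplyr::bind_rows(rows)
  out$significant <- out$p_value < thr
  pear <- out[out$method == "pearson", ]
  attr(out, "mean_r") <- tapply(pear$estimate, pear$covariate, mean)
  attr(out, "alpha_bonferroni") <- thr
  out
}
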