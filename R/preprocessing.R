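# Quality control on site-batched QA metrics, and ComBat-style
# empirical-Bayes location/scale harmonisation of morphometry per feature,
# protecting the age covariate.

#' Z-score QA metrics within acquisition site
#'
#' Each metric is centred and scaled within its site, then re-signed so
#' that larger values always mean better quality (metrics whose raw
#' orientation is "higher is worse" are negated after scaling).
#'
#' @param qa QA tibble: `subject_id`, `site_id`, six metric columns.
#' @param higher_better Named logical giving each metric's raw quality
#'   orientation; defaults to the orientation declared by [qa_metrics()].
#' @param ddof Degrees-of-freedom correction for the SD: 0 for the
#'   population SD (default) or 1 for the sample SD.
#' @return Tibble with `subject_id`, `site_id` and one z-score column per
#'   metric (quality-oriented).
#' @export
zscore_qa_within_site <- function(qa,
                                  higher_better =
                                    attr(qa_metrics(), "higher_better"),
                                  ddof = 0) {
  metrics <- setdiff(names(qa), c("subject_id", "site_id"))
  if (length(metrics) == 0) stop("no QA metric columns found", call. = FALSE)
  out <- qa[c("subject_id", "site_id")]
  for (m in metrics) {
    z <- rep(NA_real_, nrow(qa))
    for (s in unique(qa$site_id)) {
      idx <- which(qa$site_id == s)
      if (length(idx) < 2) {
        stop(sprintf("site %s has fewer than 2 subjects (metric %s)", s, m),
             call. = FALSE)
      }
      x <- qa[[m]][idx]
      mu <- mean(x)
      n_eff <- length(x) - ddof
      sdv <- sqrt(sum((x - mu)^2) / n_eff)
      if (sdv == 0) {
        stop(sprintf("site %s has zero SD for metric %s", s, m),
             call. = FALSE)
      }
      z[idx] <- (x - mu) / sdv
    }
    sgn <- if (isTRUE(higher_better[[m]])) 1 else -1
    out[[m]] <- sgn * z
  }
  out
}

#' Apply the QC inclusion rule
#'
#' A metric is coded as failed when its quality-oriented z-score falls
#' below `z_cut`; a subject is included when at most `max_fail` metrics
#' fail (the "zero or one" rule at the defaults).
#'
#' @param qc_z Output of [zscore_qa_within_site()].
#' @param z_cut Failure threshold on the quality-oriented z-score.
#' @param max_fail Maximum number of failed metrics compatible with
#'   inclusion.
#' @return Tibble `subject_id`, `site_id`, z columns, `n_failed`,
#'   `included`, with the number of exclusions reported via `message()`.
#' @export
apply_qc_filter <- function(qc_z, z_cut = -1.5, max_fail = 1) {
  if (nrow(qc_z) == 0) stop("empty QC table", call. = FALSE)
  metrics <- setdiff(names(qc_z), c("subject_id", "site_id"))
  zmat <- as.matrix(qc_z[metrics])
  n_failed <- rowSums(zmat < z_cut)
  out <- qc_z
  out$n_failed <- as.integer(n_failed)
  out$included <- n_failed <= max_fail
  message(sprintf("QC: excluded %d of %d subjects (> %d metrics below z = %s)",
                  sum(!out$included), nrow(out), max_fail,
                  format(z_cut)))
  out
}

#' @rdname apply_qc_filter
#' @return `qc_included_ids` returns the included subject ids.
#' @export
qc_included_ids <- function(qc_z, z_cut = -1.5, max_fail = 1) {
  res <- suppressMessages(apply_qc_filter(qc_z, z_cut, max_fail))
  res$subject_id[res$included]
}

# ---------------------------------------------------------------------------
# ComBat-style harmonisation. One model per morphometric feature, fitted on
# the subjects x regions matrix: standardise each region with a pooled model
# that includes age, estimate per-site location/scale, optionally shrink the
# estimates with parametric empirical Bayes (normal prior on locations,
# inverse-gamma on scales, moment-matched), and reconstruct.

.aprior <- function(delta_hat) {
  m <- mean(delta_hat); s2 <- stats::var(delta_hat)
  (2 * s2 + m^2) / s2
}
.bprior <- function(delta_hat) {
  m <- mean(delta_hat); s2 <- stats::var(delta_hat)
  (m * s2 + m^3) / s2
}

# EB iteration for one site: shrink location (gamma) and scale (delta^2).
# Fixed-point iteration of the standard parametric posterior-mean /
# posterior-variance updates, stopped on relative change.
.eb_site <- function(s_data, gamma_hat, delta_hat, gamma_bar, t2, a, b,
                     conv = 1e-4) {
  n <- rep(nrow(s_data), ncol(s_data))     # subjects per region (all equal)
  g_old <- gamma_hat
  d_old <- delta_hat
  change <- 1
  while (change > conv) {
    g_new <- (t2 * n * gamma_hat + d_old * gamma_bar) / (t2 * n + d_old)
    sum2 <- colSums((s_data - matrix(g_new, nrow(s_data), ncol(s_data),
                                     byrow = TRUE))^2)
    d_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
    change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
    g_old <- g_new
    d_old <- d_new
  }
  list(gamma_star = g_old, delta_star = d_old)
}

#' Fit a site-harmonisation model for one morphometric feature
#'
#' Location/scale batch-effect model in the ComBat family, fitted to a
#' subjects-by-regions matrix while protecting the age covariate: regions
#' are standardised with a pooled regression on site indicators plus age,
#' per-site location and scale estimates are computed on the standardised
#' data, and (by default) shrunk with the parametric empirical-Bayes
#' scheme (normal prior on locations, inverse-gamma on scales, priors
#' moment-matched across regions).
#'
#' @param values Numeric matrix, subjects x regions, one morphometric
#'   feature.
#' @param site_ids Character/factor vector of site labels per subject.
#' @param age Numeric vector of ages per subject (protected covariate).
#' @param eb Use empirical-Bayes shrinkage (`TRUE`, default) or the raw
#'   per-site estimates (`FALSE`, the closed form used in exact tests).
#' @return An object of class `harmonization_model`.
#' @export
fit_harmonization <- function(values, site_ids, age, eb = TRUE) {
  values <- as.matrix(values)
  n <- nrow(values)
  sites <- sort(unique(as.character(site_ids)))
  if (length(sites) < 2) {
    warning("single site: harmonisation model is the identity")
    mod <- structure(list(identity = TRUE, sites = sites),
                     class = "harmonization_model")
    return(mod)
  }
  counts <- table(factor(site_ids, levels = sites))
  if (any(counts < 2)) {
    stop("each site needs >= 2 subjects for harmonisation", call. = FALSE)
  }

  batch <- factor(site_ids, levels = sites)
  batchmod <- stats::model.matrix(~ -1 + batch)
  design <- cbind(batchmod, age = age)
  if (qr(design)$rank < ncol(design)) {
    stop("singular design (site indicators + age)", call. = FALSE)
  }
  dat <- t(values)                               # regions x subjects
  n_batches <- as.numeric(counts)

  B_hat <- solve(crossprod(design), t(design) %*% t(dat))
  grand_mean <- crossprod(n_batches / n, B_hat[seq_along(sites), ,
                                               drop = FALSE])
  fitted_all <- t(design %*% B_hat)              # regions x subjects
  var_pooled <- rowMeans((dat - fitted_all)^2)   # pooled residual variance
  if (any(var_pooled == 0)) {
    stop("region with zero pooled variance; cannot standardise",
         call. = FALSE)
  }
  beta_age <- B_hat[length(sites) + 1, ]         # per-region age effect

  stand_mean <- matrix(grand_mean, nrow(dat), ncol(dat)) +
    outer(beta_age, age)
  s_data <- (dat - stand_mean) / sqrt(var_pooled)

  gamma_hat <- matrix(NA_real_, length(sites), nrow(dat))
  delta_hat <- matrix(NA_real_, length(sites), nrow(dat))
  for (k in seq_along(sites)) {
    idx <- which(batch == sites[k])
    gamma_hat[k, ] <- rowMeans(s_data[, idx, drop = FALSE])
    delta_hat[k, ] <- apply(s_data[, idx, drop = FALSE], 1, stats::var)
  }

  if (eb) {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
    for (k in seq_along(sites)) {
      gbar <- mean(gamma_hat[k, ])
      t2 <- stats::var(gamma_hat[k, ])
      a <- .aprior(delta_hat[k, ])
      b <- .bprior(delta_hat[k, ])
      idx <- which(batch == sites[k])
      sol <- .eb_site(t(s_data[, idx, drop = FALSE]),
                      gamma_hat[k, ], delta_hat[k, ], gbar, t2, a, b)
      gamma_star[k, ] <- sol$gamma_star
      delta_star[k, ] <- sol$delta_star
    }
  } else {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
  }
  if (any(delta_star <= 0)) {
    stop("non-positive scale estimate in harmonisation model",
         call. = FALSE)
  }

  structure(list(
    identity = FALSE,
    sites = sites,
    grand_mean = as.numeric(grand_mean),
    beta_age = beta_age,
    var_pooled = var_pooled,
    gamma_star = gamma_star,
    delta_star = delta_star,
    eb = eb,
    regions = colnames(values)
  ), class = "harmonization_model")
}

#' Apply a fitted harmonisation model
#'
#' Standardises with the stored pooled model (re-adding the age fit on the
#' way back), removes the per-site location, divides by the per-site
#' scale, and back-transforms.
#'
#' @param model A `harmonization_model` from [fit_harmonization()].
#' @param values Subjects x regions matrix with the layout the model was
#'   fitted on.
#' @param site_ids,age Site labels and ages for the rows of `values`.
#' @return Corrected subjects x regions matrix.
#' @export
apply_harmonization <- function(model, values, site_ids, age) {
  values <- as.matrix(values)
  if (isTRUE(model$identity)) return(values)
  if (!is.null(model$regions) && !is.null(colnames(values)) &&
      !identical(colnames(values), model$regions)) {
    stop("region layout differs from the fitted model", call. = FALSE)
  }
  unseen <- setdiff(unique(as.character(site_ids)), model$sites)
  if (length(unseen) > 0) {
    stop("unseen site id(s): ", paste(unseen, collapse = ", "),
         call. = FALSE)
  }
  dat <- t(values)
  stand_mean <- matrix(model$grand_mean, nrow(dat), ncol(dat)) +
    outer(model$beta_age, age)
  s_data <- (dat - stand_mean) / sqrt(model$var_pooled)
  k <- match(as.character(site_ids), model$sites)
  adj <- (s_data - t(model$gamma_star[k, , drop = FALSE])) /
    t(sqrt(model$delta_star[k, , drop = FALSE]))
  out <- adj * sqrt(model$var_pooled) + stand_mean
  t(out)
}

#' Harmonise a whole morphometry table
#'
#' Fits and applies one harmonisation model per morphometric feature
#' (on its subjects x 68-regions slab), protecting age.
#'
#' @param morphometry Wide morphometry tibble (see [generate_cohort()]).
#' @param eb Empirical-Bayes shrinkage on/off.
#' @return List: `morphometry` (corrected tibble, metadata untouched) and
#'   `models` (named list of `harmonization_model`, one per feature).
#' @export
harmonize_cohort <- function(morphometry, eb = TRUE) {
  out <- morphometry
  models <- list()
  for (f in morph_features()) {
    cols <- paste0(dk_regions(), "__", f)
    m <- fit_harmonization(as.matrix(morphometry[cols]),
                           morphometry$site_id, morphometry$age, eb = eb)
    corrected <- apply_harmonization(m, as.matrix(morphometry[cols]),
                                     morphometry$site_id, morphometry$age)
    out[cols] <- as.data.frame(corrected)
    models[[f]] <- m
  }
  list(morphometry = out, models = models)
}
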