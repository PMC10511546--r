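# Synthetic multi-site cohort generator.
#
# Emulates a paediatric structural-MRI cohort pooled over many acquisition
# sites: regional morphometry with feature-specific age trends, additive and
# multiplicative site batch effects, a subject-level biological intercept,
# iid measurement noise, and an age-rotating low-rank coupling between
# regional feature profiles so that correlation-based (MSN) edges carry age
# signal. Every drawn parameter is recorded in a GroundTruth object so
# downstream stages can be tested for parameter recovery.

.feature_defaults <- function() {
  # mean: typical regional value; region_sd: spread of regional baselines;
  # slope: common age trend (units / yr); noise_sd: iid per-region noise;
  # subject_sd: per-subject biological intercept shared across regions.
  # Thickness and volume carry the dominant developmental signal.
  tibble::tibble(
    feature = morph_features(),
    mean = c(2400, 2.6, 14, 0.025, 0.13, 2.7, 5800),
    region_sd = c(900, 0.8, 5, 0.008, 0.025, 0.25, 2300),
    slope = c(8, 0.002, 0.03, 2e-05, 1e-04, -0.03, -55),
    quad = rep(0, 7),
    noise_sd = c(110, 0.22, 1.1, 0.0025, 0.011, 0.07, 260),
    subject_sd = c(180, 0.18, 0.9, 0.002, 0.009, 0.06, 170),
    site_loc_sd = c(160, 0.15, 0.8, 0.0018, 0.008, 0.08, 250)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Returns a validated configuration list. Defaults emulate the multi-site
#' paediatric cohort the pipeline targets: 17 sites, ages 6.5-16.9 years
#' with mean 12.4 and SD 2.5, roughly 4:1 male:female, IQ 110 +/- 15, the
#' strongest age trends on cortical thickness and volume, and an
#' age-rotating inter-regional coupling so MSN edges are age-informative.
#'
#' @param n_subjects Number of subjects to generate.
#' @param n_sites Number of acquisition sites.
#' @param age_range Length-2 numeric, minimum and maximum age in years.
#' @param age_mean,age_sd Mean and SD of the (truncated normal) age
#'   distribution, years.
#' @param sex_ratio_m Proportion of males, in (0, 1).
#' @param iq_mean,iq_sd Mean and SD of IQ.
#' @param iq_missing_frac Fraction of subjects with missing IQ.
#' @param feature_params Data frame as returned by the internal defaults:
#'   one row per morphometric feature with columns `mean`, `region_sd`,
#'   `slope`, `quad`, `noise_sd`, `subject_sd`, `site_loc_sd`.
#' @param site_location_effects Optional `n_sites x 7` matrix of additive
#'   per-site offsets per feature; drawn from `site_loc_sd` when `NULL`.
#' @param site_scale_effects Optional `n_sites x 7` matrix of positive
#'   multiplicative per-site factors; drawn log-normally when `NULL`.
#' @param site_scale_sdlog SD of log site scale factors when drawn.
#' @param coupling_age_slope Rotation rate (radians / yr) of the latent
#'   region-loading pattern that couples regional feature profiles; zero
#'   makes expected MSN edge weights age-independent.
#' @param coupling_strength Magnitude of the coupling term, relative to
#'   each feature's between-region baseline spread.
#' @param coupling_feature_contrast Length-7 loading vector giving how
#'   strongly the latent coupling factor touches each feature (must vary
#'   across features for correlation-based edges to see it).
#' @param qa_fail_frac Fraction of subjects given deliberately degraded QA
#'   metrics (to exercise the QC filter).
#' @param qa_fail_n_metrics Number of metrics degraded per failing subject.
#' @param qa_fail_shift Degradation size in within-site SD units.
#' @param seed Integer seed; the generator is deterministic given the seed.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 327,
                          n_sites = 17,
                          age_range = c(6.5, 16.9),
                          age_mean = 12.4,
                          age_sd = 2.5,
                          sex_ratio_m = 259 / 327,
                          iq_mean = 110,
                          iq_sd = 15,
                          iq_missing_frac = 19 / 327,
                          feature_params = .feature_defaults(),
                          site_location_effects = NULL,
                          site_scale_effects = NULL,
                          site_scale_sdlog = 0.08,
                          coupling_age_slope = 0.18,
                          coupling_strength = 0.45,
                          coupling_feature_contrast =
                            c(0.3, -0.25, 0.3, -0.25, 0.3, -1.1, 0.9),
                          qa_fail_frac = 14 / 361,
                          qa_fail_n_metrics = 3,
                          qa_fail_shift = 3,
                          seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects, n_sites = n_sites, age_range = age_range,
    age_mean = age_mean, age_sd = age_sd, sex_ratio_m = sex_ratio_m,
    iq_mean = iq_mean, iq_sd = iq_sd, iq_missing_frac = iq_missing_frac,
    feature_params = feature_params,
    site_location_effects = site_location_effects,
    site_scale_effects = site_scale_effects,
    site_scale_sdlog = site_scale_sdlog,
    coupling_age_slope = coupling_age_slope,
    coupling_strength = coupling_strength,
    coupling_feature_contrast = coupling_feature_contrast,
    qa_fail_frac = qa_fail_frac,
    qa_fail_n_metrics = qa_fail_n_metrics,
    qa_fail_shift = qa_fail_shift,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid cohort configuration: `%s` %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_subjects) || length(cfg$n_subjects) != 1 ||
      cfg$n_subjects < 1) {
    fail("n_subjects", "must be a positive count")
  }
  if (!is.numeric(cfg$n_sites) || cfg$n_sites < 1) {
    fail("n_sites", "must be a positive count")
  }
  if (length(cfg$age_range) != 2 || diff(cfg$age_range) <= 0) {
    fail("age_range", "must be an increasing [min, max] pair")
  }
  if (cfg$age_sd < 0) fail("age_sd", "must be >= 0")
  if (cfg$iq_sd < 0) fail("iq_sd", "must be >= 0")
  if (cfg$sex_ratio_m <= 0 || cfg$sex_ratio_m >= 1) {
    fail("sex_ratio_m", "must lie strictly in (0, 1)")
  }
  fp <- cfg$feature_params
  need <- c("feature", "mean", "region_sd", "slope", "quad", "noise_sd",
            "subject_sd", "site_loc_sd")
  if (!all(need %in% names(fp)) || nrow(fp) != 7 ||
      !identical(fp$feature, morph_features())) {
    fail("feature_params", "must have one row per morphometric feature")
  }
  for (col in c("region_sd", "noise_sd", "subject_sd", "site_loc_sd")) {
    if (any(fp[[col]] < 0)) fail(paste0("feature_params$", col),
                                 "must be >= 0")
  }
  for (nm in c("site_location_effects", "site_scale_effects")) {
    m <- cfg[[nm]]
    if (!is.null(m) && !(is.matrix(m) && nrow(m) == cfg$n_sites &&
                         ncol(m) == 7)) {
      fail(nm, "must be an n_sites x 7 matrix (or NULL)")
    }
  }
  if (!is.null(cfg$site_scale_effects) && any(cfg$site_scale_effects <= 0)) {
    fail("site_scale_effects", "must be strictly positive")
  }
  if (cfg$qa_fail_frac < 0 || cfg$qa_fail_frac >= 1) {
    fail("qa_fail_frac", "must lie in [0, 1)")
  }
  if (length(cfg$coupling_feature_contrast) != 7 ||
      !is.numeric(cfg$coupling_feature_contrast)) {
    fail("coupling_feature_contrast", "must be a length-7 numeric vector")
  }
  invisible(cfg)
}

# truncated-normal sampler (rejection; exact truncation to [lo, hi])
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# closed-form mean/SD of N(mu, sigma) truncated to [lo, hi]
.truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# parent-normal parameters whose TRUNCATED marginal has the target
# mean/SD (truncation shrinks the SD; the configured values describe the
# cohort actually drawn, so the parent is inflated to compensate)
.trunc_parent_params <- function(target_mean, target_sd, lo, hi) {
  obj <- function(p) {
    mom <- .truncnorm_moments(p[1], exp(p[2]), lo, hi)
    (mom["mean"] - target_mean)^2 + (mom["sd"] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

.qa_defaults <- function() {
  tibble::tibble(
    metric = qa_metrics(),
    mean = c(14, 0.45, 900, 3.4, 0.02, 9),
    within_sd = c(1.5, 0.03, 120, 0.25, 0.006, 1),
    between_site_sd = c(0.75, 0.015, 60, 0.125, 0.003, 0.5)
  )
}

#' Generate a synthetic multi-site morphometry cohort
#'
#' Draws a full cohort under the generative model described in
#' `vignette("brainage-msn-methods")`: regional value =
#' (baseline + age trend + subject intercept + coupling + site offset)
#' x site scale + iid noise. The low-rank coupling term rotates its region
#' loadings with age at `coupling_age_slope` rad/yr, which is what makes
#' correlation-based MSN edges informative about age.
#'
#' @param config A [cohort_config()] object.
#' @return A list with elements
#'   \describe{
#'     \item{morphometry}{tibble: `subject_id`, `site_id`, `age`, `sex`,
#'       `iq`, then 476 columns named `<region>__<feature>`.}
#'     \item{qa}{tibble: `subject_id`, `site_id`, six QA metric columns.}
#'     \item{ground_truth}{list recording every parameter actually used,
#'       including drawn site effects, coupling loadings, and the ids of
#'       deliberately QA-degraded subjects.}
#'   }
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  withr::with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  n <- cfg$n_subjects
  fp <- cfg$feature_params
  regs <- dk_regions()
  feats <- morph_features()
  p <- length(regs)

  subject_id <- sprintf("S%04d", seq_len(n))
  site_id <- sprintf("site%02d", sample.int(cfg$n_sites, n, replace = TRUE))
  age_par <- if (cfg$age_sd > 0) {
    .trunc_parent_params(cfg$age_mean, cfg$age_sd,
                         cfg$age_range[1], cfg$age_range[2])
  } else c(mean = cfg$age_mean, sd = 0)
  age <- .rtruncnorm(n, age_par["mean"], age_par["sd"],
                     cfg$age_range[1], cfg$age_range[2])
  sex <- ifelse(stats::runif(n) < cfg$sex_ratio_m, "M", "F")
  iq <- stats::rnorm(n, cfg$iq_mean, cfg$iq_sd)
  iq[stats::runif(n) < cfg$iq_missing_frac] <- NA_real_

  # regional baselines, fixed across subjects
  baseline <- vapply(seq_len(7), function(j) {
    stats::rnorm(p, fp$mean[j], fp$region_sd[j])
  }, numeric(p))
  dimnames(baseline) <- list(regs, feats)

  # site batch effects
  site_levels <- sprintf("site%02d", seq_len(cfg$n_sites))
  site_loc <- cfg$site_location_effects
  if (is.null(site_loc)) {
    site_loc <- matrix(vapply(seq_len(7), function(j) {
      stats::rnorm(cfg$n_sites, 0, fp$site_loc_sd[j])
    }, numeric(cfg$n_sites)), nrow = cfg$n_sites, ncol = 7)
  }
  site_scale <- cfg$site_scale_effects
  if (is.null(site_scale)) {
    site_scale <- matrix(exp(stats::rnorm(cfg$n_sites * 7, 0,
                                          cfg$site_scale_sdlog)),
                         cfg$n_sites, 7)
  }
  dimnames(site_loc) <- dimnames(site_scale) <- list(site_levels, feats)

  # age-rotating low-rank coupling between regional feature profiles
  w1 <- stats::rnorm(p)
  w2 <- stats::rnorm(p)
  feature_contrast <- cfg$coupling_feature_contrast
  latent <- stats::rnorm(n)
  theta <- cfg$coupling_age_slope * (age - cfg$age_mean)

  subj_intercept <- vapply(seq_len(7), function(j) {
    stats::rnorm(n, 0, fp$subject_sd[j])
  }, numeric(n))

  site_idx <- match(site_id, site_levels)
  values <- matrix(NA_real_, n, p * 7)
  colnames(values) <- .morph_columns()
  for (j in seq_len(7)) {
    trend <- fp$slope[j] * age + fp$quad[j] * age^2
    w_age <- outer(cos(theta), w1) + outer(sin(theta), w2)     # n x p
    coupling <- (cfg$coupling_strength * fp$region_sd[j] *
                   feature_contrast[j]) * latent * w_age
    signal <- matrix(baseline[, j], n, p, byrow = TRUE) +
      trend + subj_intercept[, j] + coupling +
      site_loc[site_idx, j]
    noise <- matrix(stats::rnorm(n * p, 0, fp$noise_sd[j]), n, p)
    values[, (j - 1) * p + seq_len(p)] <- signal * site_scale[site_idx, j] +
      noise
  }

  morphometry <- tibble::as_tibble(cbind(
    tibble::tibble(subject_id = subject_id, site_id = site_id,
                   age = age, sex = sex, iq = iq),
    tibble::as_tibble(values)
  ))

  # QA metrics: site-batched; a small fraction of subjects degraded on
  # several metrics (in the quality-worsening direction) to exercise QC
  qd <- .qa_defaults()
  hb <- attr(qa_metrics(), "higher_better")
  qa_site_means <- matrix(vapply(seq_len(6), function(j) {
    stats::rnorm(cfg$n_sites, qd$mean[j], qd$between_site_sd[j])
  }, numeric(cfg$n_sites)), nrow = cfg$n_sites, ncol = 6)
  qa_vals <- vapply(seq_len(6), function(j) {
    qa_site_means[site_idx, j] + stats::rnorm(n, 0, qd$within_sd[j])
  }, numeric(n))
  colnames(qa_vals) <- qd$metric

  n_fail <- round(cfg$qa_fail_frac * n)
  degraded <- if (n_fail > 0) sample(subject_id, n_fail) else character(0)
  for (s in degraded) {
    i <- match(s, subject_id)
    bad <- sample.int(6, cfg$qa_fail_n_metrics)
    for (j in bad) {
      dir <- if (hb[[qd$metric[j]]]) -1 else 1
      qa_vals[i, j] <- qa_vals[i, j] + dir * cfg$qa_fail_shift * qd$within_sd[j]
    }
  }
  qa <- tibble::as_tibble(cbind(
    tibble::tibble(subject_id = subject_id, site_id = site_id),
    tibble::as_tibble(qa_vals)
  ))

  ground_truth <- list(
    seed = cfg$seed,
    n_subjects = n,
    n_sites = cfg$n_sites,
    age_mean = cfg$age_mean,
    age_sd = cfg$age_sd,
    feature_params = as.data.frame(fp),
    baseline = baseline,
    site_location_effects = site_loc,
    site_scale_effects = site_scale,
    coupling_age_slope = cfg$coupling_age_slope,
    coupling_strength = cfg$coupling_strength,
    coupling_region_loadings = cbind(w1 = w1, w2 = w2),
    coupling_feature_contrast = feature_contrast,
    qa_degraded_subjects = degraded,
    qa_site_means = qa_site_means
  )

  list(morphometry = morphometry, qa = qa, ground_truth = ground_truth)
}

#' Write / read a cohort's tables and ground truth
#'
#' Tidy CSV for the morphometry and QA tables (one row per subject, wide
#' `<region>__<feature>` columns) and full-precision JSON for the ground
#' truth.
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns the directory invisibly; `read_cohort`
#'   returns a cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$morphometry, file.path(dir, "morphometry.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$qa, file.path(dir, "qa.csv"), row.names = FALSE)
  write_ground_truth(cohort$ground_truth,
                     file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  morph <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "morphometry.csv"),
                    check.names = FALSE, stringsAsFactors = FALSE))
  qa <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "qa.csv"),
                    check.names = FALSE, stringsAsFactors = FALSE))
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) read_ground_truth(gt_path) else NULL
  list(morphometry = morph, qa = qa, ground_truth = gt)
}

#' @rdname write_cohort
#' @param ground_truth Ground-truth list from [generate_cohort()].
#' @param path JSON file path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", dataframe = "columns",
                       na = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  sites <- sprintf("site%02d", seq_len(gt$n_sites))
  dims <- list(baseline = list(dk_regions(), morph_features()),
               site_location_effects = list(sites, morph_features()),
               site_scale_effects = list(sites, morph_features()),
               coupling_region_loadings = list(NULL, c("w1", "w2")))
  for (nm in names(dims)) {
    if (!is.null(gt[[nm]])) {
      m <- as.matrix(gt[[nm]])
      dimnames(m) <- dims[[nm]]
      gt[[nm]] <- m
    }
  }
  if (is.list(gt$feature_params)) {
    gt$feature_params <- as.data.frame(gt$feature_params)
  }
  if (length(gt$qa_degraded_subjects) == 0) {
    gt$qa_degraded_subjects <- character(0)
  }
  gt
}

#' Extract the per-subject region-by-feature matrix
#'
#' @param morphometry Morphometry tibble (wide layout).
#' @param subject_id Subject identifier.
#' @return A 68 x 7 numeric matrix (regions x features).
#' @export
subject_matrix <- function(morphometry, subject_id) {
  i <- match(subject_id, morphometry$subject_id)
  if (is.na(i)) stop("unknown subject_id: ", subject_id, call. = FALSE)
  vals <- as.numeric(morphometry[i, .morph_columns()])
  matrix(vals, nrow = 68, ncol = 7,
         dimnames = list(dk_regions(), morph_features()))
}
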