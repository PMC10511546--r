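# Shared fixtures, built in code at test time.

# small cohort for pipeline-level tests
small_cohort <- function(n = 120, sites = 5, seed = 7, ...) {
  generate_cohort(cohort_config(n_subjects = n, n_sites = sites,
                                seed = seed, ...))
}

# a noise-free generator configuration: no site effects, no noise, no
# subject intercepts, no coupling -> values are exactly baseline + trend
noise_free_config <- function(n = 6, thickness_slope = -0.03, seed = 3) {
  fp <- brainagemsn:::.feature_defaults()
  fp$noise_sd[] <- 0
  fp$subject_sd[] <- 0
  fp$slope[] <- 0
  fp$quad[] <- 0
  fp$slope[fp$feature == "cortical_thickness"] <- thickness_slope
  cohort_config(
    n_subjects = n, n_sites = 2, seed = seed, feature_params = fp,
    site_location_effects = matrix(0, 2, 7),
    site_scale_effects = matrix(1, 2, 7),
    coupling_strength = 0, qa_fail_frac = 0)
}

# hand-built QA table: two sites, controllable per-subject shifts
qa_fixture <- function(z_shift = NULL, n_per_site = 10, seed = 11) {
  withr::with_seed(seed, {
    metrics <- qa_metrics()
    n <- 2 * n_per_site
    tab <- tibble::tibble(
      subject_id = sprintf("Q%03d", seq_len(n)),
      site_id = rep(c("siteA", "siteB"), each = n_per_site))
    for (m in metrics) tab[[m]] <- stats::rnorm(n)
    tab
  })
}

# textbook Pearson correlation of two vectors (independent oracle)
textbook_cor <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}
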