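test_that("within-site z-scores have mean 0, SD 1 and quality orientation", {
  qa <- qa_fixture()
  z <- zscore_qa_within_site(qa)
  for (m in qa_metrics()) {
    for (s in c("siteA", "siteB")) {
      zi <- z[[m]][z$site_id == s]
      expect_equal(mean(zi), 0, tolerance = 1e-12)
      expect_equal(sqrt(mean(zi^2)), 1, tolerance = 1e-12)  # population SD
    }
  }
  # efc is "higher is worse": its z must be the negated within-site score
  hb <- attr(qa_metrics(), "higher_better")
  raw <- qa$efc[qa$site_id == "siteA"]
  zsite <- (raw - mean(raw)) / sqrt(mean((raw - mean(raw))^2))
  expect_false(hb[["efc"]])
  expect_equal(z$efc[z$site_id == "siteA"], -zsite, tolerance = 1e-12)
})

test_that("sample-SD option changes the scaling as requested", {
  qa <- qa_fixture()
  z0 <- zscore_qa_within_site(qa, ddof = 0)
  z1 <- zscore_qa_within_site(qa, ddof = 1)
  n <- sum(qa$site_id == "siteA")
  ratio <- z0$snr[qa$site_id == "siteA"] / z1$snr[qa$site_id == "siteA"]
  expect_equal(ratio, rep(sqrt(n / (n - 1)), n), tolerance = 1e-12)
})

test_that("QC failure counting implements the zero-or-one rule", {
  qa <- qa_fixture(n_per_site = 8)
  # put subject 1 at its site means: all z = 0 -> included
  for (m in qa_metrics()) qa[[m]][1] <- mean(qa[[m]][qa$site_id == "siteA"][-1])
  z <- zscore_qa_within_site(qa)
  # fabricate exact z patterns on a copy to isolate the counting rule
  z2 <- z
  z2[z2$subject_id == "Q002", qa_metrics()] <- 0
  z2[z2$subject_id == "Q002", c("cnr", "snr")] <- -2       # two failures
  z2[z2$subject_id == "Q003", qa_metrics()] <- 0
  z2[z2$subject_id == "Q003", "fber"] <- -3                # one failure
  res <- suppressMessages(apply_qc_filter(z2))
  expect_false(res$included[res$subject_id == "Q002"])
  expect_equal(res$n_failed[res$subject_id == "Q002"], 2L)
  expect_true(res$included[res$subject_id == "Q003"])
  expect_true(all(res$included[!res$subject_id %in% c("Q002")]))
  # z_cut = -Inf: everyone included
  all_in <- suppressMessages(apply_qc_filter(z2, z_cut = -Inf))
  expect_true(all(all_in$included))
})

test_that("generator-degraded subjects are exactly the ones excluded", {
  # large shift, everyone else exactly at their site mean except tiny jitter
  cfg <- cohort_config(n_subjects = 60, n_sites = 3, seed = 5,
                       qa_fail_frac = 0.1, qa_fail_n_metrics = 3,
                       qa_fail_shift = 8)
  co <- generate_cohort(cfg)
  qa <- co$qa
  # shrink natural variation so only degraded subjects can fail
  deg <- co$ground_truth$qa_degraded_subjects
  for (m in qa_metrics()) {
    for (s in unique(qa$site_id)) {
      idx <- which(qa$site_id == s & !qa$subject_id %in% deg)
      qa[[m]][idx] <- mean(qa[[m]][idx]) +
        0.01 * (qa[[m]][idx] - mean(qa[[m]][idx]))
    }
  }
  res <- suppressMessages(apply_qc_filter(zscore_qa_within_site(qa)))
  expect_setequal(res$subject_id[!res$included], deg)
  expect_length(deg, round(0.1 * 60))
})

test_that("degenerate QA inputs raise informative errors", {
  qa <- qa_fixture()
  qa$site_id[1] <- "lonely"
  expect_error(zscore_qa_within_site(qa), "lonely")
  qa2 <- qa_fixture()
  qa2$efc[qa2$site_id == "siteB"] <- 0.5
  expect_error(zscore_qa_within_site(qa2), "efc")
  expect_error(apply_qc_filter(qa_fixture()[0, ]), "empty")
})

test_that("QC decisions are invariant under subject reordering", {
  qa <- qa_fixture(n_per_site = 12, seed = 23)
  res1 <- suppressMessages(apply_qc_filter(zscore_qa_within_site(qa)))
  perm <- withr::with_seed(1, sample(nrow(qa)))
  res2 <- suppressMessages(apply_qc_filter(zscore_qa_within_site(qa[perm, ])))
  res2 <- res2[match(res1$subject_id, res2$subject_id), ]
  expect_equal(res1$included, res2$included)
  expect_equal(res1$n_failed, res2$n_failed)
})

test_that("single-site harmonisation is the identity", {
  co <- small_cohort(n = 20, sites = 1)
  cols <- paste0(dk_regions(), "__cortical_thickness")
  vals <- as.matrix(co$morphometry[cols])
  expect_warning(
    m <- fit_harmonization(vals, co$morphometry$site_id,
                           co$morphometry$age),
    "single site")
  out <- apply_harmonization(m, vals, co$morphometry$site_id,
                             co$morphometry$age)
  expect_equal(out, vals, tolerance = 1e-8)
})

test_that("pure additive two-site offset is removed exactly without EB", {
  # no noise: site B = site A + delta per region; ages matched across sites
  withr::with_seed(31, {
    n_half <- 15
    base <- matrix(rnorm(n_half * 10), n_half, 10)
    delta <- rnorm(10, sd = 2)
    vals <- rbind(base, base + matrix(delta, n_half, 10, byrow = TRUE))
    site <- rep(c("A", "B"), each = n_half)
    age <- rep(seq(7, 16, length.out = n_half), 2)
  })
  m <- fit_harmonization(vals, site, age, eb = FALSE)
  out <- apply_harmonization(m, vals, site, age)
  gap <- colMeans(out[site == "A", ]) - colMeans(out[site == "B", ])
  expect_true(all(abs(gap) < 1e-6))
})

test_that("harmonisation protects the age trend", {
  cfg <- cohort_config(n_subjects = 500, n_sites = 5, seed = 13,
                       coupling_strength = 0)
  co <- generate_cohort(cfg)
  h <- harmonize_cohort(co$morphometry)
  cols <- paste0(dk_regions(), "__cortical_thickness")
  y <- rowMeans(as.matrix(h$morphometry[cols]))
  fit <- lm(y ~ co$morphometry$age)
  slope_true <- cfg$feature_params$slope[
    cfg$feature_params$feature == "cortical_thickness"]
  est <- summary(fit)$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - slope_true), 3 * est["Std. Error"])
})

test_that("harmonisation reduces the site F-statistic on residual features", {
  site_f <- function(vals, site, age) {
    y <- rowMeans(vals)
    r <- resid(lm(y ~ age))
    summary(aov(r ~ factor(site)))[[1]]$`F value`[1]
  }
  for (s in c(3, 4, 5)) {
    co <- small_cohort(n = 150, sites = 4, seed = s)
    cols <- paste0(dk_regions(), "__cortical_volume")
    raw <- as.matrix(co$morphometry[cols])
    h <- harmonize_cohort(co$morphometry)$morphometry
    cor <- as.matrix(h[cols])
    f_raw <- site_f(raw, co$morphometry$site_id, co$morphometry$age)
    f_cor <- site_f(cor, co$morphometry$site_id, co$morphometry$age)
    expect_lt(f_cor, f_raw)
  }
})

test_that("EB harmonisation matches the reference ComBat implementation", {
  library(sva)
  co <- small_cohort(n = 80, sites = 3, seed = 41)
  cols <- paste0(dk_regions(), "__cortical_thickness")
  vals <- as.matrix(co$morphometry[cols])
  m <- fit_harmonization(vals, co$morphometry$site_id, co$morphometry$age,
                         eb = TRUE)
  mine <- apply_harmonization(m, vals, co$morphometry$site_id,
                              co$morphometry$age)
  mod <- model.matrix(~ co$morphometry$age)
  ref <- t(suppressMessages(
    sva::ComBat(dat = t(vals), batch = co$morphometry$site_id, mod = mod)))
  expect_lt(max(abs(mine - ref)), 1e-5)
})

test_that("unseen sites and layout mismatches are rejected", {
  co <- small_cohort(n = 30, sites = 2)
  cols <- paste0(dk_regions(), "__cortical_thickness")
  vals <- as.matrix(co$morphometry[cols])
  m <- fit_harmonization(vals, co$morphometry$site_id, co$morphometry$age)
  expect_error(
    apply_harmonization(m, vals, rep("siteXX", nrow(vals)),
                        co$morphometry$age),
    "unseen site")
})
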