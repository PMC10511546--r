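test_that("delta is signed predicted minus actual, with age banding", {
  ids <- sprintf("S%02d", 1:6)
  actual <- c(7, 10.9, 11, 13.9, 14, 16.5)
  d0 <- compute_delta(ids, actual, actual)
  expect_true(all(d0$delta == 0))
  expect_equal(attr(d0, "summary")[["mean"]], 0)
  d1 <- compute_delta(ids, actual, actual + 1)
  expect_true(all(d1$delta == 1))
  expect_equal(d1$age_band,
               c("childhood", "childhood", "early_adolescence",
                 "early_adolescence", "middle_adolescence",
                 "middle_adolescence"))
  expect_error(compute_delta(ids, actual, actual[-1]), "mismatch")
})

test_that("regularised models overestimate young and underestimate old", {
  # regression-to-the-mean bias: a shrunken prediction produces a
  # negative delta-age correlation on the test cohort
  co <- small_cohort(n = 250, sites = 5, seed = 61)
  h <- harmonize_cohort(co$morphometry)$morphometry
  X <- assemble_feature_set("cortical_thickness", h)
  sp <- stratified_undersample(h$subject_id, h$age, seed = 62)
  tr <- sp$partition == "train"
  m <- fit_gpr(X[tr, ], h$age[tr], kernel_spec("laplacedot"))
  d <- compute_delta(h$subject_id[!tr], h$age[!tr],
                     predict_age(m, X[!tr, ]))
  expect_lt(cor(d$delta, d$actual_age), 0)
})

test_that("partial correlation matches the residual-on-residual oracle", {
  withr::with_seed(77, {
    z <- rnorm(20)
    x <- 0.5 * z + rnorm(20)
    y <- -0.3 * z + rnorm(20)
  })
  pc <- partial_correlation(x, y, z, method = "pearson")
  oracle <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
  expect_lt(abs(pc$estimate - oracle), 1e-10)
  # p-value from the t transform with n - 3 df
  tt <- oracle * sqrt((20 - 3) / (1 - oracle^2))
  expect_equal(pc$p_value, 2 * pt(-abs(tt), 17), tolerance = 1e-12)
  # spearman equals the same formula on ranks
  ps <- partial_correlation(x, y, z, method = "spearman")
  oracle_s <- cor(resid(lm(rank(x) ~ rank(z))),
                  resid(lm(rank(y) ~ rank(z))))
  expect_lt(abs(ps$estimate - oracle_s), 1e-10)
})

test_that("partial correlation limits: independence and full explanation", {
  withr::with_seed(80, {
    x <- rnorm(2000); y <- rnorm(2000); z <- rnorm(2000)
  })
  expect_lt(abs(partial_correlation(x, y, z)$estimate), 0.08)
  # y identical to the control: nothing left to correlate
  expect_lt(abs(partial_correlation(x, z + 0, z)$estimate), 1e-6)
  expect_error(partial_correlation(x, rep(1, 2000), z), "zero-variance")
  expect_error(partial_correlation(1:3, 1:3, 1:3), "n >= 4")
})

test_that("partial correlation is invariant to linear covariate rescaling", {
  withr::with_seed(81, {
    z <- rnorm(50); x <- z + rnorm(50); y <- z + rnorm(50)
  })
  a <- partial_correlation(x, y, z)$estimate
  b <- partial_correlation(x, y, 100 * z - 3)$estimate
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("sex bias test recovers an injected male offset", {
  withr::with_seed(90, {
    n <- 500
    age <- runif(n, 6.5, 16.9)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    delta <- -0.3 * (age - 12) + (sex == "M") * 1 + rnorm(n, sd = 0.8)
  })
  st <- sex_bias_test(delta, sex, age)
  se <- abs(st$estimate / st$statistic)
  expect_lt(abs(st$estimate - 1), 3 * se)
  expect_lt(st$p_value, 0.001)
  # null after age adjustment: statistic near zero
  withr::with_seed(91, {
    delta0 <- -0.3 * (age - 12) + rnorm(n, sd = 0.8)
  })
  st0 <- sex_bias_test(delta0, sex, age)
  expect_gt(st0$p_value, 0.01)
  expect_error(sex_bias_test(delta, rep("M", n), age), "both sexes")
})

test_that("age-confounded sex differences are absorbed by the age term", {
  withr::with_seed(92, {
    n <- 2000
    sex <- sample(c("F", "M"), n, replace = TRUE)
    age <- 10 + 2 * (sex == "M") + runif(n, 0, 5)  # sex correlates with age
    delta <- -0.4 * (age - 12) + rnorm(n, sd = 0.5) # delta depends on age only
  })
  st <- sex_bias_test(delta, sex, age)
  expect_gt(st$p_value, 0.01)
})

test_that("the covariate screen produces the full bookkeeping table", {
  withr::with_seed(95, {
    n <- 82
    ids <- sprintf("S%03d", 1:n)
    age <- runif(n, 7, 16.5)
    covs <- tibble::tibble(
      subject_id = ids,
      efc = rnorm(n),
      iq = ifelse(runif(n) < 56 / 82, rnorm(n, 110, 15), NA),
      sex = sample(c("F", "M"), n, replace = TRUE))
    deltas <- lapply(setNames(feature_set_names(), feature_set_names()),
                     function(fs) {
                       compute_delta(ids, age, age + rnorm(n, sd = 1.5))
                     })
  })
  scr <- covariate_screen(deltas, covs)
  # 10 models x (EFC x 2 methods + IQ x 2 methods + age) = 50 continuous
  # rows plus 10 sex rows: the 60 tests behind the 0.05/60 threshold
  expect_equal(nrow(scr), 50 + 10)
  expect_equal(sum(scr$covariate == "sex"), 10)
  expect_equal(sum(scr$covariate == "age"), 10)
  # missing IQ handled pairwise: per-row n below the cohort size
  iq_n <- unique(scr$n[scr$covariate == "iq"])
  expect_true(all(iq_n < n))
  expect_true(all(scr$n[scr$covariate == "motion_efc"] == n))
  # independence by construction: no Bonferroni-significant row expected
  expect_equal(attr(scr, "alpha_bonferroni"), 0.05 / 60)
  expect_lt(abs(attr(scr, "mean_r")[["motion_efc"]]), 0.35)
  expect_error(covariate_screen(deltas, covs[, c("subject_id", "sex")]),
               "lacks column")
})

test_that("a known partial correlation is recovered across seeds", {
  # construct (x, y) with partial correlation rho given the control by
  # adding the control to a bivariate pair of known correlation
  rho <- 0.4
  n <- 120
  ok <- vapply(1:50, function(s) {
    withr::with_seed(3000 + s, {
      u <- rnorm(n)
      v <- rho * u + sqrt(1 - rho^2) * rnorm(n)
      z <- rnorm(n)
      x <- u + 0.8 * z
      y <- v - 1.2 * z
    })
    est <- partial_correlation(x, y, z)$estimate
    se <- (1 - rho^2) / sqrt(n - 3)       # Fisher large-sample SE
    abs(est - rho) <= 3 * se
  }, logical(1))
  expect_gte(sum(ok), 48)
})
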