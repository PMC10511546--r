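#!/usr/bin/env Rscript
# Stage 6 -- held-out test evaluation, resampling CIs and permutation
# null models.
#
# Retrains each feature set's selected model on the full training cohort
# and evaluates it ONCE on the held-out test cohort. Robustness: 20
# fresh age-stratified partitions give a mean predicted R^2 and a
# percentile 95% CI; 99 permutations of the training ages give a
# null-model p-value (Bonferroni alpha 0.05/10 across the ten models).

library(brainagemsn)

h <- read.csv("results/morphometry_harmonised.csv", check.names = FALSE)
msns <- build_cohort_msns(h)
split <- read.delim("results/split_assignment.tsv",
                    colClasses = c(subject_id = "character"))
sel <- read.delim("results/selection.tsv")

ages <- setNames(h$age, h$subject_id)
id_tr <- split_ids(split, "train")
id_te <- split_ids(split, "test")

rows <- list()
deltas <- list()
for (i in seq_len(nrow(sel))) {
  fs <- sel$feature_set[i]
  X <- assemble_feature_set(fs, h, msns)
  m <- fit_age_model(sel$algorithm[i], X[id_tr, , drop = FALSE],
                     ages[id_tr], sel$kernel[i])
  pred <- predict_age(m, X[id_te, , drop = FALSE])
  rs <- resample_performance(X, h$age, sel$algorithm[i], sel$kernel[i],
                             n_partitions = 20, seed = 20260107L)
  pt <- permutation_nhst(X, h$age, split, rs$mean_pred_r2,
                         sel$algorithm[i], sel$kernel[i],
                         n_perm = 99, seed = 20260108L)
  rows[[i]] <- tibble::tibble(
    feature_set = fs, algorithm = sel$algorithm[i],
    kernel = sel$kernel[i],
    test_mae = mae(pred, ages[id_te]),
    test_pred_r2 = predicted_r2(pred, ages[id_te]),
    mean_pred_r2 = rs$mean_pred_r2,
    ci_lower = rs$ci[1], ci_upper = rs$ci[2],
    p_value = pt$p_value,
    significant = pt$p_value < 0.05 / 10)
  deltas[[fs]] <- compute_delta(id_te, as.numeric(ages[id_te]), pred)
  write.csv(deltas[[fs]], sprintf("results/delta_%s.csv", fs),
            row.names = FALSE)
}
tab <- dplyr::bind_rows(rows)
write.table(tab, "results/test_results.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("test-cohort performance (MAE yrs / pred R2 / 95% CI / perm p):\n")
for (i in seq_len(nrow(tab))) {
  cat(sprintf("  %-22s %.2f  %5.2f  (%5.2f to %5.2f)  p = %.3f%s\n",
              tab$feature_set[i], tab$test_mae[i], tab$test_pred_r2[i],
              tab$ci_lower[i], tab$ci_upper[i], tab$p_value[i],
              ifelse(tab$significant[i], " *", "")))
}
cat("written: results/test_results.tsv and per-model delta tables\n")
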