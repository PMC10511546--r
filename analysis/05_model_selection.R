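#!/usr/bin/env Rscript
# Stage 5 -- algorithm and kernel selection on the internal validation
# cohort.
#
# Splits the included cohort 3:1 (age-stratified under-sampling) into
# training and held-out test, refines training 5:1 into internal
# training/validation, then fits every feature set x {GPR, RVR} x
# {laplacedot, rbfdot} cell on the internal training cohort and scores
# it on the internal validation cohort. The best validation predicted
# R^2 per feature set (ties: lower MAE, then GPR before RVR, laplacedot
# before rbfdot) is the model carried to the test stage.

library(brainagemsn)

h <- read.csv("results/morphometry_harmonised.csv", check.names = FALSE)
msns <- build_cohort_msns(h)

split <- stratified_undersample(h$subject_id, h$age, seed = 20260105L)
split <- internal_split(split, seed = 20260106L)
write.table(split, "results/split_assignment.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("split: %d internal train / %d validation / %d test\n",
            sum(split$partition == "internal_train"),
            sum(split$partition == "internal_validation"),
            sum(split$partition == "test")))

ages <- setNames(h$age, h$subject_id)
idi <- split_ids(split, "internal_train")
idv <- split_ids(split, "internal_validation")

grid <- list()
for (fs in feature_set_names()) {
  X <- assemble_feature_set(fs, h, msns)
  for (alg in c("GPR", "RVR")) for (k in c("laplacedot", "rbfdot")) {
    m <- fit_age_model(alg, X[idi, , drop = FALSE], ages[idi], k)
    tr <- eval_metrics(m, X[idi, , drop = FALSE], ages[idi])
    va <- eval_metrics(m, X[idv, , drop = FALSE], ages[idv])
    grid[[length(grid) + 1]] <- tibble::tibble(
      feature_set = fs, algorithm = alg, kernel = k,
      train_mae = tr$mae, train_pred_r2 = tr$pred_r2,
      mae = va$mae, pred_r2 = va$pred_r2)
  }
}
grid <- dplyr::bind_rows(grid)
sel <- select_model(grid)
write.table(grid, "results/selection_grid.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(sel, "results/selection.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("\nselected model per feature set (validation pred R2):\n")
for (i in seq_len(nrow(sel))) {
  cat(sprintf("  %-22s %s / %-10s  R2 = %5.2f  MAE = %.2f\n",
              sel$feature_set[i], sel$algorithm[i], sel$kernel[i],
              sel$pred_r2[i], sel$mae[i]))
}
cat("written: results/{selection_grid.tsv,selection.tsv,split_assignment.tsv}\n")
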