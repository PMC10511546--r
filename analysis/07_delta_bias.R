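#!/usr/bin/env Rscript
# Stage 7 -- Brainage-delta bias screens.
#
# Screens each model's signed delta (predicted - actual age) on the test
# cohort for associations with motion (EFC), IQ (both as partial
# correlations controlling actual age, Pearson and Spearman), age
# itself, and sex (linear model controlling age), at the family
# Bonferroni threshold 0.05/60.

library(brainagemsn)

cohort <- read_cohort("results/cohort")
h <- read.csv("results/morphometry_harmonised.csv", check.names = FALSE)
deltas <- lapply(setNames(feature_set_names(), feature_set_names()),
                 function(fs) {
                   d <- read.csv(sprintf("results/delta_%s.csv", fs))
                   d$subject_id <- as.character(d$subject_id)
                   d
                 })
covs <- tibble::tibble(
  subject_id = h$subject_id,
  efc = cohort$qa$efc[match(h$subject_id, cohort$qa$subject_id)],
  iq = h$iq, sex = h$sex)

scr <- covariate_screen(deltas, covs)
write.table(scr, "results/bias_screen.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

mr <- attr(scr, "mean_r")
cat(sprintf("mean Pearson r across models: EFC %.3f, IQ %.3f, age %.3f\n",
            mr[["motion_efc"]], mr[["iq"]], mr[["age"]]))
cat(sprintf("%d of %d tests significant at alpha = %.6f\n",
            sum(scr$significant), nrow(scr),
            attr(scr, "alpha_bonferroni")))
all_d <- unlist(lapply(deltas, function(d) d$delta))
cat(sprintf("delta across models: mean %.2f (SD %.2f), median %.2f yrs\n",
            mean(all_d), sd(all_d), median(all_d)))
cat("written: results/bias_screen.tsv\n")
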