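#!/usr/bin/env Rscript
# Stage 2 -- image-quality control.
#
# Z-scores the six spatial QA metrics within each acquisition site
# (re-signed so higher = better quality), codes a metric as failed below
# z = -1.5, and keeps subjects with zero or one failed metric.

library(brainagemsn)

cohort <- read_cohort("results/cohort")
qc <- apply_qc_filter(zscore_qa_within_site(cohort$qa),
                      z_cut = -1.5, max_fail = 1)
write.table(qc, "results/qc_report.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

deg <- cohort$ground_truth$qa_degraded_subjects
caught <- intersect(deg, qc$subject_id[!qc$included])
cat(sprintf("included %d / %d subjects (%d excluded)\n",
            sum(qc$included), nrow(qc), sum(!qc$included)))
cat(sprintf("of %d deliberately degraded subjects, %d were excluded\n",
            length(deg), length(caught)))
cat("written: results/qc_report.tsv\n")
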