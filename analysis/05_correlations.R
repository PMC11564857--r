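#!/usr/bin/env Rscript
# Stage 5: Spearman correlations of the global (single-ROI) metrics with
# CSF biomarkers and neuropsychological raw scores, within athletes only,
# plus norm-based Z-scoring with deficit classification at Z <= -1.5.

library(tractomnibus)

coh <- read_cohort("results/cohort")
norms <- read_norms("results/cohort/norms.csv")

ct <- correlation_table(coh$panel, coh$profiles, norms = norms)
write.table(ct, "results/correlations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ath <- coh$profiles[coh$profiles$group == "athlete",
                    c("subject_id", intersect(norms$test,
                                              names(coh$profiles)))]
zb <- zscore_battery(ath, norms)
write.table(zb$flags, "results/deficits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(zb$per_test, "results/deficit_prevalence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

nfl <- ct[ct$outcome == "NfL", ]
cat("NfL correlations (athletes):\n")
print(nfl[order(-abs(nfl$r_s)), c("metric", "r_s", "p", "n")][1:5, ])
cat(sprintf("athletes with at least one deficit (Z <= -1.5): %.0f%%\n",
            100 * zb$prevalence))
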