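#!/usr/bin/env Rscript
# Stage 2: per-tract Mann-Whitney comparisons and the single-WM-ROI
# (global white matter) summary, at alpha 0.05 and 0.01.

library(tractomnibus)

coh <- read_cohort("results/cohort")
stats <- compare_tracts(coh$panel, alphas = c(0.05, 0.01))
roi <- single_wm_roi(coh$panel)

write.table(stats, "results/tract_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(roi$summary, "results/single_roi.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

counts <- tapply(stats$sig_0.05, stats$metric, sum)
cat("significant tracts per metric (alpha 0.05):\n")
print(counts)
glob <- roi$summary[roi$summary$p < 0.05, "metric"]
cat("global (single-ROI) group differences at p < 0.05:",
    paste(glob, collapse = ", "), "\n")
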