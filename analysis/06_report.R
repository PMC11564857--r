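#!/usr/bin/env Rscript
# Stage 6: assemble the significant-fraction report from the per-tract
# table: fraction of the 72 x 11 = 792 comparisons significant at 0.05,
# split by modality, with percentages rounded half away from zero.

library(tractomnibus)

stats <- read.delim("results/tract_stats.tsv")
counts <- tapply(stats$sig_0.05, stats$metric, sum)
s <- summarize_significance(setNames(as.numeric(counts), names(counts)),
                            n_tracts = max(table(stats$metric)))
write.table(s, "results/significance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("significant comparisons: DTI %d%% (%d/%d), DKI %d%% (%d/%d), total %d%% (%d/%d)\n",
            s$pct[1], s$n_significant[1], s$n_tests[1],
            s$pct[2], s$n_significant[2], s$n_tests[2],
            s$pct[3], s$n_significant[3], s$n_tests[3]))
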