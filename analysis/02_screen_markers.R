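#!/usr/bin/env Rscript
# Per-marker differential screening (Welch t on log10 concentrations,
# Bonferroni-corrected) between cancer and benign after borderline
# exclusion, plus the three-group stage comparison for the strongest marker.

suppressPackageStartupMessages(library(uropanel))
coh <- apply_exclusions(read_cohort("results/cohort.tsv"))

scr <- screen_markers(coh)
write.table(scr, "results/screening.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
n_sig <- sum(scr$p_corrected < 0.05, na.rm = TRUE)
cat(sprintf("%d of %d markers differ at corrected p < 0.05:\n",
            n_sig, nrow(scr)))
print(head(scr[scr$p_corrected < 0.05, ], 10), row.names = FALSE)

# benign vs early vs advanced for the top-ranked marker
top <- scr$marker[1]
stage <- ifelse(coh$samples$group == "benign", "benign",
                ifelse(coh$samples$figo_stage %in% c("I", "II"),
                       "early", "advanced"))
av <- anova_tukey(log10(coh$concentrations[, top] + 1e-6), stage)
cat(sprintf("\n%s across benign/early/advanced: ANOVA F = %.1f, p = %.3g\n",
            top, av$f, av$p))
print(av$pairs, row.names = FALSE)
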