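#!/usr/bin/env Rscript
# Marker importance from L1-regularized logistic models: 2000 repetitions
# of 10-fold cross-validation on the standardized cohort, coefficients
# taken at the deviance-minimizing lambda, markers ranked by mean
# absolute standardized coefficient.

suppressPackageStartupMessages(library(uropanel))
coh <- apply_exclusions(read_cohort("results/cohort.tsv"))

imp <- rank_by_lasso(coh, n_iter = 2000, seed = 4L)
write.table(imp$summary, "results/lasso_rank.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
long <- data.frame(iteration = rep(seq_len(nrow(imp$coefficients)),
                                   ncol(imp$coefficients)),
                   marker = rep(colnames(imp$coefficients),
                                each = nrow(imp$coefficients)),
                   coefficient = as.numeric(imp$coefficients))
write.table(long, "results/lasso_coefficients.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(imp)
cat("\nselection frequency of the top 8:\n")
print(head(imp$summary[c("marker", "selection_freq")], 8), row.names = FALSE)
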