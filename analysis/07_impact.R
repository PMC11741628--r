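#!/usr/bin/env Rscript
# Population impact: fraction of cases prevented by the protective
# genotype under all-high-score and all-low-score scenarios, and the
# normalized iKIR-score OR within genotype carriers.

library(ikirmod)
coh <- score_cohort(read_cohort("results/cohort.tsv"))
DQ6 <- "DQA1*01:02-DQB1*06:02"
prevalence <- 0.003  # European T1D prevalence, order of magnitude

se <- stratified_effect(coh, DQ6, threshold = 1.75)
f <- mean(genotype_carriage(coh, DQ6)[coh$status == 0])  # control carriage
pf <- function(lnor) prevented_fraction(f, or = exp(lnor),
                                        prevalence = prevalence)
pf_high <- pf(se$high$ln_or); pf_low <- pf(se$low$ln_or)
cat(sprintf("Prevented fraction if everyone were score-high: %.1f%%\n",
            100 * pf_high))
cat(sprintf("Prevented fraction if everyone were score-low:  %.1f%%\n",
            100 * pf_low))
cat(sprintf("Relative increase: %.1f%%\n",
            relative_increase(100 * pf_low, 100 * pf_high)))

nor <- normalized_score_or(coh, DQ6)
cat(sprintf("Normalized-score OR in %s carriers: %.2f (95%% CI %.2f-%.2f)\n",
            DQ6, nor$or, nor$ci_low, nor$ci_high))
out <- data.frame(pf_high = pf_high, pf_low = pf_low,
                  relative_increase_pct = relative_increase(100 * pf_low,
                                                            100 * pf_high),
                  score_or = nor$or, score_or_ci_low = nor$ci_low,
                  score_or_ci_high = nor$ci_high)
write.table(out, "results/impact.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/impact.tsv\n")
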