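#!/usr/bin/env Rscript
# Regulated-gene sets by the microarray-style thresholds (fold > 1.70,
# ANOVA p < 0.05), the co-regulation overlap between the two knockdown
# models (hypergeometric test against the 2000-gene universe) and the
# enrichment of chromatin occupancy among regulated genes (Fisher exact).

source(file.path("analysis", "_common.R"))

res <- get_workflow()
regA <- res$expression$regA; regB <- res$expression$regB
ov <- res$overlap; oe <- res$occ_enrich

cat(sprintf("Model 1 regulated genes: %d up, %d down\n",
            length(regA$up), length(regA$down)))
cat(sprintf("Model 2 regulated genes: %d up, %d down\n",
            length(regB$up), length(regB$down)))
cat(sprintf("Co-regulated overlap: %d observed vs %.2f expected (%.2f%% of the universe per set); p = %.3g\n",
            ov$observed, ov$expected, 100 * ov$fraction_A, ov$p_value))
cat(sprintf("Occupancy among regulated genes: %.1f%% vs %.2f%% among others; OR = %.1f, p = %.3g\n",
            100 * oe$fraction_occupied_regulated,
            100 * oe$fraction_occupied_other, oe$odds_ratio, oe$p_value))

write_regulated_tsv(regA, file.path("results", "05_regulated_model1.tsv"))
write_regulated_tsv(regB, file.path("results", "05_regulated_model2.tsv"))
report <- c("metric\tvalue",
            sprintf("overlap_observed\t%d", ov$observed),
            sprintf("overlap_expected\t%.5f", ov$expected),
            sprintf("overlap_p\t%.5g", ov$p_value),
            sprintf("occupancy_odds_ratio\t%.5f", oe$odds_ratio),
            sprintf("occupancy_p\t%.5g", oe$p_value))
writeLines(report, file.path("results", "05_enrichment_report.tsv"))
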