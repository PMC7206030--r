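#!/usr/bin/env Rscript
# Genic annotation of the filtered peaks: each summit is classified as
# promoter / exon / intron / intergenic (precedence promoter > exon >
# intron) and per-gene occupancy is summarized.

source(file.path("analysis", "_common.R"))

res <- get_workflow()
s <- res$occupancy

cat("Peak distribution over genic categories:\n")
print(s$category_counts)
cat(sprintf("Fixture genes with at least one peak: %d / %d (%.1f%%)\n",
            sum(s$per_gene > 0), length(s$per_gene),
            100 * s$fraction_occupied))

write_annotation_tsv(res$classified, s,
                     file.path("results", "04_peak_annotation.tsv"),
                     file.path("results", "04_annotation_summary.tsv"))
cat("Annotation written to results/04_peak_annotation.tsv\n")
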