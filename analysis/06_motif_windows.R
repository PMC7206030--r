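#!/usr/bin/env Rscript
# Motif-discovery export: 400 bp windows (+/- 200 bp around the summit) of
# the top fold-enrichment-ranked peaks annotated to regulated genes,
# written as FASTA for external motif tools, plus the internal T-rich
# 21-mer scan.

source(file.path("analysis", "_common.R"))

res <- get_workflow()
w <- res$windows
scan <- res$scan

cat(sprintf("Summit windows extracted: %d (of %d filtered peaks; restricted to regulated genes)\n",
            nrow(w), nrow(res$filtered)))
cat(sprintf("Windows containing a 21 bp T-rich motif (>= 80%% T): %d / %d\n",
            attr(scan, "n_positive"), nrow(w)))

write_windows_fasta(w, file.path("results", "06_summit_windows.fasta"))
write.table(data.frame(peak_id = scan$peak_id,
                       max_t_fraction = round(scan$max_t_fraction, 4),
                       positive = scan$positive),
            file.path("results", "06_t_rich_scan.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
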