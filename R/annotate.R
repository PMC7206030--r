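#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `exon` records via `rtracklayer` and converts the
#' 1-based inclusive GFF3 coordinates to the package's 0-based half-open
#' convention. Genes without exon records receive a single exon equal to
#' their span. A light pre-scan reports malformed lines (wrong column
#' count) with their line numbers before parsing.
#'
#' @param path GFF3 file path.
#' @return list with data.frames `genes` (`gene_id`, `contig`, `strand`,
#'   `start`, `end`) and `exons` (`gene_id`, `contig`, `start`, `end`).
#' @export
read_gff <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nfield != 9))
    stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, got %d",
                 body[which(nfield != 9)[1]], nfield[which(nfield != 9)[1]]))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  is_gene <- df$type == "gene"
  genes <- data.frame(gene_id = as.character(df$ID[is_gene]),
                      contig = as.character(df$seqnames[is_gene]),
                      strand = as.character(df$strand[is_gene]),
                      start = df$start[is_gene] - 1L,
                      end = df$end[is_gene])
  is_exon <- df$type == "exon"
  parent <- vapply(df$Parent[is_exon], function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  exons <- data.frame(gene_id = parent,
                      contig = as.character(df$seqnames[is_exon]),
                      start = df$start[is_exon] - 1L,
                      end = df$end[is_exon])
  missing_ex <- setdiff(genes$gene_id, exons$gene_id)
  if (length(missing_ex)) {
    g <- genes[genes$gene_id %in% missing_ex, ]
    exons <- rbind(exons, data.frame(gene_id = g$gene_id, contig = g$contig,
                                     start = g$start, end = g$end))
  }
  rownames(genes) <- rownames(exons) <- NULL
  list(genes = genes, exons = exons)
}

#' Promoter intervals for gene models
#'
#' The promoter is `TSS +/- halfwidth` as a half-open interval, strand-aware
#' (TSS is the gene start on `+`, the gene end - 1 on `-`), clipped to
#' contig bounds when lengths are supplied.
#'
#' @param genes data.frame of gene models (0-based half-open).
#' @param halfwidth promoter half-width in bp (default 2000).
#' @param contigs optional named contig lengths for clipping.
#' @return data.frame `gene_id`, `contig`, `start`, `end`.
#' @export
promoter_intervals <- function(genes, halfwidth = 2000, contigs = NULL) {
  tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  start <- pmax(tss - halfwidth, 0L)
  end <- tss + halfwidth
  if (!is.null(contigs)) end <- pmin(end, contigs[genes$contig])
  data.frame(gene_id = genes$gene_id, contig = genes$contig,
             start = as.integer(start), end = as.integer(end))
}

point_in <- function(intervals, contig, pos) {
  intervals$contig == contig & intervals$start <= pos & pos < intervals$end
}

#' Classify peaks into genic categories
#'
#' Each peak is classified by its summit position (default) or by interval
#' overlap. Precedence when a position hits multiple feature types:
#' promoter > exon > intron; peaks hitting no gene span or promoter are
#' intergenic. All genes whose span or promoter contains the summit (or
#' overlaps the peak, in overlap mode) are reported.
#'
#' @param peaks data.frame of peaks (needs `contig`, `start`, `end`,
#'   `summit`).
#' @param models list with `genes` and `exons` data.frames (e.g. from
#'   [read_gff()] or a [simulate_genome()] fixture).
#' @param promoter_halfwidth promoter half-width in bp (default 2000).
#' @param mode `"summit"` (classify by the summit base) or `"overlap"`
#'   (classify by any overlap of the peak interval).
#' @param contigs optional named contig lengths for promoter clipping.
#' @return `peaks` with added columns `category` (factor: promoter, exon,
#'   intron, intergenic) and `genes` (comma-separated gene ids, `""` for
#'   none).
#' @export
classify_peaks <- function(peaks, models, promoter_halfwidth = 2000,
                           mode = c("summit", "overlap"), contigs = NULL) {
  mode <- match.arg(mode)
  genes <- models$genes; exons <- models$exons
  prom <- promoter_intervals(genes, promoter_halfwidth, contigs)
  category <- character(nrow(peaks)); hit_genes <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ct <- as.character(peaks$contig[i])
    if (mode == "summit") {
      pos <- peaks$summit[i]
      in_prom <- point_in(prom, ct, pos)
      in_span <- point_in(genes, ct, pos)
      in_exon <- point_in(exons, ct, pos)
    } else {
      ov <- function(d) d$contig == ct & d$start < peaks$end[i] &
        peaks$start[i] < d$end
      in_prom <- ov(prom); in_span <- ov(genes); in_exon <- ov(exons)
    }
    category[i] <- if (any(in_prom)) "promoter"
      else if (any(in_exon)) "exon"
      else if (any(in_span)) "intron"
      else "intergenic"
    ids <- union(genes$gene_id[in_span], prom$gene_id[in_prom])
    hit_genes[i] <- paste(sort(ids), collapse = ",")
  }
  peaks$category <- factor(category,
                           levels = c("promoter", "exon", "intron", "intergenic"))
  peaks$genes <- hit_genes
  peaks
}

#' Occupancy summary over genes
#'
#' Summarizes classified peaks: counts per genic category, per-gene peak
#' counts (a peak counts towards every gene whose span or promoter contains
#' its summit), and the fraction of genes with at least one peak.
#'
#' @param classified data.frame from [classify_peaks()].
#' @param models list with a `genes` data.frame.
#' @return list with `category_counts` (named integer), `per_gene` (named
#'   integer vector over all genes) and `fraction_occupied`.
#' @export
occupancy_summary <- function(classified, models) {
  cats <- c("promoter", "exon", "intron", "intergenic")
  category_counts <- stats::setNames(
    as.integer(table(factor(classified$category, levels = cats))), cats)
  per_gene <- stats::setNames(integer(nrow(models$genes)),
                              models$genes$gene_id)
  if (nrow(classified)) {
    hits <- unlist(strsplit(classified$genes[classified$genes != ""], ","))
    if (length(hits)) {
      tab <- table(hits)
      per_gene[names(tab)] <- as.integer(tab)
    }
  }
  list(category_counts = category_counts, per_gene = per_gene,
       fraction_occupied = if (length(per_gene)) mean(per_gene > 0) else 0)
}

#' Write an annotation summary as TSV files
#' @param classified data.frame from [classify_peaks()].
#' @param summary list from [occupancy_summary()].
#' @param peaks_path,summary_path output TSV paths.
#' @return `summary_path`, invisibly.
#' @export
write_annotation_tsv <- function(classified, summary, peaks_path,
                                 summary_path) {
  df <- data.frame(name = sprintf("peak_%d", seq_len(nrow(classified))),
                   contig = classified$contig, start = classified$start,
                   end = classified$end, summit = classified$summit,
                   category = as.character(classified$category),
                   genes = classified$genes)
  utils::write.table(df, peaks_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lines <- c("metric\tvalue",
             sprintf("peaks_%s\t%d", names(summary$category_counts),
                     summary$category_counts),
             sprintf("genes_total\t%d", length(summary$per_gene)),
             sprintf("genes_with_peak\t%d", sum(summary$per_gene > 0)),
             sprintf("fraction_genes_occupied\t%.5f",
                     summary$fraction_occupied))
  writeLines(lines, summary_path)
  invisible(summary_path)
}
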