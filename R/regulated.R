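#' Derive up/down regulated gene sets from a two-group expression matrix
#'
#' Per gene, the fold change is the ratio of group means on the linear
#' scale (group B over group A) and the p-value comes from a two-group
#' one-way analysis of variance — computed as the equivalent equal-variance
#' two-sample t-test — on log2-transformed values. A gene is up-regulated
#' when `fold > fold_min` and `p < alpha`, down-regulated when
#' `fold < 1/fold_min` and `p < alpha`; both fold thresholds are strict.
#'
#' @param matrix numeric matrix of linear-scale expression, genes x samples,
#'   with gene ids as rownames.
#' @param groups factor (or vector) of two group labels per column; the
#'   first level is the baseline (group A).
#' @param fold_min linear fold-change threshold (default 1.70, strict `>`).
#' @param alpha p-value threshold (default 0.05, strict `<`).
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, matching filtering on the raw test p-value;
#'   `"BH"` available).
#' @return a `RegulatedGeneSet`: list with `universe_n`, `up`, `down`
#'   (character vectors of gene ids) and `table` (per-gene `fold`,
#'   `log2fc`, `p`).
#' @export
differential_filter <- function(matrix, groups, fold_min = 1.70,
                                alpha = 0.05, adjust = "none") {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  a <- groups == levels(groups)[1]
  b <- groups == levels(groups)[2]
  if (sum(a) < 2 || sum(b) < 2) stop("each group needs >= 2 replicates")
  lg <- log2(matrix)
  fold <- rowMeans(matrix[, b, drop = FALSE]) /
    rowMeans(matrix[, a, drop = FALSE])
  p <- vapply(seq_len(nrow(lg)), function(i)
    stats::t.test(lg[i, b], lg[i, a], var.equal = TRUE)$p.value, numeric(1))
  p <- stats::p.adjust(p, method = adjust)
  genes <- rownames(matrix)
  up <- genes[fold > fold_min & p < alpha]
  down <- genes[fold < 1 / fold_min & p < alpha]
  structure(list(universe_n = nrow(matrix), up = up, down = down,
                 table = data.frame(gene_id = genes, fold = fold,
                                    log2fc = log2(fold), p = p,
                                    row.names = NULL)),
            class = "RegulatedGeneSet")
}

#' @export
print.RegulatedGeneSet <- function(x, ...) {
  cat(sprintf("RegulatedGeneSet: %d up, %d down of %d genes tested\n",
              length(x$up), length(x$down), x$universe_n))
  invisible(x)
}

#' Overlap of two gene sets against a common universe
#'
#' Observed overlap, the expected overlap under independence
#' (`|A| * |B| / N`), the marginal fractions `|A|/N` and `|B|/N` (the
#' "random probability" that a random gene falls in each set), and the
#' hypergeometric upper-tail p-value `P(X >= observed)` for drawing `|B|`
#' genes from a universe containing `|A|` successes.
#'
#' @param setA,setB character vectors of gene ids (subsets of the universe).
#' @param universe_n universe size (>= `|A U B|`).
#' @return list with `observed`, `expected`, `fraction_A`, `fraction_B`,
#'   `p_value`.
#' @export
overlap_enrichment <- function(setA, setB, universe_n) {
  setA <- unique(setA); setB <- unique(setB)
  if (universe_n < length(union(setA, setB)))
    stop("universe smaller than the union of the two sets")
  observed <- length(intersect(setA, setB))
  expected <- length(setA) * length(setB) / universe_n
  p <- stats::phyper(observed - 1, length(setA), universe_n - length(setA),
                     length(setB), lower.tail = FALSE)
  list(observed = observed, expected = expected,
       fraction_A = length(setA) / universe_n,
       fraction_B = length(setB) / universe_n,
       p_value = p)
}

#' Enrichment of chromatin occupancy among regulated genes
#'
#' Builds the 2x2 table (regulated vs not) x (occupied vs not) over the
#' gene universe. The odds ratio uses the Haldane correction (0.5 added to
#' every cell) when any cell is zero. The p-value is the two-sided Fisher
#' exact test for universes up to 10,000 genes and the hypergeometric upper
#' tail beyond that.
#'
#' @param genes_with_peaks character vector: genes with >= 1 peak.
#' @param regulated character vector: regulated genes.
#' @param universe_n universe size; both sets must fit inside it.
#' @return list with `table` (2x2 matrix), `odds_ratio`, `p_value`, and
#'   `fraction_occupied_regulated` / `fraction_occupied_other`.
#' @export
occupancy_enrichment <- function(genes_with_peaks, regulated, universe_n) {
  genes_with_peaks <- unique(genes_with_peaks)
  regulated <- unique(regulated)
  if (universe_n < length(union(genes_with_peaks, regulated)))
    stop("universe smaller than the union of the two sets")
  a <- length(intersect(regulated, genes_with_peaks))   # regulated & occupied
  b <- length(regulated) - a                            # regulated, no peak
  cc <- length(genes_with_peaks) - a                    # occupied, not regulated
  d <- universe_n - a - b - cc
  if (d < 0) stop("inconsistent universe size")
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("regulated", "not_regulated"),
                                c("occupied", "not_occupied")))
  or <- if (any(tab == 0)) ((a + .5) * (d + .5)) / ((b + .5) * (cc + .5))
        else (a * d) / (b * cc)
  p <- if (universe_n <= 10000) stats::fisher.test(tab)$p.value
       else stats::phyper(a - 1, length(genes_with_peaks),
                          universe_n - length(genes_with_peaks),
                          length(regulated), lower.tail = FALSE)
  list(table = tab, odds_ratio = or, p_value = p,
       fraction_occupied_regulated = if (a + b > 0) a / (a + b) else NA_real_,
       fraction_occupied_other = if (cc + d > 0) cc / (cc + d) else NA_real_)
}

#' Write a regulated-gene set and enrichment report as TSV
#' @param rgs a [differential_filter()] result.
#' @param path output TSV path (gene_id, direction, fold, log2fc, p).
#' @return `path`, invisibly.
#' @export
write_regulated_tsv <- function(rgs, path) {
  tab <- rgs$table
  dir <- ifelse(tab$gene_id %in% rgs$up, "up",
                ifelse(tab$gene_id %in% rgs$down, "down", "ns"))
  keep <- dir != "ns"
  df <- data.frame(gene_id = tab$gene_id[keep], direction = dir[keep],
                   fold = sprintf("%.5f", tab$fold[keep]),
                   log2fc = sprintf("%.5f", tab$log2fc[keep]),
                   p = sprintf("%.5g", tab$p[keep]))
  df <- df[order(df$direction, df$gene_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
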