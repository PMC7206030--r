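#' Rolling mean with edge truncation
#'
#' Mean of `x` over a centred window of `width` bases, truncated at the
#' vector ends (the window shrinks rather than padding with zeros).
#' @param x numeric vector.
#' @param width window width in bases.
#' @return numeric vector of the same length.
#' @keywords internal
rolling_mean <- function(x, width) {
  n <- length(x)
  half <- width %/% 2
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Poisson upper tail P(X >= x | lambda), vectorized, computed on the log
# scale for numerical range; returns both p and -log10(p)
poisson_upper_tail <- function(x, lambda) {
  logp <- stats::ppois(x - 1, lambda, lower.tail = FALSE, log.p = TRUE)
  list(p = exp(logp), neglog10 = -logp / log(10))
}

#' Call peaks on a consensus track against the input lane
#'
#' A transparent local-Poisson caller in the spirit of MACS: every base of
#' the consensus lane is tested against a local background rate taken from
#' the input lane, significant bases are merged into regions, and short
#' regions are dropped.
#'
#' The test is computed on the count scale: both tracks must be normalized
#' to the same mapped-read total, and the consensus track's recorded `scale`
#' factor is used to recover counts, so the Poisson model stays valid after
#' depth normalization. The local rate at a base is
#' `max(genome-wide input mean, 1 kb window mean, 10 kb window mean,
#' pseudo_rate)`, all measured on the depth-matched input.
#'
#' @param consensus,input [coverage_track()]s normalized to the same
#'   mapped-read total (see [normalize_track()]).
#' @param p_cutoff per-base Poisson upper-tail p-value cutoff (default
#'   1e-5).
#' @param min_gap significant bases closer than this are merged into one
#'   region (default 130 bp, the nominal read length).
#' @param min_length regions shorter than this are dropped (default 100 bp).
#' @param pseudo_rate floor on the local rate, preventing zero-rate tests
#'   and division by zero in fold enrichment (default 0.1).
#' @param even,odd optional raw even/odd lanes; when supplied, per-peak
#'   statistics (fold enrichment, average coverage, even/odd Pearson r) are
#'   filled in via [peak_statistics()].
#' @return data.frame of peaks: `contig`, `start`, `end` (0-based half-open),
#'   `summit` (0-based position of the consensus maximum; leftmost on ties),
#'   `length`, `p_value` (minimum per-base p), `neglog10_p`, and — when
#'   `even`/`odd` are given — `fold_enrichment`, `avg_coverage`,
#'   `pearson_r`.
#' @export
call_peaks <- function(consensus, input, p_cutoff = 1e-5, min_gap = 130,
                       min_length = 100, pseudo_rate = 0.1,
                       even = NULL, odd = NULL) {
  stopifnot_same_contigs(consensus, input)
  if (min_gap < 1 || min_length < 1) stop("min_gap and min_length must be >= 1")
  if (abs(consensus$total_mapped_reads - input$total_mapped_reads) >
      1e-6 * max(consensus$total_mapped_reads, input$total_mapped_reads))
    stop("tracks must be normalized to the same mapped-read total before calling")
  s <- consensus$scale
  peaks <- list()
  for (contig in names(consensus$values)) {
    x <- round(consensus$values[[contig]] / s)   # consensus counts
    lam_base <- input$values[[contig]] / s       # depth-matched input rate
    lam <- pmax(mean(lam_base), rolling_mean(lam_base, 1000),
                rolling_mean(lam_base, 10000), pseudo_rate)
    pt <- poisson_upper_tail(x, lam)
    sig <- pt$p < p_cutoff
    if (!any(sig)) next
    r <- rle(sig)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    reg <- cbind(starts[r$values], ends[r$values])   # 1-based inclusive runs
    # merge runs separated by < min_gap
    if (nrow(reg) > 1) {
      keep_s <- reg[1, 1]; keep_e <- reg[1, 2]; merged <- list()
      for (i in 2:nrow(reg)) {
        if (reg[i, 1] - keep_e - 1 < min_gap) keep_e <- reg[i, 2]
        else { merged[[length(merged) + 1]] <- c(keep_s, keep_e)
               keep_s <- reg[i, 1]; keep_e <- reg[i, 2] }
      }
      merged[[length(merged) + 1]] <- c(keep_s, keep_e)
      reg <- do.call(rbind, merged)
    }
    reg <- reg[reg[, 2] - reg[, 1] + 1 >= min_length, , drop = FALSE]
    for (i in seq_len(nrow(reg))) {
      a <- reg[i, 1]; b <- reg[i, 2]
      summit <- a + which.max(consensus$values[[contig]][a:b]) - 1
      peaks[[length(peaks) + 1]] <- data.frame(
        contig = contig, start = a - 1L, end = b, summit = summit - 1L,
        length = b - a + 1L, p_value = min(pt$p[a:b]),
        neglog10_p = max(pt$neglog10[a:b]))
    }
  }
  out <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(contig = character(), start = integer(), end = integer(),
               summit = integer(), length = integer(), p_value = numeric(),
               neglog10_p = numeric())
  rownames(out) <- NULL
  if (!is.null(even) && !is.null(odd) && nrow(out)) {
    st <- lapply(seq_len(nrow(out)), function(i)
      peak_statistics(out[i, c("contig", "start", "end")], consensus, input,
                      even, odd, pseudo_rate = pseudo_rate))
    out$fold_enrichment <- vapply(st, `[[`, numeric(1), "fold_enrichment")
    out$avg_coverage <- vapply(st, `[[`, numeric(1), "avg_coverage")
    out$pearson_r <- vapply(st, `[[`, numeric(1), "pearson_r")
  }
  out
}

#' Per-peak filter statistics
#'
#' Computes the three statistics the multi-criteria filter acts on:
#' fold enrichment of the consensus lane against the input lane, average
#' consensus coverage, and the Pearson correlation of the even and odd
#' lanes' per-base coverage over the region (the even/odd concordance).
#'
#' @param region one-row data.frame or list with `contig`, `start`, `end`
#'   (0-based half-open; length >= 2 for the correlation).
#' @param consensus,input normalized [coverage_track()]s.
#' @param even,odd raw probe-lane [coverage_track()]s.
#' @param pseudo_rate floor on the input mean in the fold-enrichment
#'   denominator.
#' @return list with `fold_enrichment`, `avg_coverage`, `pearson_r`
#'   (`NA` when either lane is constant over the region — an undefined
#'   correlation, treated downstream as failing the filter).
#' @export
peak_statistics <- function(region, consensus, input, even, odd,
                            pseudo_rate = 0.1) {
  contig <- as.character(region$contig)
  if (region$end <= region$start) stop("zero-length region")
  idx <- (region$start + 1):region$end
  if (max(idx) > length(consensus$values[[contig]]))
    stop("region outside track bounds")
  cv <- consensus$values[[contig]][idx]
  iv <- input$values[[contig]][idx]
  ev <- even$values[[contig]][idx]
  ov <- odd$values[[contig]][idx]
  pearson_r <- if (length(idx) < 2 || stats::sd(ev) == 0 || stats::sd(ov) == 0)
    NA_real_ else stats::cor(ev, ov, method = "pearson")
  list(fold_enrichment = mean(cv) / max(mean(iv), pseudo_rate),
       avg_coverage = mean(cv),
       pearson_r = pearson_r)
}

#' Multi-criteria peak filter
#'
#' Retains peaks with fold enrichment strictly greater than `fe_min`,
#' average coverage strictly greater than `cov_min`, even/odd Pearson
#' correlation strictly greater than `r_min` (an undefined correlation
#' fails), length at least `min_length`, and summit at least
#' `summit_window` bases from both peak ends.
#'
#' @param peaks data.frame from [call_peaks()] with statistics populated.
#' @param fe_min fold-enrichment threshold (default 2; strict `>`).
#' @param cov_min average-coverage threshold (default 1.5; strict `>`).
#' @param r_min Pearson-correlation threshold (default 0.3; strict `>`).
#' @param min_length minimum peak length in bp.
#' @param summit_window minimum distance (bp) from the summit to either peak
#'   end.
#' @return the surviving subset of `peaks`.
#' @export
filter_peaks <- function(peaks, fe_min = 2, cov_min = 1.5, r_min = 0.3,
                         min_length = 100, summit_window = 10) {
  if (!nrow(peaks)) return(peaks)
  if (!all(c("fold_enrichment", "avg_coverage", "pearson_r") %in% names(peaks)))
    stop("peak statistics must be populated before filtering")
  r_ok <- !is.na(peaks$pearson_r) & peaks$pearson_r > r_min
  keep <- peaks$fold_enrichment > fe_min &
    peaks$avg_coverage > cov_min &
    r_ok &
    peaks$length >= min_length &
    (peaks$summit - peaks$start) >= summit_window &
    (peaks$end - 1 - peaks$summit) >= summit_window
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank peaks by fold enrichment
#'
#' Stable descending sort by fold enrichment; ties broken by smaller
#' p-value, then genomic order (contig, start).
#'
#' @param peaks data.frame of peaks with statistics populated.
#' @param top_n number of top peaks to return (> 0); fewer are returned if
#'   fewer exist.
#' @return the ranked head of `peaks`.
#' @export
rank_peaks <- function(peaks, top_n = nrow(peaks)) {
  if (top_n <= 0) stop("top_n must be > 0")
  if (!nrow(peaks)) return(peaks)
  ord <- order(-peaks$fold_enrichment, peaks$p_value,
               as.character(peaks$contig), peaks$start)
  out <- peaks[ord[seq_len(min(top_n, nrow(peaks)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write peaks as ENCODE narrowPeak (BED6+4)
#'
#' Column 7 is fold enrichment, column 8 the -log10 p-value, column 9 is -1
#' (no q-value; the pipeline filters on raw p), column 10 the summit offset
#' from the peak start.
#'
#' @param peaks data.frame of peaks with statistics populated.
#' @param path output path.
#' @param sidecar_tsv optional path for a TSV sidecar with the filter
#'   statistics per peak.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path, sidecar_tsv = NULL) {
  name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  score <- pmin(1000L, as.integer(round(10 * peaks$neglog10_p)))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%.5f\t%.5f\t-1\t%d",
                   peaks$contig, peaks$start, peaks$end, name, score,
                   peaks$fold_enrichment, peaks$neglog10_p,
                   peaks$summit - peaks$start)
  writeLines(lines, path)
  if (!is.null(sidecar_tsv)) {
    df <- data.frame(name = name, contig = peaks$contig, start = peaks$start,
                     end = peaks$end, summit = peaks$summit,
                     length = peaks$length,
                     fold_enrichment = sprintf("%.5f", peaks$fold_enrichment),
                     avg_coverage = sprintf("%.5f", peaks$avg_coverage),
                     pearson_r = sprintf("%.5f", peaks$pearson_r),
                     neglog10_p = sprintf("%.5f", peaks$neglog10_p))
    utils::write.table(df, sidecar_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read peaks from a narrowPeak file
#'
#' Escape hatch for importing externally produced peak calls into the
#' annotation and motif-window stages. Statistics columns map back from the
#' narrowPeak fields; `avg_coverage` and `pearson_r` are `NA` unless a
#' sidecar TSV written by [write_narrowpeak()] is supplied.
#'
#' @param path narrowPeak path.
#' @param sidecar_tsv optional sidecar TSV path.
#' @return data.frame of peaks.
#' @export
read_narrowpeak <- function(path, sidecar_tsv = NULL) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  peaks <- data.frame(contig = df[[1]], start = as.integer(df[[2]]),
                      end = as.integer(df[[3]]),
                      summit = as.integer(df[[2]]) + as.integer(df[[10]]),
                      length = as.integer(df[[3]]) - as.integer(df[[2]]),
                      p_value = 10^(-df[[8]]), neglog10_p = df[[8]],
                      fold_enrichment = df[[7]], avg_coverage = NA_real_,
                      pearson_r = NA_real_)
  if (!is.null(sidecar_tsv)) {
    sc <- utils::read.table(sidecar_tsv, header = TRUE, sep = "\t")
    peaks$avg_coverage <- sc$avg_coverage
    peaks$pearson_r <- sc$pearson_r
  }
  peaks
}
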