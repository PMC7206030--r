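#' Per-base coverage track
#'
#' A `CoverageTrack` holds per-base coverage over named contigs in 0-based
#' half-open coordinates, together with the lane label and mapped-read
#' metadata. Element `i` of a contig's vector is the coverage of base
#' `[i-1, i)`.
#'
#' The `scale` field records the cumulative multiplicative factor applied by
#' [normalize_track()]; `values / scale` recovers the original count scale,
#' which the Poisson peak caller relies on.
#'
#' @param values named list of non-negative numeric vectors, one per contig.
#' @param label lane name, conventionally one of `"even"`, `"odd"`,
#'   `"input"`, `"consensus"`.
#' @param nominal_read_length read length (bp) used to convert coverage sums
#'   into mapped-read counts. Default 130 bp, the study's nominal read length.
#' @param total_mapped_reads mapped-read count; if `NULL`, computed as
#'   `sum(values) / nominal_read_length`.
#' @param scale cumulative depth-normalization factor already applied to
#'   `values` (1 for raw counts).
#' @return an object of class `CoverageTrack`.
#' @export
coverage_track <- function(values, label = "track", nominal_read_length = 130,
                           total_mapped_reads = NULL, scale = 1) {
  if (!is.list(values) || is.null(names(values)) || any(!nzchar(names(values))))
    stop("`values` must be a named list of per-contig numeric vectors")
  values <- lapply(values, as.numeric)
  if (any(vapply(values, function(v) any(v < 0 | !is.finite(v)), logical(1))))
    stop("coverage values must be finite and non-negative")
  if (is.null(total_mapped_reads))
    total_mapped_reads <- sum(vapply(values, sum, numeric(1))) / nominal_read_length
  if (total_mapped_reads < 0) stop("total_mapped_reads must be non-negative")
  structure(
    list(values = values, label = label,
         nominal_read_length = nominal_read_length,
         total_mapped_reads = total_mapped_reads, scale = scale),
    class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  lens <- vapply(x$values, length, integer(1))
  cat(sprintf("CoverageTrack <%s>: %d contig(s), %s bp, %.1f mapped reads (scale %.4g)\n",
              x$label, length(lens), format(sum(lens), big.mark = ","),
              x$total_mapped_reads, x$scale))
  invisible(x)
}

contig_lengths <- function(track) vapply(track$values, length, integer(1))

stopifnot_same_contigs <- function(a, b) {
  la <- contig_lengths(a); lb <- contig_lengths(b)
  if (!identical(names(la), names(lb)) || !identical(unname(la), unname(lb)))
    stop("tracks have mismatched contig sets or lengths")
}

#' Read a bedGraph file into a CoverageTrack
#'
#' Coordinates are 0-based half-open per the bedGraph standard. Bases not
#' covered by any record are filled with 0. Records beyond contig bounds
#' raise an error naming the offending line.
#'
#' @param path bedGraph file path.
#' @param contigs named integer vector of contig lengths.
#' @param label lane label for the resulting track.
#' @inheritParams coverage_track
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, contigs, label = "track",
                          nominal_read_length = 130) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  values <- lapply(contigs, function(L) numeric(L))
  if (any(keep)) {
    ln <- which(keep)
    df <- data.table::fread(text = lines[keep], header = FALSE, sep = "\t",
                            col.names = c("chrom", "start", "end", "value"),
                            colClasses = list(character = 1, numeric = 2:4))
    bad <- which(!(df$chrom %in% names(contigs)))
    if (length(bad))
      stop(sprintf("line %d: unknown contig '%s'", ln[bad[1]], df$chrom[bad[1]]))
    bad <- which(df$start < 0 | df$end > contigs[df$chrom] | df$start >= df$end)
    if (length(bad))
      stop(sprintf("line %d: interval [%d, %d) out of bounds for contig '%s'",
                   ln[bad[1]], df$start[bad[1]], df$end[bad[1]], df$chrom[bad[1]]))
    for (i in seq_len(nrow(df)))
      values[[df$chrom[i]]][(df$start[i] + 1):df$end[i]] <- df$value[i]
  }
  coverage_track(values, label = label, nominal_read_length = nominal_read_length)
}

fmt_num <- function(x) {
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))), sprintf("%.17g", x))
}

#' Write a CoverageTrack as bedGraph
#'
#' Runs of equal coverage are collapsed into single records; zero-coverage
#' runs are omitted. Integer values are written without a decimal point;
#' fractional values with full double precision so that
#' `read_bedgraph(write_bedgraph(x))` round-trips per-base values exactly.
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @param metadata_sidecar if `TRUE`, also write `<path>.meta.json` with the
#'   track's label, mapped-read total, nominal read length and scale.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, metadata_sidecar = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (contig in names(track$values)) {
    v <- track$values[[contig]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%s", contig, starts[keep], ends[keep],
                         fmt_num(r$values[keep])), con)
  }
  if (metadata_sidecar)
    jsonlite::write_json(
      list(label = track$label, total_mapped_reads = track$total_mapped_reads,
           nominal_read_length = track$nominal_read_length, scale = track$scale),
      paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a BED file of blacklist intervals
#'
#' @param path BED file (0-based half-open).
#' @param contigs named integer vector of contig lengths, used for bounds
#'   checks.
#' @return a data.frame with columns `contig`, `start`, `end`, sorted and
#'   merged.
#' @export
read_blacklist_bed <- function(path, contigs = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(keep))
    return(data.frame(contig = character(), start = integer(), end = integer()))
  ln <- which(keep)
  df <- data.table::fread(text = lines[keep], header = FALSE, sep = "\t")
  df <- data.frame(contig = as.character(df[[1]]), start = as.integer(df[[2]]),
                   end = as.integer(df[[3]]))
  if (!is.null(contigs)) {
    bad <- which(!(df$contig %in% names(contigs)) | df$start < 0 |
                   df$end > contigs[df$contig] | df$start >= df$end)
    if (length(bad))
      stop(sprintf("line %d: invalid blacklist interval", ln[bad[1]]))
  }
  merge_intervals(df)
}

#' Merge and sort half-open intervals per contig
#' @param intervals data.frame with columns contig, start, end.
#' @return merged, sorted data.frame.
#' @export
merge_intervals <- function(intervals) {
  if (!nrow(intervals))
    return(intervals[, c("contig", "start", "end")])
  out <- do.call(rbind, lapply(split(intervals, intervals$contig), function(d) {
    d <- d[order(d$start, d$end), ]
    ms <- d$start[1]; me <- d$end[1]; res <- list()
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= me) me <- max(me, d$end[i])
      else { res[[length(res) + 1]] <- c(ms, me); ms <- d$start[i]; me <- d$end[i] }
    }
    res[[length(res) + 1]] <- c(ms, me)
    m <- do.call(rbind, res)
    data.frame(contig = d$contig[1], start = m[, 1], end = m[, 2])
  }))
  rownames(out) <- NULL
  out
}

#' Zero coverage inside blacklist regions
#'
#' Sets coverage to 0 within every blacklist interval and reduces the
#' mapped-read total by the masked coverage sum (on the count scale) divided
#' by the nominal read length. An empty blacklist is the identity.
#'
#' @param track a [coverage_track()].
#' @param blacklist data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open), e.g. from [read_blacklist_bed()].
#' @return the masked track.
#' @export
mask_blacklist <- function(track, blacklist) {
  masked_sum <- 0
  for (i in seq_len(nrow(blacklist))) {
    contig <- blacklist$contig[i]
    if (!contig %in% names(track$values)) next
    idx <- (blacklist$start[i] + 1):blacklist$end[i]
    idx <- idx[idx >= 1 & idx <= length(track$values[[contig]])]
    masked_sum <- masked_sum + sum(track$values[[contig]][idx])
    track$values[[contig]][idx] <- 0
  }
  # values and the read total share the same (possibly normalized) scale
  track$total_mapped_reads <- max(
    0, track$total_mapped_reads - masked_sum / track$nominal_read_length)
  track
}

#' Even/odd consensus track (per-base minimum)
#'
#' The consensus ("true") coverage at every base is the smaller of the even-
#' and odd-lane coverages, so signal present in only one probe lane is
#' suppressed.
#'
#' @param even,odd [coverage_track()]s over identical contigs.
#' @return a consensus `CoverageTrack`; its mapped-read total is the
#'   consensus coverage sum divided by the nominal read length.
#' @export
consensus_track <- function(even, odd) {
  stopifnot_same_contigs(even, odd)
  if (even$scale != odd$scale)
    stop("even and odd lanes must be on the same scale")
  values <- mapply(pmin, even$values, odd$values, SIMPLIFY = FALSE)
  coverage_track(values, label = "consensus",
                 nominal_read_length = even$nominal_read_length,
                 total_mapped_reads = sum(vapply(values, sum, numeric(1))) /
                   even$nominal_read_length,
                 scale = even$scale)
}

#' Normalize a track to a fixed mapped-read total
#'
#' Every per-base value is multiplied by `target_reads / total_mapped_reads`
#' (default target 150 million mappable reads). Fractional coverage is
#' retained. The track's `scale` field accumulates the factor so downstream
#' code can recover the count scale.
#'
#' @param track a [coverage_track()].
#' @param target_reads target mapped-read total (default 1.5e8).
#' @return the rescaled track.
#' @export
normalize_track <- function(track, target_reads = 150e6) {
  if (track$total_mapped_reads <= 0)
    stop("cannot normalize a track with zero mapped reads")
  f <- target_reads / track$total_mapped_reads
  track$values <- lapply(track$values, function(v) v * f)
  track$total_mapped_reads <- target_reads
  track$scale <- track$scale * f
  track
}
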