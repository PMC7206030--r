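#' Extract fixed-width sequence windows around peak summits
#'
#' Takes the top-ranked peaks (optionally restricted to peaks annotated to
#' a given gene set) and extracts the sequence of
#' `[summit - half_width, summit + half_width)` from the genome, clipped at
#' contig edges. With the default half-width of 200 bp each window is a
#' 400 bp peak-centred sequence ready for external motif discovery.
#'
#' @param peaks data.frame of peaks ranked by fold enrichment (see
#'   [rank_peaks()]); if `restrict_to` is used the peaks must carry the
#'   `genes` column from [classify_peaks()].
#' @param genome named character vector of contig sequences (e.g.
#'   `fixture$sequence`) or a `Biostrings::DNAStringSet`.
#' @param top_n number of top peaks to keep after restriction.
#' @param half_width half-width of the window in bp (default 200).
#' @param restrict_to optional character vector of gene ids; only peaks
#'   annotated to at least one of these genes are considered.
#' @return data.frame with `peak_id`, `contig`, `start`, `end`, `clipped`,
#'   `seq`.
#' @export
extract_summit_windows <- function(peaks, genome, top_n = 204,
                                   half_width = 200, restrict_to = NULL) {
  if (inherits(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  if (!is.null(restrict_to)) {
    if (is.null(peaks$genes))
      stop("peaks must be annotated (classify_peaks) to restrict by gene set")
    hit <- vapply(strsplit(peaks$genes, ","), function(g)
      any(g %in% restrict_to), logical(1))
    peaks <- peaks[hit, , drop = FALSE]
  }
  peaks <- utils::head(peaks, top_n)
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    ct <- as.character(peaks$contig[i])
    L <- nchar(genome[[ct]])
    s <- peaks$summit[i]
    if (s < 0 || s >= L) stop("summit outside genome for contig ", ct)
    w0 <- max(0, s - half_width)
    w1 <- min(L, s + half_width)
    data.frame(peak_id = sprintf("peak_%s_%d_%d", ct, peaks$start[i],
                                 peaks$end[i]),
               contig = ct, start = w0, end = w1,
               clipped = (w1 - w0) < 2 * half_width,
               seq = substr(genome[[ct]], w0 + 1, w1))
  })
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(peak_id = character(), contig = character(), start = integer(),
               end = integer(), clipped = logical(), seq = character())
  rownames(out) <- NULL
  out
}

#' Write summit windows as FASTA
#' @param windows data.frame from [extract_summit_windows()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_windows_fasta <- function(windows, path) {
  dna <- Biostrings::DNAStringSet(stats::setNames(windows$seq,
                                                  windows$peak_id))
  Biostrings::writeXStringSet(dna, path, width = 80)
  invisible(path)
}

#' Read summit windows back from FASTA
#' @param path FASTA path.
#' @return data.frame with `peak_id` and `seq`.
#' @export
read_windows_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  data.frame(peak_id = names(dna), seq = as.character(dna),
             row.names = NULL)
}

#' Scan windows for a T-rich motif
#'
#' A window is positive when some substring of length `motif_len` has a
#' T fraction of at least `min_t_fraction` (N bases count as non-T). This
#' is a transparent internal check on motif content; de novo motif
#' discovery is delegated to external tools fed by the FASTA export.
#'
#' @param windows data.frame from [extract_summit_windows()] (or any
#'   data.frame with `peak_id` and `seq` of uppercase ACGTN).
#' @param motif_len motif length in bp (default 21).
#' @param min_t_fraction minimum T fraction in the best window (default
#'   0.8). Windows shorter than `motif_len` are negative, with a warning.
#' @return data.frame with `peak_id`, `max_t_fraction`, `positive`; the
#'   total positive count is in attribute `n_positive`.
#' @export
t_rich_scan <- function(windows, motif_len = 21, min_t_fraction = 0.8) {
  res <- lapply(seq_len(nrow(windows)), function(i) {
    s <- windows$seq[i]
    n <- nchar(s)
    if (n < motif_len) {
      warning("window ", windows$peak_id[i], " shorter than motif_len; negative")
      return(data.frame(peak_id = windows$peak_id[i],
                        max_t_fraction = NA_real_, positive = FALSE))
    }
    isT <- as.integer(strsplit(s, "", fixed = TRUE)[[1]] == "T")
    cs <- c(0L, cumsum(isT))
    counts <- cs[(motif_len + 1):(n + 1)] - cs[1:(n - motif_len + 1)]
    frac <- max(counts) / motif_len
    data.frame(peak_id = windows$peak_id[i], max_t_fraction = frac,
               positive = frac >= min_t_fraction)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(peak_id = character(), max_t_fraction = numeric(),
               positive = logical())
  rownames(out) <- NULL
  attr(out, "n_positive") <- sum(out$positive)
  out
}
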