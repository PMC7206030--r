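#' Construct a qPCR Cq table
#'
#' Wraps replicate Cq measurements with the designated reference-gene set
#' and a detection ceiling. Cq values at or above the ceiling are treated as
#' not detected (ND), never as an error.
#'
#' @param records data.frame with columns `target`, `sample`, `replicate`,
#'   `cq` (>= 0) and `efficiency` (per-primer amplification factor in
#'   (1, 2]).
#' @param reference_genes non-empty character vector of reference targets.
#' @param detection_ceiling Cq at or above which a measurement counts as not
#'   detected. Default 35.
#' @return a `QPCRTable` object.
#' @export
qpcr_table <- function(records, reference_genes, detection_ceiling = 35) {
  need <- c("target", "sample", "replicate", "cq", "efficiency")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (!length(reference_genes)) stop("reference gene set must be non-empty")
  if (any(records$cq < 0, na.rm = TRUE)) stop("Cq values must be >= 0")
  if (any(records$efficiency <= 1 | records$efficiency > 2))
    stop("primer efficiencies must lie in (1, 2]")
  if (!all(reference_genes %in% records$target))
    stop("reference genes missing from the table: ",
         paste(setdiff(reference_genes, records$target), collapse = ", "))
  structure(list(records = records, reference_genes = reference_genes,
                 detection_ceiling = detection_ceiling),
            class = "QPCRTable")
}

#' @export
print.QPCRTable <- function(x, ...) {
  cat(sprintf("QPCRTable: %d measurements, %d targets, references: %s\n",
              nrow(x$records), length(unique(x$records$target)),
              paste(x$reference_genes, collapse = ", ")))
  invisible(x)
}

#' Read a qPCR Cq table from TSV
#' @param path TSV with columns target, sample, replicate, cq, efficiency.
#' @inheritParams qpcr_table
#' @return a [qpcr_table()].
#' @export
read_qpcr_tsv <- function(path, reference_genes, detection_ceiling = 35) {
  qpcr_table(utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE),
             reference_genes = reference_genes,
             detection_ceiling = detection_ceiling)
}

# mean Cq over technical replicates for one (target, sample);
# NA when absent or at/above the detection ceiling
mean_cq <- function(table, target, sample) {
  r <- table$records
  cq <- r$cq[r$target == target & r$sample == sample]
  cq <- cq[!is.na(cq)]
  if (!length(cq)) return(NA_real_)
  m <- mean(cq)
  if (m >= table$detection_ceiling) NA_real_ else m
}

efficiency_of <- function(table, target) {
  e <- unique(table$records$efficiency[table$records$target == target])
  if (!length(e)) stop("no efficiency recorded for target ", target)
  e[1]
}

#' Efficiency-corrected relative expression (Pfaffl quantification)
#'
#' Technical replicates are averaged to a mean Cq per (target, sample). The
#' expression ratio of the comparison sample relative to the baseline is
#'
#'   E_target^(Cq_base - Cq_comp) / geomean_ref( E_ref^(Cq_base - Cq_comp) )
#'
#' where the denominator is the geometric mean over the table's reference
#' genes. With all efficiencies equal to 2 this reduces to the classical
#' 2^(-ddCt) value.
#'
#' @param table a [qpcr_table()].
#' @param target target id.
#' @param sample_pair length-2 character: (baseline, comparison) sample ids.
#' @return list with `ratio`, `log2fc` and `detected`. When the target is
#'   not detected in either sample, `detected` is `FALSE` and the values are
#'   `NA` (not an error). Missing reference measurements are an error.
#' @export
relative_expression <- function(table, target, sample_pair) {
  stopifnot(length(sample_pair) == 2)
  base <- sample_pair[1]; comp <- sample_pair[2]
  ref_ratios <- vapply(table$reference_genes, function(ref) {
    cb <- mean_cq(table, ref, base); cc <- mean_cq(table, ref, comp)
    if (is.na(cb) || is.na(cc))
      stop("reference gene ", ref, " missing or not detected")
    efficiency_of(table, ref)^(cb - cc)
  }, numeric(1))
  normalizer <- exp(mean(log(ref_ratios)))
  cb <- mean_cq(table, target, base); cc <- mean_cq(table, target, comp)
  if (is.na(cb) || is.na(cc))
    return(list(ratio = NA_real_, log2fc = NA_real_, detected = FALSE))
  ratio <- efficiency_of(table, target)^(cb - cc) / normalizer
  list(ratio = ratio, log2fc = log2(ratio), detected = TRUE)
}

#' Per-target enrichment results for one model
#'
#' Applies [relative_expression()] to every target over one or more
#' biological sample pairings; with several pairings, per-pair log2 ratios
#' are averaged (ratios first, then the mean of log2 ratios).
#'
#' @param table a [qpcr_table()].
#' @param targets target ids to screen (defaults to all non-reference
#'   targets in the table).
#' @param pairs data.frame with columns `baseline` and `comparison`, one row
#'   per biological pairing.
#' @return data.frame with columns `target`, `log2fc`, `detected`.
#' @export
enrichment_screen <- function(table, targets = NULL, pairs) {
  if (is.null(targets))
    targets <- setdiff(unique(table$records$target), table$reference_genes)
  res <- lapply(targets, function(tg) {
    l2 <- vapply(seq_len(nrow(pairs)), function(i)
      relative_expression(table, tg,
                          c(pairs$baseline[i], pairs$comparison[i]))$log2fc,
      numeric(1))
    det <- all(!is.na(l2))
    data.frame(target = tg, log2fc = if (det) mean(l2) else NA_real_,
               detected = det)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Dual-model candidate filter
#'
#' Returns targets detected in both models whose log2 fold change meets the
#' threshold in both (default inclusive `>= 1`, i.e. at least 2-fold
#' enrichment in each model). Undetected targets are excluded, with the
#' reason recorded in the `excluded` attribute.
#'
#' @param results_model1,results_model2 data.frames from
#'   [enrichment_screen()], indexed by `target`.
#' @param threshold_log2 log2 fold-change threshold (default 1).
#' @param strict if `TRUE`, require strictly greater than the threshold; the
#'   default is inclusive (`>=`).
#' @return character vector of candidate target ids, with an `excluded`
#'   attribute (data.frame of target and reason).
#' @export
dual_model_filter <- function(results_model1, results_model2,
                              threshold_log2 = 1, strict = FALSE) {
  common <- intersect(results_model1$target, results_model2$target)
  i1 <- match(common, results_model1$target)
  i2 <- match(common, results_model2$target)
  det <- results_model1$detected[i1] & results_model2$detected[i2]
  cmp <- if (strict) `>` else `>=`
  pass <- det &
    cmp(results_model1$log2fc[i1], threshold_log2) &
    cmp(results_model2$log2fc[i2], threshold_log2)
  pass[is.na(pass)] <- FALSE
  excluded <- data.frame(
    target = common[!pass],
    reason = ifelse(!det[!pass], "not detected in both models",
                    "below threshold in at least one model"))
  structure(common[pass], excluded = excluded)
}
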