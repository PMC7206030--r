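#' Default study-scale workflow parameters
#'
#' The defaults define the synthetic study conditions the pipeline is
#' exercised under: a 1 Mb contig with 120 genes, Poisson background
#' coverage of 2 reads/base, 20 true binding sites (fold 8, present in both
#' probe lanes) of which half carry a planted T-rich 21-mer and half sit
#' inside regulated genes, 20 single-lane artifact sites (fold 8), two
#' knockdown expression experiments with 25 up + 25 down planted 2-fold
#' genes sharing 20 planted genes, and a 50-target dual-model qPCR screen
#' with 36 detectable targets of which exactly 10 are enriched at least
#' 2-fold in both models.
#'
#' @return named list of parameters; override entries via
#'   [run_chirp_workflow()]'s `params` argument.
#' @export
chirp_workflow_params <- function() {
  list(
    contig_length = 1e6, n_genes = 120, n_extra_genes = 1880,
    n_blacklist = 4, blacklist_length = 500,
    background_rate = 2, n_true = 20, n_artifact = 20, site_width = 300,
    site_fold = 8, prefer_fraction = 0.5,
    motif_len = 21, motif_t_fraction = 0.9, min_t_fraction = 0.8,
    n_up = 25, n_down = 25, de_fold = 2, de_reps = 3, de_noise_sd = 0.25,
    de_fold_min = 1.70, de_alpha = 0.05,
    target_reads = 150e6, p_cutoff = 1e-5, min_gap = 130, min_length = 100,
    fe_min = 2, cov_min = 1.5, r_min = 0.3, summit_window = 10,
    promoter_halfwidth = 2000,
    top_n = 204, half_width = 200,
    qpcr_n_targets = 50, qpcr_n_detected = 36, qpcr_n_planted = 10,
    qpcr_planted_fold = 4, qpcr_noise_sd = 0.2, qpcr_reps = 3,
    qpcr_threshold_log2 = 1)
}

workflow_subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 100 + k) %% .Machine$integer.max)
}

#' Build the dual-model qPCR screen fixture
#'
#' Fifty lncRNA targets plus two reference genes per model. Targets
#' `t01..t10` carry the planted fold in both models, `t11..t15` in model 1
#' only, `t16..t20` in model 2 only, `t21..t36` are unchanged, and
#' `t37..t50` are below the detection ceiling, so 36 targets are detected
#' and exactly 10 are enriched >= 2-fold in both models.
#'
#' @param params workflow parameter list (see [chirp_workflow_params()]).
#' @param seed integer seed.
#' @return list with `table1`, `table2` ([qpcr_table()]s), `planted`
#'   (character vector of the 10 dual-enriched targets) and `undetected`.
#' @export
qpcr_screen_fixture <- function(params = chirp_workflow_params(), seed) {
  n <- params$qpcr_n_targets
  targets <- sprintf("t%02d", seq_len(n))
  refs <- c("PUM1", "ARF1")
  all_t <- c(targets, refs)
  planted <- targets[1:params$qpcr_n_planted]
  only1 <- targets[11:15]; only2 <- targets[16:20]
  undetected <- targets[(params$qpcr_n_detected + 1):n]
  eff <- stats::setNames(rep(1.9, length(all_t)), all_t)
  eff[refs] <- 2.0
  f1 <- f2 <- stats::setNames(rep(1, length(all_t)), all_t)
  f1[c(planted, only1)] <- params$qpcr_planted_fold
  f2[c(planted, only2)] <- params$qpcr_planted_fold
  table1 <- simulate_qpcr(all_t, f1, eff, refs,
                          noise_sd = params$qpcr_noise_sd,
                          n_reps = params$qpcr_reps,
                          seed = workflow_subseed(seed, 11),
                          undetected = undetected,
                          samples = c("alde_low", "alde_high"))
  table2 <- simulate_qpcr(all_t, f2, eff, refs,
                          noise_sd = params$qpcr_noise_sd,
                          n_reps = params$qpcr_reps,
                          seed = workflow_subseed(seed, 12),
                          undetected = undetected,
                          samples = c("alde_low", "alde_high"))
  list(table1 = table1, table2 = table2, planted = planted,
       undetected = undetected)
}

#' Run the full synthetic study workflow
#'
#' Executes every pipeline stage end-to-end on seeded synthetic data with
#' known ground truth: the dual-model qPCR enrichment screen; genome,
#' truth and lane simulation; blacklist masking, even/odd consensus and
#' depth normalization; local-Poisson peak calling, multi-criteria
#' filtering and fold-enrichment ranking; genic annotation and occupancy
#' summary; regulated-gene derivation, regulated-set overlap and
#' occupancy-vs-regulation enrichment; summit-window extraction and the
#' T-rich scan.
#'
#' @param seed integer master seed; all stage seeds derive from it.
#' @param outdir optional directory; when given, narrowPeak, annotation,
#'   enrichment-report, regulated-gene, qPCR and FASTA outputs are written
#'   there with byte-stable formatting.
#' @param params parameter list from [chirp_workflow_params()]; entries may
#'   be overridden.
#' @return list with all intermediate and final results (see the methods
#'   vignette for a walk-through).
#' @export
run_chirp_workflow <- function(seed, outdir = NULL,
                               params = chirp_workflow_params()) {
  ss <- function(k) workflow_subseed(seed, k)

  # -- stage 1: dual-model qPCR enrichment screen -------------------------
  qf <- qpcr_screen_fixture(params, seed)
  pairs <- data.frame(baseline = "alde_low", comparison = "alde_high")
  screen1 <- enrichment_screen(qf$table1, pairs = pairs)
  screen2 <- enrichment_screen(qf$table2, pairs = pairs)
  candidates <- dual_model_filter(screen1, screen2,
                                  threshold_log2 = params$qpcr_threshold_log2)

  # -- stage 2: genome fixture and knockdown expression -------------------
  fixture <- simulate_genome(1, params$contig_length, params$n_genes,
                             seed = ss(1), n_blacklist = params$n_blacklist,
                             blacklist_length = params$blacklist_length)
  # the expression universe is larger than the simulated region: genes on
  # the fixture contig plus off-fixture genes (the rest of the "genome"),
  # as in array data where the tested universe dwarfs any one locus
  genome_ids <- fixture$genes$gene_id
  extra_ids <- sprintf("xgene%04d", seq_len(params$n_extra_genes))
  gids <- c(genome_ids, extra_ids)
  # planted regulated genes: half on the fixture contig (these can host
  # planted binding sites), half off-fixture
  plantedA <- c(genome_ids[1:13], extra_ids[1:12],       # up
                genome_ids[14:25], extra_ids[13:25])     # down
  simA <- simulate_expression(gids, params$n_up, params$n_down,
                              fold = params$de_fold, n_reps = params$de_reps,
                              noise_sd = params$de_noise_sd, seed = ss(2),
                              planted = plantedA)
  # second knockdown shares 10 up + 10 down planted genes with the first
  upA <- plantedA[seq_len(params$n_up)]
  downA <- plantedA[params$n_up + seq_len(params$n_down)]
  fresh <- extra_ids[26:55]
  plantedB <- c(upA[c(1:5, 14:18)], fresh[1:15],
                downA[c(1:5, 13:17)], fresh[16:30])
  simB <- simulate_expression(gids, 25, 25, fold = params$de_fold,
                              n_reps = params$de_reps,
                              noise_sd = params$de_noise_sd, seed = ss(3),
                              planted = plantedB)
  regA <- differential_filter(simA$matrix, simA$groups,
                              fold_min = params$de_fold_min,
                              alpha = params$de_alpha)
  regB <- differential_filter(simB$matrix, simB$groups,
                              fold_min = params$de_fold_min,
                              alpha = params$de_alpha)

  # -- stage 3: ChIRP truth, lanes, consensus -----------------------------
  reg_spans <- fixture$genes[fixture$genes$gene_id %in% plantedA,
                             c("contig", "start", "end")]
  truth <- simulate_chirp_truth(
    fixture, n_true = params$n_true, n_artifact = params$n_artifact,
    site_width = params$site_width, fold = params$site_fold,
    background_rate = params$background_rate, seed = ss(4),
    prefer = reg_spans, prefer_fraction = params$prefer_fraction,
    avoid = fixture$blacklist)
  motif_sites <- truth$true_sites[seq(1, nrow(truth$true_sites), by = 2), ]
  fixture <- plant_t_rich_motifs(fixture, motif_sites,
                                 motif_len = params$motif_len,
                                 t_fraction = params$motif_t_fraction,
                                 seed = ss(5))
  lanes <- simulate_chirp_lanes(fixture, truth, seed = ss(6))
  even <- mask_blacklist(lanes$even, fixture$blacklist)
  odd <- mask_blacklist(lanes$odd, fixture$blacklist)
  input <- mask_blacklist(lanes$input, fixture$blacklist)
  consensus <- consensus_track(even, odd)
  consensus_n <- normalize_track(consensus, params$target_reads)
  input_n <- normalize_track(input, params$target_reads)

  # -- stage 4: peak calling, filtering, ranking --------------------------
  peaks <- call_peaks(consensus_n, input_n, p_cutoff = params$p_cutoff,
                      min_gap = params$min_gap,
                      min_length = params$min_length,
                      even = even, odd = odd)
  filtered <- filter_peaks(peaks, fe_min = params$fe_min,
                           cov_min = params$cov_min, r_min = params$r_min,
                           min_length = params$min_length,
                           summit_window = params$summit_window)
  ranked <- rank_peaks(filtered, top_n = max(1, nrow(filtered)))

  # -- stage 5: annotation and occupancy ----------------------------------
  classified <- classify_peaks(ranked, fixture,
                               promoter_halfwidth = params$promoter_halfwidth,
                               contigs = fixture$contigs)
  occupancy <- occupancy_summary(classified, fixture)

  # -- stage 6: regulated-set overlap and occupancy enrichment ------------
  regulatedA <- union(regA$up, regA$down)
  regulatedB <- union(regB$up, regB$down)
  overlap <- overlap_enrichment(regulatedA, regulatedB,
                                universe_n = length(gids))
  occupied <- names(occupancy$per_gene)[occupancy$per_gene > 0]
  occ_enrich <- occupancy_enrichment(occupied, regulatedA,
                                     universe_n = length(gids))

  # -- stage 7: summit windows and T-rich scan ----------------------------
  windows <- extract_summit_windows(classified, fixture$sequence,
                                    top_n = params$top_n,
                                    half_width = params$half_width,
                                    restrict_to = regulatedA)
  scan <- t_rich_scan(windows, motif_len = params$motif_len,
                      min_t_fraction = params$min_t_fraction)

  # -- recovery against planted truth -------------------------------------
  recovery <- site_recovery(truth, filtered)

  res <- list(params = params, seed = seed,
              qpcr = list(fixture = qf, screen1 = screen1, screen2 = screen2,
                          candidates = candidates),
              fixture = fixture, truth = truth,
              expression = list(simA = simA, simB = simB,
                                regA = regA, regB = regB),
              tracks = list(even = even, odd = odd, input = input,
                            consensus = consensus_n, input_n = input_n),
              peaks = peaks, filtered = filtered, ranked = ranked,
              classified = classified, occupancy = occupancy,
              overlap = overlap, occ_enrich = occ_enrich,
              windows = windows, scan = scan, recovery = recovery)
  if (!is.null(outdir)) write_workflow_outputs(res, outdir)
  res
}

#' Fraction of planted sites recovered by filtered peaks
#'
#' A true or artifact site counts as recovered/surviving when any filtered
#' peak overlaps it.
#'
#' @param truth a [chirp_truth()].
#' @param filtered data.frame of filtered peaks.
#' @return list with `true_recall`, `n_true_recovered`,
#'   `n_artifact_surviving`.
#' @export
site_recovery <- function(truth, filtered) {
  overlaps_peak <- function(site)
    any(filtered$contig == site$contig & filtered$start < site$end &
          site$start < filtered$end)
  n_true <- nrow(truth$true_sites)
  rec <- vapply(seq_len(n_true), function(i)
    overlaps_peak(truth$true_sites[i, ]), logical(1))
  art <- vapply(seq_len(nrow(truth$artifact_sites)), function(i)
    overlaps_peak(truth$artifact_sites[i, ]), logical(1))
  list(true_recall = if (n_true) mean(rec) else NA_real_,
       n_true_recovered = sum(rec), n_artifact_surviving = sum(art))
}

#' Write all workflow outputs with byte-stable formatting
#' @param res a [run_chirp_workflow()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_workflow_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)

  s1 <- res$qpcr$screen1; s2 <- res$qpcr$screen2
  df <- data.frame(target = s1$target,
                   log2fc_model1 = ifelse(s1$detected,
                                          sprintf("%.5f", s1$log2fc), "ND"),
                   log2fc_model2 = ifelse(s2$detected,
                                          sprintf("%.5f", s2$log2fc), "ND"),
                   candidate = s1$target %in% res$qpcr$candidates)
  utils::write.table(df, p("qpcr_screen.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  write_narrowpeak(res$ranked, p("peaks.narrowPeak"),
                   sidecar_tsv = p("peaks_stats.tsv"))
  write_annotation_tsv(res$classified, res$occupancy,
                       p("peak_annotation.tsv"), p("annotation_summary.tsv"))
  write_regulated_tsv(res$expression$regA, p("regulated_model1.tsv"))
  write_regulated_tsv(res$expression$regB, p("regulated_model2.tsv"))

  ov <- res$overlap; oe <- res$occ_enrich
  report <- c("metric\tvalue",
              sprintf("regulated_model1_n\t%d",
                      length(union(res$expression$regA$up,
                                   res$expression$regA$down))),
              sprintf("regulated_model2_n\t%d",
                      length(union(res$expression$regB$up,
                                   res$expression$regB$down))),
              sprintf("overlap_observed\t%d", ov$observed),
              sprintf("overlap_expected\t%.5f", ov$expected),
              sprintf("overlap_fraction_A\t%.5f", ov$fraction_A),
              sprintf("overlap_fraction_B\t%.5f", ov$fraction_B),
              sprintf("overlap_p\t%.5g", ov$p_value),
              sprintf("occupied_and_regulated\t%d", oe$table[1, 1]),
              sprintf("regulated_total\t%d", sum(oe$table[1, ])),
              sprintf("fraction_occupied_regulated\t%.5f",
                      oe$fraction_occupied_regulated),
              sprintf("fraction_occupied_other\t%.5f",
                      oe$fraction_occupied_other),
              sprintf("occupancy_odds_ratio\t%.5f", oe$odds_ratio),
              sprintf("occupancy_p\t%.5g", oe$p_value))
  writeLines(report, p("enrichment_report.tsv"))

  write_windows_fasta(res$windows, p("summit_windows.fasta"))
  scan_df <- data.frame(peak_id = res$scan$peak_id,
                        max_t_fraction = sprintf("%.5f",
                                                 res$scan$max_t_fraction),
                        positive = res$scan$positive)
  utils::write.table(scan_df, p("t_rich_scan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
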