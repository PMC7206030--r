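#' Run code with a private, seeded RNG stream
#'
#' Saves and restores the caller's RNG state so that generators are
#' bit-reproducible for a fixed seed without clobbering the global stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("`seed` must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# non-overlapping placement of n intervals of given widths on [0, L),
# uniform over admissible configurations via the gap ("stars and bars") trick
place_nonoverlapping <- function(L, widths) {
  n <- length(widths)
  if (n == 0) return(integer(0))
  free <- L - sum(widths)
  if (free < 0) stop("impossible packing: intervals cannot fit without overlap")
  gaps <- diff(c(0, sort(stats::runif(n, 0, free)), free))[seq_len(n)]
  starts <- cumsum(gaps) + cumsum(c(0, widths[-n]))
  as.integer(floor(starts))
}

#' Simulate a small genome fixture with gene models and a blacklist
#'
#' Generates random ACGT contig sequences, non-overlapping gene models with
#' 1-10 exons each, and optional blacklist intervals. Stands in for a real
#' reference assembly so that every pipeline stage can run on inputs with
#' known ground truth.
#'
#' @param n_contigs number of contigs (named `chr1`, `chr2`, ...).
#' @param contig_length length of each contig in bp; must be at least 10
#'   times the mean gene length.
#' @param n_genes total number of genes across contigs.
#' @param seed integer seed (required; all generators are deterministic
#'   given it).
#' @param gene_length_range min/max gene span in bp.
#' @param n_blacklist number of blacklist intervals to place.
#' @param blacklist_length blacklist interval width in bp.
#' @return a `GenomeFixture`: list with `contigs` (named lengths),
#'   `sequence` (named character), `genes` and `exons` data.frames (0-based
#'   half-open), and `blacklist` data.frame.
#' @export
simulate_genome <- function(n_contigs = 1, contig_length = 1e6, n_genes = 100,
                            seed, gene_length_range = c(1000, 5000),
                            n_blacklist = 0, blacklist_length = 500) {
  stopifnot(n_contigs >= 1, n_genes >= 0, contig_length >= 1)
  if (contig_length < 10 * mean(gene_length_range))
    stop("contig_length must be at least 10 x the mean gene length")
  with_seed(seed, {
    contigs <- stats::setNames(rep(as.integer(contig_length), n_contigs),
                               paste0("chr", seq_len(n_contigs)))
    sequence <- vapply(contigs, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    genes <- exons <- NULL
    if (n_genes > 0) {
      # draw gene widths first, then pack genes onto contigs greedily by
      # remaining free space so feasible configurations always succeed
      all_widths <- as.integer(round(stats::runif(n_genes,
                                                  gene_length_range[1],
                                                  gene_length_range[2])))
      free <- contigs
      contig_of <- character(n_genes)
      for (i in order(all_widths, decreasing = TRUE)) {
        ok <- names(free)[free >= all_widths[i]]
        if (!length(ok))
          stop("impossible packing: genes cannot fit without overlap")
        pick <- if (length(ok) == 1) ok else
          sample(ok, 1, prob = free[ok] / sum(free[ok]))
        contig_of[i] <- pick
        free[pick] <- free[pick] - all_widths[i]
      }
      glist <- list(); elist <- list(); gi <- 0
      for (contig in names(contigs)) {
        k <- sum(contig_of == contig)
        if (k == 0) next
        widths <- all_widths[contig_of == contig]
        starts <- sort(place_nonoverlapping(contigs[[contig]], widths))
        for (j in seq_len(k)) {
          gi <- gi + 1
          id <- sprintf("gene%03d", gi)
          s <- starts[j]; e <- s + widths[j]
          strand <- sample(c("+", "-"), 1)
          len <- e - s
          nex <- sample(seq_len(min(10, (len + 1) %/% 2)), 1)
          if (nex == 1) ex <- cbind(s, e)
          else {
            # 2*nex-1 alternating exon/intron segments, all non-empty
            cuts <- sort(sample(seq_len(len - 1), 2 * nex - 2))
            bounds <- c(0, cuts, len)
            seg_s <- bounds[-length(bounds)]; seg_e <- bounds[-1]
            odd <- seq(1, 2 * nex - 1, by = 2)
            ex <- cbind(s + seg_s[odd], s + seg_e[odd])
          }
          glist[[gi]] <- data.frame(gene_id = id, contig = contig,
                                    strand = strand, start = s, end = e)
          elist[[gi]] <- data.frame(gene_id = id, contig = contig,
                                    start = ex[, 1], end = ex[, 2])
        }
      }
      genes <- do.call(rbind, glist); exons <- do.call(rbind, elist)
      rownames(genes) <- rownames(exons) <- NULL
    } else {
      genes <- data.frame(gene_id = character(), contig = character(),
                          strand = character(), start = integer(),
                          end = integer())
      exons <- data.frame(gene_id = character(), contig = character(),
                          start = integer(), end = integer())
    }
    blacklist <- if (n_blacklist > 0) {
      bl_contig <- sample(names(contigs), n_blacklist, replace = TRUE)
      bl_start <- vapply(bl_contig, function(ct)
        sample.int(contigs[[ct]] - blacklist_length, 1) - 1L, integer(1))
      merge_intervals(data.frame(contig = bl_contig, start = bl_start,
                                 end = bl_start + as.integer(blacklist_length)))
    } else data.frame(contig = character(), start = integer(), end = integer())
    structure(list(contigs = contigs, sequence = sequence, genes = genes,
                   exons = exons, blacklist = blacklist),
              class = "GenomeFixture")
  })
}

#' @export
print.GenomeFixture <- function(x, ...) {
  cat(sprintf("GenomeFixture: %d contig(s) (%s bp), %d genes, %d blacklist intervals\n",
              length(x$contigs), format(sum(x$contigs), big.mark = ","),
              nrow(x$genes), nrow(x$blacklist)))
  invisible(x)
}

#' Write a GenomeFixture's sequence as FASTA
#' @param fixture a [simulate_genome()] fixture.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(fixture, path) {
  dna <- Biostrings::DNAStringSet(fixture$sequence)
  Biostrings::writeXStringSet(dna, path, width = 80)
  invisible(path)
}

#' Write a GenomeFixture's gene models as GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 is written 1-based
#' inclusive per the format specification.
#' @inheritParams write_genome_fasta
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(fixture, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ct in names(fixture$contigs))
    writeLines(sprintf("##sequence-region %s 1 %d", ct, fixture$contigs[[ct]]), con)
  g <- fixture$genes
  for (i in seq_len(nrow(g))) {
    writeLines(sprintf("%s\tchirpscreen\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$contig[i], g$start[i] + 1L, g$end[i], g$strand[i],
                       g$gene_id[i]), con)
    ex <- fixture$exons[fixture$exons$gene_id == g$gene_id[i], ]
    for (j in seq_len(nrow(ex)))
      writeLines(sprintf("%s\tchirpscreen\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         ex$contig[j], ex$start[j] + 1L, ex$end[j], g$strand[i],
                         g$gene_id[i], j, g$gene_id[i]), con)
  }
  invisible(path)
}

#' Write blacklist intervals as BED (0-based half-open)
#' @inheritParams write_genome_fasta
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_blacklist_bed <- function(fixture, path) {
  bl <- fixture$blacklist
  writeLines(sprintf("%s\t%d\t%d", bl$contig, bl$start, bl$end), path)
  invisible(path)
}

#' Plant T-rich motif insertions in a genome fixture
#'
#' Overwrites the center of each given site with a T-rich k-mer (each base T
#' with probability `t_fraction`, otherwise uniform A/C/G) so that the motif
#' scan has known positives to find.
#'
#' @inheritParams write_genome_fasta
#' @param sites data.frame with columns `contig`, `start`, `end`.
#' @param motif_len inserted motif length (bp).
#' @param t_fraction per-base probability of T within the insertion.
#' @param seed integer seed.
#' @return the modified fixture.
#' @export
plant_t_rich_motifs <- function(fixture, sites, motif_len = 21,
                                t_fraction = 0.9, seed) {
  with_seed(seed, {
    for (i in seq_len(nrow(sites))) {
      mid <- (sites$start[i] + sites$end[i]) %/% 2
      s <- mid - motif_len %/% 2
      motif <- ifelse(stats::runif(motif_len) < t_fraction, "T",
                      sample(c("A", "C", "G"), motif_len, replace = TRUE))
      substr(fixture$sequence[[sites$contig[i]]], s + 1, s + motif_len) <-
        paste(motif, collapse = "")
    }
    fixture
  })
}

#' Ground truth for simulated ChIRP lanes
#'
#' @param true_sites data.frame (`contig`, `start`, `end`, `fold`): sites
#'   with planted signal in both the even and odd lanes.
#' @param artifact_sites data.frame (`contig`, `start`, `end`, `fold`,
#'   `lane`): sites with signal in exactly one lane (`lane` is `"even"` or
#'   `"odd"`), emulating probe-specific artifacts.
#' @param background_rate mean background coverage per base (> 0).
#' @return a `ChirpTruth` object.
#' @export
chirp_truth <- function(true_sites, artifact_sites, background_rate) {
  if (background_rate <= 0) stop("background_rate must be > 0")
  if (any(c(true_sites$fold, artifact_sites$fold) <= 1))
    stop("planted folds must be > 1")
  if (nrow(artifact_sites) && !all(artifact_sites$lane %in% c("even", "odd")))
    stop("artifact lane must be 'even' or 'odd'")
  both <- rbind(true_sites[, c("contig", "start", "end")],
                artifact_sites[, c("contig", "start", "end")])
  if (nrow(both) > 1) {
    for (ct in unique(both$contig)) {
      d <- both[both$contig == ct, ]
      d <- d[order(d$start), ]
      if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
        stop("planted sites must be disjoint")
    }
  }
  structure(list(true_sites = true_sites, artifact_sites = artifact_sites,
                 background_rate = background_rate),
            class = "ChirpTruth")
}

#' Place random true and artifact binding sites on a fixture
#'
#' Sites are non-overlapping. Optionally a fraction of the true sites is
#' placed inside supplied preferred intervals (e.g. the spans of planted
#' regulated genes) to couple chromatin occupancy with regulation, as in
#' real data where an RNA binds the genes it regulates. Artifact sites
#' alternate between the even and odd lanes.
#'
#' @inheritParams write_genome_fasta
#' @param n_true,n_artifact site counts.
#' @param site_width site width in bp.
#' @param fold planted coverage fold over background.
#' @param background_rate mean background coverage per base.
#' @param seed integer seed.
#' @param prefer data.frame of intervals (`contig`, `start`, `end`) to host
#'   a fraction of true sites, or `NULL`.
#' @param prefer_fraction fraction of true sites placed inside `prefer`.
#' @param avoid data.frame of intervals sites must not overlap (e.g. the
#'   blacklist), or `NULL`.
#' @return a [chirp_truth()].
#' @export
simulate_chirp_truth <- function(fixture, n_true = 20, n_artifact = 20,
                                 site_width = 300, fold = 8,
                                 background_rate = 2, seed,
                                 prefer = NULL, prefer_fraction = 0,
                                 avoid = NULL) {
  with_seed(seed, {
    taken <- data.frame(contig = character(), start = integer(), end = integer())
    if (!is.null(avoid) && nrow(avoid))
      taken <- avoid[, c("contig", "start", "end")]
    overlaps_taken <- function(ct, s, e) {
      d <- taken[taken$contig == ct, ]
      nrow(d) > 0 && any(s < d$end & e > d$start)
    }
    draw_site <- function(host = NULL) {
      for (try in 1:2000) {
        if (is.null(host)) {
          ct <- sample(names(fixture$contigs), 1,
                       prob = fixture$contigs / sum(fixture$contigs))
          s <- sample.int(fixture$contigs[[ct]] - site_width, 1) - 1L
        } else {
          k <- sample.int(nrow(host), 1)
          ct <- host$contig[k]
          lo <- host$start[k]; hi <- host$end[k] - site_width
          if (hi <= lo) next
          s <- lo + sample.int(hi - lo, 1) - 1L
        }
        e <- s + as.integer(site_width)
        if (!overlaps_taken(ct, s, e)) {
          taken <<- rbind(taken, data.frame(contig = ct, start = s, end = e))
          return(data.frame(contig = ct, start = s, end = e))
        }
      }
      stop("could not place disjoint sites; reduce counts or widths")
    }
    n_pref <- if (is.null(prefer) || !nrow(prefer)) 0L
              else as.integer(round(prefer_fraction * n_true))
    true_sites <- do.call(rbind, lapply(seq_len(n_true), function(i)
      draw_site(host = if (i <= n_pref) prefer else NULL)))
    artifact_sites <- do.call(rbind, lapply(seq_len(n_artifact), function(i)
      draw_site()))
    if (!is.null(true_sites)) true_sites$fold <- fold
    else true_sites <- data.frame(contig = character(), start = integer(),
                                  end = integer(), fold = numeric())
    if (!is.null(artifact_sites)) {
      artifact_sites$fold <- fold
      artifact_sites$lane <- rep(c("even", "odd"),
                                 length.out = nrow(artifact_sites))
    } else artifact_sites <- data.frame(contig = character(), start = integer(),
                                        end = integer(), fold = numeric(),
                                        lane = character())
    chirp_truth(true_sites, artifact_sites, background_rate)
  })
}

#' Simulate even, odd and input ChIRP-seq coverage lanes
#'
#' Per-base coverage is independent Poisson: `background_rate` everywhere in
#' the input lane; inside true sites both pulldown lanes share a summit-
#' shaped (triangular) rate profile whose mean over the site is
#' `background_rate * fold` (edges at background, apex at
#' `(2 * fold - 1) * background_rate`), and artifact sites get the same
#' profile in exactly one lane. The shared profile is what gives genuine
#' sites their even/odd per-base concordance — two lanes sampling the same
#' underlying fragment pile-up — while a flat rate would leave the two
#' lanes uncorrelated even at a true site. Mapped-read metadata is the
#' coverage sum divided by the nominal read length.
#'
#' @inheritParams write_genome_fasta
#' @param truth a [chirp_truth()].
#' @param seed integer seed.
#' @param nominal_read_length read length used for read-count metadata.
#' @return list with elements `even`, `odd`, `input`, each a
#'   [coverage_track()].
#' @export
simulate_chirp_lanes <- function(fixture, truth, seed,
                                 nominal_read_length = 130) {
  if (truth$background_rate <= 0) stop("background_rate must be > 0")
  with_seed(seed, {
    # triangular profile with mean `fold`: 1 at the edges, 2*fold - 1 at
    # the apex, times the background rate
    site_profile <- function(width, fold) {
      x <- seq_len(width) - 1
      c0 <- (width - 1) / 2
      m <- 1 + (2 * fold - 2) * (1 - abs(x - c0) / c0)
      truth$background_rate * m
    }
    rate_for <- function(lane) {
      lapply(stats::setNames(names(fixture$contigs), names(fixture$contigs)),
             function(ct) {
        r <- rep(truth$background_rate, fixture$contigs[[ct]])
        ts <- truth$true_sites[truth$true_sites$contig == ct, ]
        for (i in seq_len(nrow(ts)))
          r[(ts$start[i] + 1):ts$end[i]] <-
            site_profile(ts$end[i] - ts$start[i], ts$fold[i])
        as_ <- truth$artifact_sites[truth$artifact_sites$contig == ct &
                                      truth$artifact_sites$lane == lane, ]
        for (i in seq_len(nrow(as_)))
          r[(as_$start[i] + 1):as_$end[i]] <-
            site_profile(as_$end[i] - as_$start[i], as_$fold[i])
        r
      })
    }
    draw <- function(rates, label) {
      if (any(unlist(lapply(rates, function(r) r < 0))))
        stop("negative Poisson rates")
      coverage_track(lapply(rates, function(r) stats::rpois(length(r), r)),
                     label = label, nominal_read_length = nominal_read_length)
    }
    even <- draw(rate_for("even"), "even")
    odd <- draw(rate_for("odd"), "odd")
    input <- draw(lapply(stats::setNames(names(fixture$contigs),
                                         names(fixture$contigs)),
                         function(ct) rep(truth$background_rate,
                                          fixture$contigs[[ct]])), "input")
    list(even = even, odd = odd, input = input)
  })
}

#' Simulate a two-group expression matrix with planted regulated genes
#'
#' Log2 expression is baseline + group effect + Gaussian noise; the first
#' `n_up` planted genes gain `+log2(fold)` in group B, the next `n_down`
#' lose `log2(fold)`. The returned matrix is on the linear scale (like
#' summarized array intensities).
#'
#' @param genes character vector of gene ids.
#' @param n_up,n_down numbers of planted up-/down-regulated genes (in group
#'   B relative to group A).
#' @param fold planted linear fold change (> 0).
#' @param n_reps replicates per group (>= 2).
#' @param noise_sd Gaussian noise SD in log2 units.
#' @param seed integer seed.
#' @param planted optionally, the gene ids to plant (length
#'   `n_up + n_down`); defaults to the first genes in `genes`.
#' @return list with `matrix` (linear scale, genes x samples), `groups`
#'   (factor of `"A"`/`"B"` per column), and `truth` (data.frame `gene_id`,
#'   `direction`).
#' @export
simulate_expression <- function(genes, n_up, n_down, fold = 2, n_reps = 3,
                                noise_sd = 0.25, seed, planted = NULL) {
  if (fold <= 0) stop("fold must be > 0")
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (n_up + n_down > length(genes)) stop("more planted genes than genes")
  with_seed(seed, {
    if (is.null(planted)) planted <- genes[seq_len(n_up + n_down)]
    stopifnot(length(planted) == n_up + n_down)
    effect <- stats::setNames(rep(0, length(genes)), genes)
    effect[planted[seq_len(n_up)]] <- log2(fold)
    if (n_down > 0) effect[planted[n_up + seq_len(n_down)]] <- -log2(fold)
    baseline <- stats::runif(length(genes), 6, 12)
    n <- length(genes)
    A <- matrix(stats::rnorm(n * n_reps, baseline, noise_sd), nrow = n)
    B <- matrix(stats::rnorm(n * n_reps, baseline + effect, noise_sd), nrow = n)
    m <- 2^cbind(A, B)
    dimnames(m) <- list(genes, c(paste0("A_", seq_len(n_reps)),
                                 paste0("B_", seq_len(n_reps))))
    truth <- data.frame(
      gene_id = planted,
      direction = rep(c("up", "down"), times = c(n_up, n_down)))
    list(matrix = m,
         groups = factor(rep(c("A", "B"), each = n_reps)),
         truth = truth)
  })
}

#' Simulate a qPCR Cq table with known fold changes and efficiencies
#'
#' For each target, baseline-sample Cq is drawn once, and the comparison
#' sample's true Cq is `Cq_baseline - log(fold) / log(E)` so that
#' efficiency-corrected quantification recovers `fold` exactly at zero
#' noise. Technical replicates share the true Cq and differ by Gaussian
#' noise. Reference genes must have fold 1.
#'
#' @param targets character vector of target ids (including references).
#' @param fold_changes named numeric: planted linear fold (comparison vs
#'   baseline) per target.
#' @param efficiencies named numeric: per-primer amplification factor in
#'   (1, 2].
#' @param reference_genes character vector (subset of `targets`).
#' @param noise_sd Gaussian Cq noise SD.
#' @param n_reps technical replicates per (target, sample).
#' @param seed integer seed.
#' @param undetected targets reported above the detection ceiling
#'   (Cq set to 40) in both samples.
#' @param samples length-2 character: baseline and comparison sample ids.
#' @return a [qpcr_table()].
#' @export
simulate_qpcr <- function(targets, fold_changes, efficiencies,
                          reference_genes, noise_sd = 0.2, n_reps = 3, seed,
                          undetected = character(),
                          samples = c("baseline", "comparison")) {
  if (any(efficiencies <= 1) || any(efficiencies > 2))
    stop("efficiencies must lie in (1, 2]")
  if (!all(reference_genes %in% targets))
    stop("reference genes must be among targets")
  if (any(abs(fold_changes[reference_genes] - 1) > 1e-12))
    stop("reference genes must have fold change 1")
  with_seed(seed, {
    rows <- list()
    for (tg in targets) {
      E <- efficiencies[[tg]]
      cq_base <- stats::runif(1, 18, 28)
      cq_comp <- cq_base - log(fold_changes[[tg]]) / log(E)
      if (tg %in% undetected) cq_base <- cq_comp <- 40
      for (r in seq_len(n_reps)) {
        rows[[length(rows) + 1]] <- data.frame(
          target = tg, sample = samples[1], replicate = r,
          cq = cq_base + stats::rnorm(1, 0, noise_sd), efficiency = E)
        rows[[length(rows) + 1]] <- data.frame(
          target = tg, sample = samples[2], replicate = r,
          cq = cq_comp + stats::rnorm(1, 0, noise_sd), efficiency = E)
      }
    }
    qpcr_table(do.call(rbind, rows), reference_genes = reference_genes)
  })
}

#' Write an expression matrix as TSV (genes x samples)
#' @param sim a [simulate_expression()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(sim, path) {
  df <- data.frame(gene_id = rownames(sim$matrix),
                   round(sim$matrix, 6), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a qPCR Cq table as TSV
#' @param table a [qpcr_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_qpcr_tsv <- function(table, path) {
  utils::write.table(table$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
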