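# Local-Poisson peak caller, statistics, filter, ranking

make_flat_tracks <- function(cons_vals, input_vals) {
  n <- length(cons_vals)
  cons <- coverage_track(list(chr1 = cons_vals), label = "consensus",
                         total_mapped_reads = 1000)
  inp <- coverage_track(list(chr1 = input_vals), label = "input",
                        total_mapped_reads = 1000)
  list(cons = cons, inp = inp)
}

test_that("per-base Poisson tail p-values match direct summation", {
  pt <- get("poisson_upper_tail", asNamespace("chirpscreen"))
  for (lambda in c(0.1, 1, 5, 20)) {
    for (x in c(1, 2, 5, 20, 50, 100)) {
      got <- pt(x, lambda)$p
      want <- pois_upper_oracle(x, lambda)
      expect_lt(abs(got - want) / want, 1e-9)
    }
  }
  expect_equal(pt(0, 5)$p, 1)
})

test_that("a consensus equal to the input yields zero peaks", {
  set.seed(5)
  v <- rpois(20000, 3)
  tr <- make_flat_tracks(v, v)
  peaks <- call_peaks(tr$cons, tr$inp)
  expect_equal(nrow(peaks), 0)
})

test_that("an enriched region over flat input is called with correct p", {
  v <- rep(1, 50000); w <- rep(1, 50000)
  w[20001:20200] <- 30
  tr <- make_flat_tracks(w, v)
  peaks <- call_peaks(tr$cons, tr$inp, min_gap = 50, min_length = 100)
  expect_equal(nrow(peaks), 1)
  expect_lte(peaks$start, 20000)
  expect_gte(peaks$end, 20200)
  expect_true(peaks$summit >= 20000 && peaks$summit < 20200)
  # the input lane is flat at 1, so the local rate is 1 everywhere and the
  # peak p-value is the plain Poisson tail at the observed count
  expect_equal(peaks$p_value, pois_upper_oracle(30, 1), tolerance = 1e-9)
})

test_that("mismatched or unnormalized tracks are rejected", {
  a <- coverage_track(list(chr1 = rep(1, 100)), total_mapped_reads = 10)
  b <- coverage_track(list(chr1 = rep(1, 100)), total_mapped_reads = 20)
  expect_error(call_peaks(a, b), "same mapped-read total")
  cc <- coverage_track(list(chr2 = rep(1, 100)), total_mapped_reads = 10)
  expect_error(call_peaks(a, cc), "mismatched")
})

test_that("call_peaks recovers planted sites and is deterministic", {
  fx <- simulate_genome(1, 3e5, 0, seed = 21, gene_length_range = c(100, 200))
  truth <- simulate_chirp_truth(fx, n_true = 10, n_artifact = 0,
                                site_width = 300, fold = 8,
                                background_rate = 2, seed = 22)
  lanes <- simulate_chirp_lanes(fx, truth, seed = 23)
  cons <- normalize_track(consensus_track(lanes$even, lanes$odd))
  inp <- normalize_track(lanes$input)
  p1 <- call_peaks(cons, inp, even = lanes$even, odd = lanes$odd)
  p2 <- call_peaks(cons, inp, even = lanes$even, odd = lanes$odd)
  expect_identical(p1, p2)
  hit <- vapply(seq_len(nrow(truth$true_sites)), function(i) {
    s <- truth$true_sites[i, ]
    any(p1$start < s$end & s$start < p1$end)
  }, logical(1))
  expect_gte(sum(hit), 9)
})

test_that("peak statistics match a naive per-base recomputation", {
  set.seed(31)
  n <- 400
  ev <- rpois(n, 6); od <- 2 * ev          # exact linear relation
  cons <- coverage_track(list(chr1 = pmin(ev, od)), total_mapped_reads = 100)
  inp <- coverage_track(list(chr1 = rpois(n, 2)), total_mapped_reads = 100)
  evt <- coverage_track(list(chr1 = ev)); odt <- coverage_track(list(chr1 = od))
  st <- peak_statistics(list(contig = "chr1", start = 50, end = 350),
                        cons, inp, evt, odt)
  expect_equal(st$pearson_r, 1.0)
  idx <- 51:350
  expect_equal(st$avg_coverage, sum(cons$values$chr1[idx]) / 300)
  expect_equal(st$fold_enrichment,
               mean(cons$values$chr1[idx]) /
                 max(mean(inp$values$chr1[idx]), 0.1))
  # reversed ramp gives perfect anticorrelation
  ramp <- coverage_track(list(chr1 = as.numeric(1:n)))
  anti <- coverage_track(list(chr1 = as.numeric(n:1)))
  st2 <- peak_statistics(list(contig = "chr1", start = 0, end = n),
                         cons, inp, ramp, anti)
  expect_equal(st2$pearson_r, -1.0)
  # constant lane -> undefined correlation, flagged as NA
  flat <- coverage_track(list(chr1 = rep(2, n)))
  st3 <- peak_statistics(list(contig = "chr1", start = 0, end = n),
                         cons, inp, flat, odt)
  expect_true(is.na(st3$pearson_r))
  expect_error(peak_statistics(list(contig = "chr1", start = 10, end = 10),
                               cons, inp, evt, odt), "zero-length")
})

test_that("filter thresholds are strict and the boundary peak is rejected", {
  base <- data.frame(contig = "chr1", start = 0L, end = 300L, summit = 150L,
                     length = 300L, p_value = 1e-10, neglog10_p = 10)
  at_boundary <- transform(base, fold_enrichment = 2.0, avg_coverage = 1.5,
                           pearson_r = 0.3)
  expect_equal(nrow(filter_peaks(at_boundary)), 0)
  passing <- transform(base, fold_enrichment = 3, avg_coverage = 2,
                       pearson_r = 0.5)
  expect_equal(nrow(filter_peaks(passing)), 1)
  # each statistic individually at the boundary fails
  for (col in c("fold_enrichment", "avg_coverage", "pearson_r")) {
    p <- passing
    p[[col]] <- c(fold_enrichment = 2.0, avg_coverage = 1.5,
                  pearson_r = 0.3)[[col]]
    expect_equal(nrow(filter_peaks(p)), 0)
  }
  # undefined correlation fails the filter
  expect_equal(nrow(filter_peaks(transform(passing, pearson_r = NA))), 0)
  # summit too close to an edge fails
  expect_equal(nrow(filter_peaks(transform(passing, summit = 5L))), 0)
})

test_that("filter equals a truth-table evaluation and is monotone", {
  peaks <- random_peak_table(200, seed = 41)
  got <- filter_peaks(peaks)
  want <- peaks[peaks$fold_enrichment > 2 & peaks$avg_coverage > 1.5 &
                  peaks$pearson_r > 0.3 & peaks$length >= 100 &
                  peaks$summit - peaks$start >= 10 &
                  peaks$end - 1 - peaks$summit >= 10, ]
  rownames(want) <- NULL
  expect_equal(got, want)
  # raising any threshold never adds a peak
  for (i in 1:20) {
    fe <- runif(1, 0, 5); cv <- runif(1, 0, 5); r <- runif(1, -1, 1)
    sub <- filter_peaks(peaks, fe_min = fe, cov_min = cv, r_min = r)
    sup <- filter_peaks(peaks, fe_min = 2 + fe, cov_min = cv, r_min = r)
    expect_true(all(sup$start %in% sub$start))
    expect_lte(nrow(sup), nrow(sub))
  }
})

test_that("ranking sorts by fold enrichment with p-value tie-break", {
  pk <- random_peak_table(3, seed = 1)
  pk$fold_enrichment <- c(5, 2.5, 9)
  expect_equal(rank_peaks(pk, 3)$fold_enrichment, c(9, 5, 2.5))
  pk$fold_enrichment <- c(4, 4, 1)
  pk$p_value <- c(1e-6, 1e-8, 1e-3)
  expect_equal(rank_peaks(pk, 2)$p_value, c(1e-8, 1e-6))
  expect_error(rank_peaks(pk, 0), "top_n")

  # independent selection-sort oracle on 1000 random peaks: repeatedly
  # extract the best remaining peak by explicit comparison
  peaks <- random_peak_table(1000, seed = 51)
  got <- rank_peaks(peaks, 1000)
  remaining <- peaks
  oracle_idx <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    best <- which(remaining$fold_enrichment == max(remaining$fold_enrichment))
    best <- best[remaining$p_value[best] == min(remaining$p_value[best])]
    best <- best[order(remaining$contig[best], remaining$start[best])][1]
    oracle_idx <- c(oracle_idx, as.integer(rownames(remaining)[best]))
    remaining <- remaining[-best, ]
  }
  oracle <- peaks[oracle_idx, ]
  rownames(oracle) <- NULL
  expect_equal(got, oracle)
})

test_that("narrowPeak export/import round-trips coordinates and summits", {
  peaks <- random_peak_table(20, seed = 61)
  f <- tempfile(); sc <- tempfile()
  write_narrowpeak(peaks, f, sidecar_tsv = sc)
  rt <- read_narrowpeak(f, sidecar_tsv = sc)
  expect_equal(rt$start, peaks$start)
  expect_equal(rt$end, peaks$end)
  expect_equal(rt$summit, peaks$summit)
  expect_equal(rt$fold_enrichment, peaks$fold_enrichment, tolerance = 1e-4)
  expect_equal(rt$pearson_r, peaks$pearson_r, tolerance = 1e-4)
})

test_that("peaks never overlap blacklist-masked intervals", {
  fx <- simulate_genome(1, 2e5, 0, seed = 71, gene_length_range = c(100, 200),
                        n_blacklist = 3, blacklist_length = 500)
  truth <- simulate_chirp_truth(fx, n_true = 6, n_artifact = 0,
                                site_width = 300, fold = 8,
                                background_rate = 2, seed = 72,
                                avoid = fx$blacklist)
  lanes <- simulate_chirp_lanes(fx, truth, seed = 73)
  even <- mask_blacklist(lanes$even, fx$blacklist)
  odd <- mask_blacklist(lanes$odd, fx$blacklist)
  inp <- mask_blacklist(lanes$input, fx$blacklist)
  cons <- normalize_track(consensus_track(even, odd))
  peaks <- call_peaks(cons, normalize_track(inp))
  for (i in seq_len(nrow(fx$blacklist)))
    expect_false(any(peaks$start < fx$blacklist$end[i] &
                       fx$blacklist$start[i] < peaks$end))
})
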