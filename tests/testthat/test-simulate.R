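# Synthetic-data generators: determinism, bounds, planted-signal means

test_that("simulate_genome is deterministic and respects packing bounds", {
  g1 <- simulate_genome(1, 1e5, 20, seed = 1)
  g2 <- simulate_genome(1, 1e5, 20, seed = 1)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$genes), 20)

  g3 <- simulate_genome(2, 5e4, 30, seed = 3, n_blacklist = 3)
  expect_equal(nrow(g3$genes), 30)
  # exhaustive bounds check over every record
  for (i in seq_len(nrow(g3$genes))) {
    g <- g3$genes[i, ]
    expect_true(g$start >= 0 && g$end <= g3$contigs[[g$contig]])
    ex <- g3$exons[g3$exons$gene_id == g$gene_id, ]
    expect_true(all(ex$start >= g$start & ex$end <= g$end))
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1)
      expect_true(all(ex$start[-1] >= ex$end[-nrow(ex)])) # non-overlapping
    expect_true(nrow(ex) >= 1 && nrow(ex) <= 10)
  }
  for (i in seq_len(nrow(g3$blacklist)))
    expect_true(g3$blacklist$end[i] <= g3$contigs[[g3$blacklist$contig[i]]])
  # genes within a contig never overlap
  for (ct in names(g3$contigs)) {
    d <- g3$genes[g3$genes$contig == ct, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
})

test_that("empty gene list and impossible packing are handled", {
  g <- simulate_genome(1, 1000, 0, seed = 7, gene_length_range = c(20, 80))
  expect_equal(nrow(g$genes), 0)
  expect_error(simulate_genome(1, 3e4, 100, seed = 1,
                               gene_length_range = c(2000, 3000)),
               "packing|fit")
})

test_that("planted sites have the stated mean coverage in the right lanes", {
  fx <- simulate_genome(1, 5e4, 0, seed = 11, gene_length_range = c(100, 200))
  truth <- chirp_truth(
    true_sites = data.frame(contig = "chr1", start = 10000, end = 10300,
                            fold = 8),
    artifact_sites = data.frame(contig = "chr1", start = 30000, end = 30300,
                                fold = 8, lane = "even"),
    background_rate = 2)
  lanes <- simulate_chirp_lanes(fx, truth, seed = 5)
  idx <- 10001:10300
  se <- sqrt(16 / 300)
  expect_lt(abs(mean(lanes$even$values$chr1[idx]) - 16), 3 * se)
  expect_lt(abs(mean(lanes$odd$values$chr1[idx]) - 16), 3 * se)
  expect_lt(abs(mean(lanes$input$values$chr1[idx]) - 2), 3 * sqrt(2 / 300))
  # artifact present in even lane only; odd stays at background
  aidx <- 30001:30300
  expect_lt(abs(mean(lanes$odd$values$chr1[aidx]) - 2), 3 * sqrt(2 / 300))
  expect_gt(mean(lanes$even$values$chr1[aidx]), 10)
  # coverage is non-negative integer before normalization
  expect_true(all(lanes$even$values$chr1 >= 0))
  expect_true(all(lanes$even$values$chr1 == round(lanes$even$values$chr1)))
})

test_that("planted-site mean converges to background x fold (10 kb site)", {
  fx <- simulate_genome(1, 3e4, 0, seed = 2, gene_length_range = c(100, 200))
  truth <- chirp_truth(
    true_sites = data.frame(contig = "chr1", start = 5000, end = 15000,
                            fold = 8),
    artifact_sites = data.frame(contig = character(), start = integer(),
                                end = integer(), fold = numeric(),
                                lane = character()),
    background_rate = 2)
  lanes <- simulate_chirp_lanes(fx, truth, seed = 9)
  m <- mean(lanes$even$values$chr1[5001:15000])
  expect_lt(abs(m - 16) / 16, 0.05)
})

test_that("lane bedGraph output is byte-identical under a fixed seed", {
  fx <- simulate_genome(1, 2e4, 0, seed = 4, gene_length_range = c(100, 200))
  truth <- chirp_truth(
    data.frame(contig = "chr1", start = 1000, end = 1300, fold = 4),
    data.frame(contig = "chr1", start = 5000, end = 5300, fold = 4,
               lane = "odd"),
    background_rate = 2)
  f1 <- tempfile(); f2 <- tempfile()
  write_bedgraph(simulate_chirp_lanes(fx, truth, seed = 77)$even, f1)
  write_bedgraph(simulate_chirp_lanes(fx, truth, seed = 77)$even, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("chirp_truth validates folds, rates and disjointness", {
  ts <- data.frame(contig = "chr1", start = 0, end = 100, fold = 8)
  as_ <- data.frame(contig = "chr1", start = 50, end = 150, fold = 8,
                    lane = "even")
  expect_error(chirp_truth(ts, as_, 2), "disjoint")
  expect_error(chirp_truth(transform(ts, fold = 0.5), as_[0, ], 2), "fold")
  expect_error(chirp_truth(ts, as_[0, ], 0), "background_rate")
})

test_that("simulate_expression plants exact folds at zero noise", {
  genes <- sprintf("g%03d", 1:50)
  sim <- simulate_expression(genes, 5, 5, fold = 2, n_reps = 3,
                             noise_sd = 0, seed = 3)
  fold <- rowMeans(sim$matrix[, sim$groups == "B"]) /
    rowMeans(sim$matrix[, sim$groups == "A"])
  expect_equal(unname(fold[sim$truth$gene_id[sim$truth$direction == "up"]]),
               rep(2, 5))
  expect_equal(unname(fold[sim$truth$gene_id[sim$truth$direction == "down"]]),
               rep(0.5, 5))
  expect_equal(unname(fold[11:50]), rep(1, 40))
})

test_that("null expression matrices carry no planted structure", {
  sim <- simulate_expression(sprintf("g%d", 1:200), 0, 0, fold = 2,
                             n_reps = 3, noise_sd = 0.3, seed = 8)
  expect_equal(nrow(sim$truth), 0)
  l2fc <- log2(rowMeans(sim$matrix[, 4:6]) / rowMeans(sim$matrix[, 1:3]))
  expect_lt(abs(mean(l2fc)), 0.1)
  expect_error(simulate_expression(letters, 1, 0, fold = -1, seed = 1),
               "fold")
})

test_that("planted expression fold is recovered on average", {
  sim <- simulate_expression(sprintf("g%04d", 1:1000), 50, 0, fold = 2,
                             n_reps = 3, noise_sd = 0.25, seed = 11)
  up <- sim$truth$gene_id
  l2fc <- log2(rowMeans(sim$matrix[up, sim$groups == "B"]) /
                 rowMeans(sim$matrix[up, sim$groups == "A"]))
  # Monte-Carlo error of the mean over 50 genes, 3 reps, sd 0.25
  expect_lt(abs(mean(l2fc) - 1), 4 * 0.25 * sqrt(2 / 3) / sqrt(50))
})

test_that("simulate_qpcr encodes folds via primer efficiency", {
  tg <- c("x", "ref")
  tab <- simulate_qpcr(tg, c(x = 2, ref = 1), c(x = 2, ref = 2), "ref",
                       noise_sd = 0, n_reps = 2, seed = 1)
  r <- tab$records
  dcq <- mean(r$cq[r$target == "x" & r$sample == "comparison"]) -
    mean(r$cq[r$target == "x" & r$sample == "baseline"])
  expect_equal(dcq, -1)   # fold 2, E = 2 -> exactly one cycle earlier

  tab4 <- simulate_qpcr(tg, c(x = 4, ref = 1), c(x = 1.9, ref = 2), "ref",
                        noise_sd = 0, n_reps = 1, seed = 1)
  r4 <- tab4$records
  dcq4 <- r4$cq[r4$target == "x" & r4$sample == "comparison"] -
    r4$cq[r4$target == "x" & r4$sample == "baseline"]
  expect_equal(dcq4, -log(4) / log(1.9))   # closed-form logarithm oracle
  expect_error(simulate_qpcr(tg, c(x = 2, ref = 1), c(x = 1, ref = 2),
                             "ref", seed = 1), "effic")
  expect_error(simulate_qpcr(tg, c(x = 2, ref = 2), c(x = 2, ref = 2),
                             "ref", seed = 1), "reference")
})

test_that("generators restore the caller's RNG state", {
  set.seed(99); before <- .Random.seed
  invisible(simulate_genome(1, 5e4, 5, seed = 1))
  expect_identical(.Random.seed, before)
})
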