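# GFF3 coordinate conventions, genic classification, occupancy summary

fake_peak <- function(summit, contig = "chr1") {
  data.frame(contig = contig, start = summit - 50L, end = summit + 50L,
             summit = as.integer(summit), length = 100L, p_value = 1e-8,
             neglog10_p = 8, fold_enrichment = 5, avg_coverage = 3,
             pearson_r = 0.8)
}

test_that("GFF3 1-based inclusive converts to 0-based half-open", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=gA",
               "chr1\tsrc\texon\t1\t50\t.\t+\t.\tID=gA.e1;Parent=gA",
               "chr1\tsrc\texon\t61\t100\t.\t+\t.\tID=gA.e2;Parent=gA",
               "chr1\tsrc\tgene\t201\t300\t.\t-\t.\tID=gB"), f)
  m <- read_gff(f)
  expect_equal(m$genes$start[m$genes$gene_id == "gA"], 0)
  expect_equal(m$genes$end[m$genes$gene_id == "gA"], 100)
  exA <- m$exons[m$exons$gene_id == "gA", ]
  expect_equal(exA$start, c(0, 60))
  expect_equal(exA$end, c(50, 100))
  # the implied intron is [50, 60)
  expect_equal(sort(setdiff(0:99, unlist(mapply(seq, exA$start,
                                                exA$end - 1)))), 50:59)
  # genes without exon records get a single exon covering the span
  exB <- m$exons[m$exons$gene_id == "gB", ]
  expect_equal(c(exB$start, exB$end), c(200, 300))
})

test_that("malformed GFF3 lines are reported with line numbers", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=gA",
               "chr1\tgene\t1\t100"), f)
  expect_error(read_gff(f), "line 3")
})

test_that("GFF3 writer round-trips through the reader", {
  fx <- simulate_genome(2, 5e4, 12, seed = 19)
  f <- tempfile(fileext = ".gff3")
  write_genes_gff3(fx, f)
  m <- read_gff(f)
  m$genes <- m$genes[order(m$genes$gene_id), ]
  fx_genes <- fx$genes[order(fx$genes$gene_id), ]
  expect_equal(m$genes$start, fx_genes$start)
  expect_equal(m$genes$end, fx_genes$end)
  expect_equal(m$genes$strand, fx_genes$strand)
  ord <- function(d) d[order(d$gene_id, d$start), c("gene_id", "start", "end")]
  expect_equal(ord(m$exons), ord(fx$exons), ignore_attr = TRUE)
})

test_that("promoters are strand-aware and clipped to contig bounds", {
  genes <- data.frame(gene_id = c("p", "m"), contig = "chr1",
                      strand = c("+", "-"), start = c(500, 3000),
                      end = c(1500, 4000))
  pr <- promoter_intervals(genes, halfwidth = 1000,
                           contigs = c(chr1 = 4500L))
  expect_equal(pr$start[1], 0)      # 500 - 1000 clipped at 0
  expect_equal(pr$end[1], 1500)
  expect_equal(pr$start[2], 2999)   # TSS of '-' gene is end - 1
  expect_equal(pr$end[2], 4500)     # clipped at contig length
})

test_that("classification follows promoter > exon > intron precedence", {
  models <- list(
    genes = data.frame(gene_id = c("gA", "gB"), contig = "chr1",
                       strand = c("+", "+"), start = c(1000, 4000),
                       end = c(3000, 6000)),
    exons = data.frame(gene_id = c("gA", "gA", "gB"), contig = "chr1",
                       start = c(1000, 2500, 4000),
                       end = c(2000, 3000, 6000)))
  # summit in gA's intron
  cl <- classify_peaks(fake_peak(2200), models, promoter_halfwidth = 200)
  expect_equal(as.character(cl$category), "intron")
  expect_equal(cl$genes, "gA")
  # summit in gA's second exon, which is also within gB's promoter
  # (gB TSS = 4000; halfwidth 1200 reaches back to 2800)
  cl2 <- classify_peaks(fake_peak(2900), models, promoter_halfwidth = 1200)
  expect_equal(as.character(cl2$category), "promoter")
  expect_equal(cl2$genes, "gA,gB")
  # the same summit without the promoter is exonic
  cl3 <- classify_peaks(fake_peak(2900), models, promoter_halfwidth = 100)
  expect_equal(as.character(cl3$category), "exon")
  # summit on a gene-free contig is intergenic with no genes
  cl4 <- classify_peaks(fake_peak(500, contig = "chr9"), models)
  expect_equal(as.character(cl4$category), "intergenic")
  expect_equal(cl4$genes, "")
})

test_that("every peak gets exactly one category and fractions sum to one", {
  fx <- simulate_genome(1, 2e5, 30, seed = 23)
  peaks <- do.call(rbind, lapply(seq(1000, 190000, by = 9500), fake_peak))
  cl <- classify_peaks(peaks, fx, contigs = fx$contigs)
  expect_false(any(is.na(cl$category)))
  expect_equal(sum(table(cl$category)), nrow(peaks))
  s <- occupancy_summary(cl, fx)
  expect_equal(sum(s$category_counts), nrow(peaks))
})

test_that("occupancy summary counts match exhaustive membership checks", {
  tiny <- list(genes = data.frame(gene_id = "g", contig = "chr1",
                                  strand = "+", start = 0, end = 10),
               exons = data.frame(gene_id = "g", contig = "chr1",
                                  start = 0, end = 10))
  empty <- occupancy_summary(classify_peaks(fake_peak(1)[0, ], tiny), tiny)
  expect_equal(empty$fraction_occupied, 0)
  expect_equal(sum(empty$category_counts), 0)

  fx <- simulate_genome(1, 3e5, 40, seed = 29)
  peaks <- do.call(rbind, lapply(seq(2000, 290000, by = 7000), fake_peak))
  cl <- classify_peaks(peaks, fx, promoter_halfwidth = 2000,
                       contigs = fx$contigs)
  s <- occupancy_summary(cl, fx)
  # brute force: for every gene, count peaks whose summit lies in the span
  # or promoter
  pr <- promoter_intervals(fx$genes, 2000, fx$contigs)
  for (i in seq_len(nrow(fx$genes))) {
    g <- fx$genes[i, ]
    p <- pr[i, ]
    n <- sum(vapply(peaks$summit, function(smt)
      (g$start <= smt && smt < g$end) || (p$start <= smt && smt < p$end),
      logical(1)))
    expect_equal(unname(s$per_gene[g$gene_id]), n)
  }
  expect_equal(s$fraction_occupied, mean(s$per_gene > 0))
  # invariance to peak order
  s2 <- occupancy_summary(cl[rev(seq_len(nrow(cl))), ], fx)
  expect_equal(s2$per_gene, s$per_gene)
})

test_that("three peaks in one gene count three times for that gene", {
  models <- list(
    genes = data.frame(gene_id = c("g1", "g2"), contig = "chr1",
                       strand = "+", start = c(1000, 50000),
                       end = c(9000, 58000)),
    exons = data.frame(gene_id = c("g1", "g2"), contig = "chr1",
                       start = c(1000, 50000), end = c(9000, 58000)))
  peaks <- do.call(rbind, lapply(c(2000, 4000, 6000), fake_peak))
  cl <- classify_peaks(peaks, models, promoter_halfwidth = 100)
  s <- occupancy_summary(cl, models)
  expect_equal(unname(s$per_gene["g1"]), 3)
  expect_equal(s$fraction_occupied, 0.5)
})

test_that("widening the promoter never shrinks the occupied gene set", {
  fx <- simulate_genome(1, 2e5, 25, seed = 31)
  peaks <- do.call(rbind, lapply(seq(3000, 190000, by = 11000), fake_peak))
  prev <- character(0)
  for (hw in c(200, 1000, 2000, 5000)) {
    cl <- classify_peaks(peaks, fx, promoter_halfwidth = hw,
                         contigs = fx$contigs)
    s <- occupancy_summary(cl, fx)
    occ <- names(s$per_gene)[s$per_gene > 0]
    expect_true(all(prev %in% occ))
    prev <- occ
  }
})
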