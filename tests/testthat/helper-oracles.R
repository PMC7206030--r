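# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks: direct summation instead of ppois, exhaustive
# enumeration instead of phyper/fisher.test, naive loops instead of the
# vectorized track operations.

# Poisson upper tail P(X >= x) by direct term summation on the log scale
pois_upper_oracle <- function(x, lambda) {
  if (x <= 0) return(1)
  k <- x:(x + 2000)
  sum(exp(k * log(lambda) - lambda - lgamma(k + 1)))
}

# per-base minimum by explicit loop
naive_min_loop <- function(a, b) {
  out <- numeric(length(a))
  for (i in seq_along(a)) out[i] <- min(a[i], b[i])
  out
}

# zero out blacklist members base by base
naive_mask_loop <- function(v, intervals_01based) {
  for (iv in intervals_01based) for (i in iv) v[i] <- 0
  v
}

# hypergeometric upper tail P(overlap >= k) by exhaustive enumeration of
# all |B|-subsets of a universe of size N containing |A| marked elements
hyper_upper_enum <- function(N, nA, nB, k) {
  subsets <- utils::combn(N, nB)
  marked <- seq_len(nA)
  hits <- apply(subsets, 2, function(s) sum(s %in% marked))
  mean(hits >= k)
}

# two-sided Fisher exact p by enumerating all tables with the observed
# margins and summing probabilities of tables no more likely than observed
fisher_two_sided_enum <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  probs <- vapply(max(0, c1 - (n - r1)):min(r1, c1), function(x)
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)),
    numeric(1))
  p_obs <- exp(lchoose(r1, a) + lchoose(n - r1, c1 - a) - lchoose(n, c1))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force best T-window fraction by substring enumeration
t_rich_oracle <- function(seq, motif_len) {
  n <- nchar(seq)
  if (n < motif_len) return(NA_real_)
  best <- 0
  for (i in 1:(n - motif_len + 1)) {
    sub <- substr(seq, i, i + motif_len - 1)
    frac <- sum(strsplit(sub, "")[[1]] == "T") / motif_len
    best <- max(best, frac)
  }
  best
}

# small ready-made track pair over one contig
tiny_tracks <- function(values_even, values_odd, label = c("even", "odd")) {
  list(even = coverage_track(list(chr1 = values_even), label = label[1]),
       odd = coverage_track(list(chr1 = values_odd), label = label[2]))
}

# random peak table with statistics, for filter/rank property tests
random_peak_table <- function(n, seed) {
  with_seed <- get("with_seed", asNamespace("chirpscreen"))
  with_seed(seed, {
    start <- sort(sample.int(1e6, n))
    len <- sample(100:500, n, replace = TRUE)
    data.frame(contig = sample(c("chr1", "chr2"), n, replace = TRUE),
               start = start, end = start + len,
               summit = start + pmax(11L, pmin(len - 12L, as.integer(len / 2))),
               length = len,
               p_value = 10^-runif(n, 1, 30),
               neglog10_p = runif(n, 1, 30),
               fold_enrichment = runif(n, 0, 10),
               avg_coverage = runif(n, 0, 10),
               pearson_r = runif(n, -1, 1))
  })
}
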