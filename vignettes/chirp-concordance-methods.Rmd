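---
title: "Methods: concordance-based ChIRP-seq analysis and the qPCR enrichment screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concordance-based ChIRP-seq analysis and the qPCR enrichment screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chirpscreen)
```

`chirpscreen` packages the computational arc of a lncRNA characterization
study: a qPCR screen nominating candidate lncRNAs enriched in a stem-like
cell population, and a ChIRP-seq concordance analysis mapping where the
lncRNA touches chromatin and whether that occupancy is concentrated in the
genes it regulates. This vignette is the package's own account of the
models, the parameters that matter, the synthetic-data design, and the
numerical decisions — including the places where the procedure was
genuinely open and a convention had to be chosen.

## 1. Efficiency-corrected qPCR quantification

`relative_expression()` implements Pfaffl-style quantification. Technical
replicates are first averaged to a mean Cq per (target, sample); the
comparison/baseline expression ratio is

$$\mathrm{ratio} \;=\;
\frac{E_t^{\,Cq_\mathrm{base} - Cq_\mathrm{comp}}}
     {\mathrm{geomean}_{r \in \mathrm{refs}}\; E_r^{\,Cq_\mathrm{base} - Cq_\mathrm{comp}}}$$

with per-primer efficiencies $E \in (1, 2]$ estimated upstream from
standard curves (efficiency estimation itself is out of scope; $E$ is an
input). With all $E = 2$ this reduces to the classical $2^{-\Delta\Delta
Cq}$, which the tests assert to machine precision.

Choices worth stating:

* **Reference set is explicit per run.** Different experiments legitimately
  use different reference-gene pairs; nothing is hard-coded. The recovery
  simulations use a two-reference design because that is the design the
  screen emulates — and because with Cq noise $\sigma = 0.2$ and 3
  replicates the estimator's error scales as
  $\sigma\sqrt{2/3}\,\sqrt{1 + 1/n_\mathrm{ref}}$: a single reference gives
  a median absolute log2 error of ~0.156, two references ~0.135.
* **Detection ceiling** Cq 35 (configurable): at or above it a measurement
  is "not detected" (ND), which excludes a target from the screen rather
  than erroring; a missing *reference* measurement, by contrast, is an
  error because nothing downstream is interpretable without it.
* **Biological replicates**: ratios are computed per sample pairing, then
  log2 ratios are averaged (`enrichment_screen()`); averaging Cq across
  biological pairs first would conflate pairing structure with technical
  noise.
* **Dual-model filter boundary**: inclusive, `log2FC >= 1` in both models.
  The source material states the threshold both inclusively and strictly
  in different places; the inclusive figure-legend form is the default and
  `strict = TRUE` is available.

## 2. Coverage tracks and the even/odd consensus

A `CoverageTrack` stores per-base coverage (0-based half-open) per contig,
the lane label, a mapped-read total (coverage sum / 130 bp nominal read
length), and a cumulative normalization `scale` factor. Per-base rather
than binned storage is deliberate: fixtures are ≤ a few Mb, and exactness
makes every operation testable against naive loops.

The pipeline order is **mask → consensus → normalize**:

1. `mask_blacklist()` zeroes coverage in blacklist intervals and reduces
   the read total accordingly.
2. `consensus_track()` takes the per-base minimum of the even and odd
   lanes — the concordance operation. Signal present in one lane only is
   capped at the other lane's background.
3. `normalize_track()` rescales to 150 M mappable reads (the conventional
   depth), recording the factor in `scale`.

Whether normalization should precede the consensus is not determined by
the source procedure; we normalize after, and normalize the consensus and
input lanes identically, because fold enrichment is only meaningful when
both sides share a depth scale. Masking and the per-base minimum commute
(proved as a property test), so their order is immaterial.

## 3. The local-Poisson peak caller

`call_peaks()` is a transparent stand-in for a full peak caller (MACS-class
tools bring fragment-shift models, duplicate handling and q-values that are
out of scope; an escape hatch imports external narrowPeak files). Per base,
the consensus count $x$ is tested against

$$\lambda_\mathrm{local} = \max(\bar{\lambda}_\mathrm{genome},\;
\bar{\lambda}_\mathrm{1kb},\; \bar{\lambda}_\mathrm{10kb},\; 0.1)$$

computed from the depth-matched input lane, with upper-tail p-value
$P(X \ge x)$ evaluated on the log scale. Bases with $p < 10^{-5}$ are
merged when closer than `min_gap` (130 bp, one read length), regions
shorter than `min_length` (100 bp) are dropped, the summit is the leftmost
maximum of consensus coverage, and the peak p-value is the per-base
minimum.

**Scale handling is the one subtle point.** The Poisson model is only valid
on counts, but the pipeline normalizes tracks to 150 M reads first. The
track's `scale` field resolves this: consensus counts are recovered as
`value / scale`, and because both tracks share a read total, the
depth-matched input rate is `input_value / consensus_scale`. Normalized
values are never themselves treated as counts — doing so would inflate
significance by the normalization factor.

`filter_peaks()` applies the multi-criteria filter with **strict**
inequalities: fold enrichment > 2, average coverage > 1.5, even/odd
Pearson r > 0.3. A peak sitting exactly at (2.0, 1.5, 0.3) is rejected. The
correlation is computed per-base over the peak interval only; when either
lane is constant there the correlation is undefined (`NA`) and the peak
fails the filter — an undefined concordance is no evidence of concordance.
Two further criteria the source procedure names but does not quantify —
peak length and summit placement — default to `min_length = 100` bp and
`summit_window = 10` bp (summit at least 10 bp from both ends), both
configurable and logged rather than guessed silently. The pseudo-rate
floor 0.1 prevents division by zero in fold enrichment over empty input.

`rank_peaks()` sorts by fold enrichment, breaking ties by smaller p-value
and then genomic order, so ranking is total and deterministic.

## 4. Annotation and the occupancy statistics

Peaks are classified by **summit position** (a point), with precedence
promoter > exon > intron and intergenic otherwise; interval-overlap mode
exists behind a flag. Summit classification avoids multi-category
ambiguity for long peaks; the precedence order is a stated convention.
Promoters are TSS ± 2000 bp, strand-aware, clipped to contig bounds —
a conventional definition, configurable. UTRs are not modelled separately.

`occupancy_summary()` counts peaks per category and per gene (a peak
counts toward every gene whose span or promoter contains its summit), and
reports the fraction of genes with ≥ 1 peak.

## 5. Regulated genes and enrichment tests

`differential_filter()` reproduces the microarray-style volcano filter:
per gene, fold change is the ratio of group means on the linear scale, and
the p-value is a two-group one-way ANOVA — computed as the equivalent
equal-variance two-sample t-test — on log2 intensities. A gene is up when
fold > 1.70 and p < 0.05 (both strict on the fold side; the p threshold is
a strict `<`). The source figure legend reads "a p-value of >0.05", which
can only be a typographical inversion given the volcano-plot convention
and the $-\log_{10}$(ANOVA p) axis; the filter implements p < 0.05. No
multiple-testing correction is applied by default (matching the filter
being reproduced); Benjamini–Hochberg is available via `adjust = "BH"`.

`overlap_enrichment()` models set overlap hypergeometrically: observed
$|A \cap B|$, expected $|A||B|/N$, and upper-tail
$P(X \ge \mathrm{obs})$. Because the informal "random probability"
expectation can be read as either $|A|/N$ or $|B|/N$, both marginal
fractions are reported alongside the expectation rather than choosing one.

`occupancy_enrichment()` builds the 2×2 regulated × occupied table; the
odds ratio uses Haldane's +0.5 correction when any cell is zero; the
p-value is the two-sided Fisher exact test up to a 10,000-gene universe
and the hypergeometric upper tail beyond.

## 6. Summit windows and the T-rich scan

`extract_summit_windows()` emits `[summit − 200, summit + 200)` sequences
(400 bp total) of the top fold-enrichment-ranked peaks, optionally
restricted to peaks annotated to a regulated-gene set, clipped and flagged
at contig edges — the FASTA handed to external motif-discovery tools.
De novo motif discovery is deliberately not reimplemented; `t_rich_scan()`
exists only so the repository can assert something about motif content
internally: a window is positive when any 21-mer within it is ≥ 80% T
(≈ 17/21; N counts as non-T). Both the motif length and the fraction are
conventions, configurable.

## 7. What the synthetic data emulates — and what it does not

The generators (`simulate_genome()`, `simulate_chirp_truth()`,
`simulate_chirp_lanes()`, `simulate_expression()`, `simulate_qpcr()`) are
first-class, seeded, and bit-reproducible; every seed is an explicit
argument and the caller's RNG state is restored.

* **Coverage lanes** are independent per-base Poisson draws. Inside a
  true site both pulldown lanes share a **triangular rate profile**
  (edges at background, apex at $(2f-1)\times$ background, mean exactly
  $f \times$ background). The shared profile matters: two lanes sampling
  the same underlying fragment pile-up is precisely what makes even/odd
  per-base correlation informative at genuine sites, whereas a flat
  planted rate would leave the lanes uncorrelated and the concordance
  filter meaningless. Artifact sites get the same profile in exactly one
  lane. Not modelled: fragment-length autocorrelation, GC/mappability
  bias, read-level artifacts — so real tracks are rougher than these, and
  passing tests demonstrate correctness of the operations, not
  performance on real libraries.
* **The genome** is uniform ACGT with optional planted T-rich 21-mers
  (`plant_t_rich_motifs()`), gene models with 1–10 non-overlapping exons
  packed without overlap, and blacklist intervals. No repeats, no
  isoforms, no UTR structure.
* **Expression matrices** are log2-Gaussian around per-gene baselines
  with ±log2(fold) planted group effects; arrays' probe-level summarization
  and batch structure are not modelled.
* **qPCR tables** encode a planted fold through the primer efficiency,
  $Cq_\mathrm{comp} = Cq_\mathrm{base} - \log_E(\mathrm{fold})$, plus
  Gaussian Cq noise on technical replicates — so zero-noise recovery is
  exact by construction and noisy recovery measures the estimator.

The default study conditions (`chirp_workflow_params()`): one 1 Mb contig,
120 genes, background rate 2 reads/base, 20 true + 20 artifact sites of
300 bp at fold 8, a 2000-gene expression universe (120 on-fixture genes
plus 1880 off-fixture genes, since a tested universe always dwarfs any one
locus) with 25 + 25 planted 2-fold genes per knockdown model sharing 20,
half the true sites placed inside planted regulated genes, T-rich
insertions in every other true site, and a 50-target qPCR screen with 36
detectable targets of which exactly 10 are dual-model enriched. These
sizes keep the full workflow to tens of seconds while leaving every
statistic well away from small-sample degeneracy; they are the package's
chosen study scale, stated here so results are interpreted at that scale.

## 8. Numerical choices and degenerate inputs

* Poisson tails, hypergeometric tails, and Fisher tests come from R's
  stats routines (`ppois` on the log scale, `phyper`, `fisher.test`);
  the test suite cross-checks them against independent summation and
  exhaustive enumeration oracles rather than trusting either side.
* bedGraph writing collapses runs and prints integers plainly and
  fractional values with 17 significant digits, so write→read round-trips
  per-base values exactly and outputs are byte-stable for golden-file
  comparison.
* Normalized fractional coverage is kept as-is (no re-rounding); counts
  are recovered through the `scale` field where a count model needs them.
* Empty cases are defined, not accidental: empty bedGraph → all-zero
  track; empty blacklist → identity; zero peaks → zero-count summaries;
  zero-length regions, zero-read normalization, impossible gene packing,
  efficiencies outside (1, 2] and undersized universes are explicit
  errors.

## 9. Known limitations

* The peak caller is a desk-scale stand-in: no fragment-shift model, no
  duplicate handling, no q-values (filtering is on raw p, as in the
  procedure being reproduced).
* Per-base tracks are memory-proportional to genome size; the design
  targets fixtures of a few Mb, not full mammalian genomes.
* Summit-point classification understates multi-gene contact for very
  broad peaks; overlap mode is available but changes category semantics.
* The T-rich scan is a presence/absence check, not motif discovery; its
  output should be read as "the exported windows contain the planted
  signal", nothing more.
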