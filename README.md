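# chirpscreen

Identifying where a chromatin-associated long non-coding RNA (lncRNA) binds
the genome — and whether it binds the genes it regulates — requires stitching
together several analyses: a qPCR screen that nominates candidate lncRNAs
enriched in a cell population of interest (here, Aldefluor-high cancer
stem-cell-like cells), and a ChIRP-seq (chromatin isolation by RNA
purification sequencing) analysis that maps the RNA's chromatin occupancy
from two independent "even" and "odd" probe pulldowns. `chirpscreen`
implements this pipeline end to end as a tested R package, together with a
seeded synthetic-data module that generates every input with known ground
truth, so that each stage's behaviour (recovery, specificity, calibration)
is measurable.

## The methods at the core

**Efficiency-corrected qPCR quantification (Pfaffl).** For target *t* with
primer amplification efficiency *E_t*, the expression ratio of a comparison
sample over a baseline is

    ratio = E_t^(Cq_base − Cq_comp) / geomean_ref( E_r^(Cq_base − Cq_comp) )

with the denominator a geometric mean over reference genes. Candidates are
targets with log2 ratio ≥ 1 (at least 2-fold enrichment) in **both** tumor
models (`dual_model_filter()`).

**Even/odd consensus.** ChIRP splits the antisense probes into even and odd
sets; only signal concordant between the two pulldowns is trusted. The
consensus ("true") coverage at every base is

    true coverage = min(even coverage, odd coverage)

which suppresses probe-specific artifacts present in one lane only. Tracks
are blacklist-masked, and depth-normalized to 150 M mappable reads.

**Local-Poisson peak calling and the multi-criteria filter.** Each consensus
base is tested against a Poisson upper tail with local rate
λ = max(genome-wide input mean, 1 kb window, 10 kb window, pseudo-rate),
measured on the depth-matched input lane (p < 1e-5). Merged regions are
kept only when fold enrichment against input > 2, average coverage > 1.5
and the even/odd per-base Pearson correlation > 0.3 (all strict), then
ranked by fold enrichment.

**Downstream statistics.** Peaks are classified by summit into
promoter/exon/intron/intergenic; regulated gene sets come from a
fold > 1.70, ANOVA p < 0.05 filter on two-group expression matrices; set
overlap and occupancy-vs-regulation enrichment use hypergeometric and
Fisher exact tests; 400 bp summit windows are exported as FASTA for motif
discovery, with an internal 21 bp T-rich scan.

## Worked example

The numbered drivers under `analysis/` run the full seeded study
(`run_chirp_workflow(seed = 42)`); each is a thin narrative over package
functions. For example:

```sh
$ Rscript analysis/03_chirp_peaks.R
Significant regions called: 20
Peaks surviving the multi-criteria filter: 20
Planted true sites recovered: 20 / 20 (100%)
Single-lane artifact sites surviving: 0 / 20

$ Rscript analysis/05_regulated_enrichment.R
Model 1 regulated genes: 19 up, 23 down
Model 2 regulated genes: 19 up, 21 down
Co-regulated overlap: 11 observed vs 0.84 expected (2.10% of the universe per set); p = 1.3e-10
Occupancy among regulated genes: 28.6% vs 0.31% among others; OR = 130.1, p = 2.28e-17

$ Rscript analysis/06_motif_windows.R
Summit windows extracted: 12 (of 20 filtered peaks; restricted to regulated genes)
Windows containing a 21 bp T-rich motif (>= 80% T): 6 / 12
```

All 20 planted true binding sites are recovered while none of the 20
single-lane artifact sites survive the consensus + filter path; the two
knockdown models' regulated genes overlap far above the ~0.8 genes expected
under independence; and occupancy is concentrated in regulated genes
(28.6% vs 0.31%), with the planted T-rich motif found in half the summit
windows — each number traceable to the generator's ground truth.

In R the same run is one call:

```r
library(chirpscreen)
res <- run_chirp_workflow(seed = 42, outdir = "out")
res$recovery
#> $true_recall [1] 1 ... $n_artifact_surviving [1] 0
```

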