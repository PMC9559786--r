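---
title: "Methods: peak enrichment over risk haplotypes, CTCF-validated TADs, and target-gene nomination"
author: "haplotad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak enrichment over risk haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplotad)
```

## The scientific question

Genome-wide association studies tag disease risk with SNPs, but the tag SNP
is rarely the causal variant, and the causal variant's target gene is rarely
obvious. For juvenile idiopathic arthritis (JIA), risk is tagged by 36 SNPs
whose linkage-disequilibrium (LD) blocks (r² ≥ 0.80) span 5 kb–468 kb.
`haplotad` asks three questions about these LD blocks in a cell type of
interest:

1. **Are the risk haplotypes enriched for regulatory-element peaks** —
   H3K4me1/H3K27ac ChIP-seq (enhancer chromatin) or GRO-seq bidirectional
   transcription (functionally active enhancers) — relative to the genome
   background?
2. **Which topologically associating domains (TADs) around those haplotypes
   are structurally credible**, i.e. carry CTCF anchors at both boundaries?
3. **Which expressed genes inside those TADs are plausible enhancer
   targets?**

## The enrichment model

Let $k_{obs}$ be the overlap count between a peak set and the $n$ risk
haplotypes. The null model drops $n_r$ random regions of fixed length $L$
uniformly on the genome (each wholly inside one chromosome; the chromosome
is chosen with probability proportional to its number of valid start
positions, $\mathrm{len} - L + 1$), counts their overlap with the peaks,
and repeats this $R$ times. A normal distribution is fitted to the
replicate counts by the sample mean $\hat\mu$ and $n{-}1$ standard
deviation $\hat\sigma$, and

$$ z = \frac{k_{obs} - \hat\mu}{\hat\sigma}, \qquad
   p = 1 - \Phi(z) $$

is reported one-sided (enrichment only; the analysis never tests
depletion). Defaults mirror the study design: $n_r = 36$ regions of
$L = 86{,}676$ bp — the floor of the mean printed haplotype length — and
$R = 1000$ replicates. For MPRA-region enrichment the same engine is
configured with $n_r = 18$ and $L$ = the mean MPRA region length.

### What "overlap count" means

The phrase "number of overlaps" is ambiguous between *intersection events*
(peak × region pairs, so one haplotype covered by three peaks counts three)
and *regions hit* (haplotypes with ≥ 1 peak). Both readings are
implemented; `overlap_unit = "events"` is the default for the statistic,
and `"regions_hit"` generates the per-haplotype "+/−" annotation tables.
The choice is an explicit `null_config()` parameter, never implicit.

### Numerical and degenerate-case choices

* The mean region length is **floored** to an integer bp (86,676.61 →
  86,676).
* No continuity correction is applied to the normal fit.
* The p-value is floored at $10^{-300}$ to avoid underflow; rounding
  happens only at print time.
* If every replicate count is identical ($\hat\sigma = 0$, e.g. an empty
  peak set, or a saturating one under `regions_hit`), the null is flagged
  *degenerate* and `enrichment_p()` refuses to fit a normal; the
  documented fallback is the rank-based `empirical_p()`,
  $(1 + \#\{r_i \ge k_{obs}\})/(R+1)$.
* Random regions may overlap each other and real features; there is no
  assembly-gap or blacklist exclusion by default (an optional
  `exclusion_mask` redraws offending regions), because the reference
  procedure states none.
* Every result records its `null_config`, including the seed; no global
  RNG state is consumed (`with_seed` saves and restores `.Random.seed`).

### Overlap engine

Intervals are 0-based half-open (BED convention); abutting intervals do
not overlap; strand is ignored everywhere. Counting is sort-and-sweep: the
peak set is indexed once per chromosome as sorted start/end vectors, and
the number of peaks overlapping $[s,e)$ is
$\#\{start \le e-1\} - \#\{end \le s\}$ by binary search —
$O((n+m)\log m)$ overall. The test suite proves equivalence with an
all-pairs brute force on 100 seeded random instances and against
`GenomicRanges::countOverlaps`.

### Coordinate conventions

Printed locus strings ("chr1:113,761,186-113,834,946") are 1-based
inclusive and converted on ingest (`start = A−1`, `end = B`). The
published table's "Length" column equals $B-A$, one less than the
half-open span; the packaged fixture keeps the printed value verbatim (it
is what the published mean of 86,676 bp is computed from) and the loader
asserts the convention rather than recomputing lengths.

## CTCF-anchor validation of TADs

Candidate TADs arrive as plain intervals (loop calling from Hi-C contact
maps is out of scope — candidates are produced externally). A domain is
retained iff **both** boundaries have ≥ 1 CTCF peak within
`[boundary − w, boundary + w)`. The reference procedure gives no window,
so the default is $w = 25{,}000$ bp — the order of Hi-C loop-anchor
resolution — exposed as `check_anchors(window = )`; retention is monotone
non-decreasing in $w$ (tested). "Clear anchor" is operationalized as
presence only; an optional `min_signal` cut on the narrowPeak signalValue
column is available but off by default. On the packaged annotation, 29 of
36 LD blocks qualify for TAD analysis (H3K4me1 present, with or without
H3K27ac — H3K27ac alone does not qualify; no such row exists in the
published table, so that reading is our decision, recorded here), and the
published outcome is that exactly one qualified locus (PTPN22) fails the
anchor check, leaving 28.

## Target genes

Genes are assigned to a TAD on **any overlap** of the gene body with the
domain (the least restrictive faithful reading of browser-based RefSeq
alignment; a TSS-only mode exists behind `mode = "tss"`). Filters:
biotype must be `protein_coding` (pseudogenes and ncRNA removed), and
TPM ≥ 1 — the exclusion rule is "TPM < 1", so the boundary value 1 is
kept. The filters commute (tested). Genes spanning two TADs count once in
the union summary; whether the published 321-gene figure deduplicated such
genes is unstated, so both per-TAD counts and the deduplicated union are
reported. The 321 count itself depends on external RefSeq/RNA-seq inputs
and is not treated as reproducible here.

## The synthetic-data generator

`sim_config()` defaults define the study conditions the tests run under:

* genome: 3 chromosomes × 50 Mb — large enough to hold 36 haplotypes
  (~3.1 Mb total) without crowding, small enough for seconds-scale tests;
* haplotypes: 36, with the published length distribution
  (`"from_table1"`), placed by rejection sampling with ≥ 500 kb spacing so
  that TAD margins (50–200 kb) and anchor windows of neighbouring loci can
  never interact — this is what makes anchor-failure outcomes exact;
* peaks: 2000, widths Normal(500, 150) truncated at 50 bp (histone
  ChIP-seq scale; a GRO-seq-like narrower law is a parameter choice away);
  `enrichment_fraction` of them planted uniformly *inside* haplotypes, the
  rest uniform on the genome;
* TADs: one per haplotype, extended by independent uniform 50–200 kb
  margins, 400 bp CTCF peaks centred on each boundary except the
  deliberately failed ones;
* genes: 400, half planted inside TADs; expressed genes get
  TPM = 1 + lognormal, the rest TPM < 1, so the expression filter
  separates them exactly and the generator's bookkeeping is exact truth.

Every generator records ground truth (planted peak counts and background
spillover, expected retained-TAD count, per-TAD post-filter gene counts),
computed by direct comparison independent of the sweep engine, and the
pipeline's outputs are required to match it exactly.

**What the generator does not emulate:** the non-uniform distribution of
genes and regulatory elements along real chromosomes, GC/mappability
structure, assembly gaps, peak-width/signal correlation, and correlated
peak sets across marks. Passing calibration here shows the statistic is
correct *under its own null*; on real data the uniform-background null is
a modelling assumption, which is exactly why the reference procedure
repeats the randomization 1000 times rather than deriving a closed form.

## Calibration evidence (computed by the test suite)

* Type-I error: over 200 independent null-mode datasets (no planted
  enrichment), 200 replicates each, the rejection count at α = 0.05 must
  fall inside the exact binomial 99% interval around 0.05.
* Power: the median p over seeded datasets is non-increasing in the
  planted enrichment fraction (0, 0.25, 0.5, 0.75).
* Agreement: the normal-approximation p is within a factor of 3 of the
  empirical permutation p whenever both are ≥ 10⁻³ (1000 replicates).
* Determinism: identical configuration + seed gives byte-identical
  outputs, verified by md5 manifest comparison of two runs.

These problem sizes (200 × 200, 8 datasets per fraction) keep the whole
suite around a minute while leaving the binomial check sensitive enough to
catch a mis-sided test or a wrong variance estimate.

## Known limitations

* The uniform random-region null ignores genome structure (see above); a
  GC- or gap-aware null is out of scope by design.
* Published p-values for the real datasets are not reproduced here: the
  underlying ChIP-seq/GRO-seq peak files are external downloads, and the
  pipeline treats peak calls as inputs.
* No multiple-testing correction is applied across peak sets (none is in
  the reference procedure).
* LD-block derivation, liftover, Hi-C loop calling, GO enrichment and
  eQTL lookup are all external; the package consumes or emits their
  tables.
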