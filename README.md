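# haplotad

Chromatin-architecture analysis of disease risk haplotypes: a
random-region enrichment test for regulatory-element peaks over
GWAS-derived linkage-disequilibrium (LD) blocks, CTCF-anchor validation of
candidate topologically associating domains (TADs), and nomination of
expressed candidate target genes within the retained TADs.

The package was built around the juvenile idiopathic arthritis (JIA) risk
haplotypes — 36 LD blocks (r² ≥ 0.80, hg38) tagged by GWAS SNPs — and
ships those published tables as machine-readable fixtures, but every
operation takes generic BED/TSV inputs, so any set of risk regions and
peak calls (histone ChIP-seq, GRO-seq enhancer calls, CTCF ChIP-seq) can
be analysed the same way.

## The statistic

For a peak set and *n* risk haplotypes, let *k*obs be their overlap count
(peak × region intersection events by default, or regions-with-≥1-peak).
The null drops *n*r random regions of fixed length *L* uniformly on the
genome (*n*r = 36, *L* = 86,676 bp — the mean haplotype length — by
default), counts overlap with the peaks, and repeats *R* = 1000 times.
With replicate mean μ̂ and n−1 SD σ̂:

```
z = (k_obs − μ̂) / σ̂ ,   p = 1 − Φ(z)    (one-sided, enrichment)
```

A rank-based `empirical_p()` is the documented fallback when the null is
degenerate or the normal fit is in doubt. Downstream, candidate TADs are
retained only if both boundaries carry a CTCF peak within a ±25 kb window,
and candidate target genes are the protein-coding genes overlapping a
retained TAD with TPM ≥ 1.

## Worked example

The packaged tables alone reproduce every published tally:

```r
library(haplotad)
mean_region_length(jia_haplotypes())
#> [1] 86676
str(count_mark_classes(jia_marks()))
#> List of 6
#>  $ both                : int 22
#>  $ k4me1_only          : int 7
#>  $ neither             : int 7
#>  $ gro_resting         : int 11
#>  $ gro_activated       : int 16
#>  $ gained_on_activation: int 5
```

22 LD blocks carry both enhancer marks, 7 carry H3K4me1 alone (so 29
qualify for TAD analysis), 7 carry neither; 11 and 16 blocks have GRO-seq
peaks in resting and activated macrophages, with 5 gained on activation.

A full pipeline run on a synthetic bundle with 25% of peaks planted inside
the haplotypes and a deliberate CTCF-anchor failure at PTPN22:

```r
cfg <- sim_config(enrichment_fraction = 0.25,
                  anchor_fail_loci = "PTPN22", seed = 11)
d <- simulate_bundle(cfg, "bundle")
res <- run_pipeline(pipeline_config(
  chrom_sizes = d$chrom_sizes, haplotypes = d$haplotypes,
  peaks = c(H3K4me1_like = d$peaks), tads = d$tads, ctcf = d$ctcf,
  genes = d$genes, expression = d$expression,
  out_dir = "out", seed = 2))
#> [enrich] H3K4me1_like: k_obs=519, p=1e-300
#> [annotate] annotated 36 haplotypes with 1 peak set(s)
#> [qualify] 36/36 loci qualified on H3K4me1_like
#> [tads] 35/36 candidate TADs retained
#> [genes] 93 expressed target gene(s)
#> [report] wrote 7 output file(s) to out
res$enrichment
#>          label k_obs mu_hat sigma_hat       z p_value significant
#> 1 H3K4me1_like   519 41.964  12.00528 39.7355  1e-300        TRUE
```

The observed 519 overlap events against a null of ≈ 42 ± 12 reflect the
planted enrichment; the PTPN22 TAD is the single one excluded (35/36
retained), and the 93 surviving genes match the generator's truth record
exactly. Outputs land in `out/` as TSVs plus `manifest.json` (config
hash, seed, md5 of every file): re-running with the same configuration and
seed reproduces identical hashes.

A thin command-line wrapper (`inst/scripts/haplotad.R`) exposes
`simulate`, `run` and `fixtures` subcommands over the same functions.

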