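---
title: "Measuring the onset of embryonic dosage compensation from single-embryo allele-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the onset of embryonic dosage compensation from single-embryo allele-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryocomp)
```

## The problem

In *Drosophila*-type XY systems, males carry one X chromosome against the
female's two. Somatic dosage compensation — MSL-complex-mediated
hypertranscription of the single male X — is established only some hours
into embryogenesis, well after the maternal-to-zygotic transition (MZT).
The window between zygotic genome activation and MSL establishment is
therefore a natural experiment in uncompensated (or partially compensated)
X dose, and species carrying younger sex chromosomes — an XR arm recruited
to the X tens of millions of years ago, or a neo-X/neo-Y pair formed about
a million years ago whose neo-Y still transcribes roughly half its genes —
let one ask how compensation tracks the evolutionary age of a chromosome.

The measurement design this package supports is a timecourse of
single-embryo mRNA-seq across eight morphologically staged timepoints
(morphological stages 2, 4, mid-5, late-5, 7, 8/9, 10 and 12, stored as
ordinals 1–8), with replicate female and male embryos at each stage. All
embryos are F1 hybrids between two sequenced parental lines, so reads
overlapping fixed SNPs can be assigned to the maternal or the paternal
allele. Two facts make the allele dimension powerful:

* maternally deposited transcript is identical between the sexes and
  carries only maternal alleles, while zygotic transcription of a
  biallelic autosomal gene is split evenly between alleles — so the
  paternal read fraction `p` of a gene estimates half its zygotic
  transcript share, and `z = min(2p, 1)` estimates the share itself;
* the male X is entirely maternally inherited, so the maternal allele is
  the one quantity directly comparable between a male's single X and each
  of the female's two Xs.

## The analysis pipeline

**Normalization.** Each sample is rescaled so that the summed RPKM of
reference autosomes (chromosomes 2 and 4, autosomal in every karyotype
considered) is constant (`normalize_autosomal()`). Scaling to all
autosomes or skipping rescaling are provided as alternatives; X:autosome
contrasts are insensitive to the choice.

**Allele aggregation.** Maternal and paternal reads are summed over a
gene's SNPs and divided by the number of SNPs observed with reads
(`allele_fractions()`). Genes without observed SNPs are absent, not zero:
missing allele information is never conflated with absent transcription.

**Zygotic classification.** Two definitions are implemented
(`call_allele_specific()`, `call_transcript_level()`):

1. *allele-specific*: per stage and species, mean female RPKM strictly
   above 5 and female paternal fraction strictly above 40%. Stage-specific,
   so genes transitioning from maternal to zygotic supply are picked up as
   they transition; used for all total-transcript-level analyses.
2. *transcript-level*: below 5 RPKM at the first stage (no maternal
   deposition) and above 5 RPKM at a later stage. Per gene and
   allele-free, which makes it the right conditioning set for
   allele-specific quantities — classifying genes by their paternal
   fraction and then measuring allele levels on the same genes would be
   circular.

Thresholds are applied as strict inequalities. Replicates are averaged
before thresholding (a per-embryo majority vote is available as an
option, since the choice between stage-pooled and per-embryo gating is
genuinely open; on simulated data the two agree closely).

**Sex-bias statistics.** Female:male ratios of sex-mean RPKM are computed
per gene for genes above 5 RPKM in both sexes (`fm_ratio()`), classified
into bias bins split at 0.8, 1.25, 1.5 and 2 (`bias_class()`; only the
1.5 and 2 cut points carry analysis weight, and all are configurable),
compared between groups by 2×2 chi-squared tests over a 1.5–2.0 cutoff
grid (`chisq_cutoff_scan()`, df = 1, no continuity correction by default,
unadjusted p-values as primary with a Benjamini–Hochberg column added),
and by two-sided Wilcoxon rank-sum tests (`wilcoxon_compare()`, exact
enumeration when both groups have ≤ 10 untied values, tie-corrected
normal approximation otherwise).

**Onset of compensation.** `maternal_allele_onset()` compares the
per-gene mean maternal-allele level (per-SNP reads scaled by the sample's
normalization factor) between males and females, per stage and chromosome
class, over transcript-level zygotic genes. Uncertainty comes from a
gene-resampling bootstrap (genes, not embryos, are the resampling unit;
1000 resamples by default; empirical 2.5%/97.5% quantiles). A cell is
significant when the male mean exceeds the female upper quantile — a
one-sided criterion by construction, with no additional p-value invented —
and the onset stage of a class is its earliest significant cell. Because
male and female levels are computed over the same genes, gene-level
variance cancels from the male–female contrast while still driving the CI
width; the procedure is therefore conservative under the null, which the
calibration tests confirm (per-cell false-flag rates well below 5%).
Cells where either sex has fewer than 10 genes with reads are reported
but never flagged: a bootstrap over a handful of values is degenerate and
its quantiles meaningless.

**Neo-sex chromosomes.** On the neo-X/neo-Y pair, male reads split by
neo-divergence SNPs into the maternally inherited neo-X and the paternally
inherited neo-Y (`partition_neo_alleles()`); genes without neo-divergence
SNPs stay in combined neo-XY totals. `orf_stratified_bias()` contrasts
genes whose neo-Y copy retains an intact open reading frame against
functionally hemizygous broken-ORF genes, in combined and neo-X-only
modes, with per-stage Wilcoxon tests between strata and against XL/XR.

**Space and chromatin.** `clustering_test()` asks whether compensated (or
uncompensated) genes sit closer together than expected, using the mean
nearest-neighbour distance and a null of equally sized gene sets drawn
without replacement — from the zygotic genes of that stage, because
zygotic genes are themselves clustered and an all-gene null would confound
zygotic clustering with compensation clustering (both universes are
supported precisely to expose that contrast). Empirical p-values use the
add-one convention, so the smallest attainable p is `1/(n_reps + 1)`.
`has_proximity_test()` compares female:male ratios between the quartile of
genes nearest a high-affinity-site interval (distance from gene start,
zero inside an interval, ties joining the lower quartile, pooled over
chromosomes by default) and the remaining three quartiles.
`h4k16ac_compare()` contrasts mean per-gene H4K16ac enrichment between
compensated (< 1.5× female-biased among genes above 5 RPKM in both sexes)
and uncompensated genes with bootstrap CIs, flagging exclusion in either
direction.

## The synthetic-data generator

`simulate_experiment()` produces expression, allele counts, sample sheet,
annotation and full ground truth for one of three karyotype profiles
(`default_config()`): `pse_like` (XL + XR, chromosome 3 autosomal),
`mir_like` (additionally a neo-X/neo-Y with half the neo-Y ORFs broken and
a one-stage developmental delay) and `mel_like` (a single ancestral X,
modelling the early-zygotic regime in which about half of zygotic X genes
are fully compensated per gene).

The generative model per gene: a maternal level (lognormal, meanlog
`log(20)` RPKM, sdlog 1, deposited in 70% of genes) decays geometrically
(0.7 retained per stage) after the MZT; a zygotic per-copy rate (same
lognormal) switches on at an onset stage drawn mostly at mid-stage-5
(distribution `c(0, .05, .55, .20, .10, .10, 0, 0)` over ordinals, shifted
by the species delay) in 50% of genes. Male X output is the per-copy rate
times a compensation factor — a non-decreasing stage trajectory rising
from 1 to 2 with onset at ordinal 5 (`pse_like`) or 6 (`mir_like`), or a
per-gene factor of 2 with probability ½ (`mel_like`). Male neo-XY output
adds a neo-Y copy at a per-gene retention level (Beta(1.2, 1.8), drawn
independently of ORF status, since transcription and coding integrity
decay independently). Counts are negative binomial around the expected
RPKM (size 20; single-embryo libraries of this design are highly
reproducible, with replicate rank correlations above 0.95, so technical
overdispersion is modest), with RPKM recovered from counts at a fixed
1 kb gene length so the count–RPKM mapping stays transparent. SNP reads
track realized RPKM, scaled so a typical two-copy zygotic gene receives
200 SNP-overlapping reads, and split binomially by the transcript pool's
true allele composition; 92%/75% of genes carry informative line SNPs in
the `pse_like`/`mir_like` profiles and 68% of neo genes carry
neo-divergence SNPs. The number of SNPs observed is the rounded expected
occupancy of the gene's SNP sites under the drawn read total — an
analytic shortcut that keeps hundreds of replicate simulations cheap
without affecting any downstream quantity, which depends on summed reads.

What the generator does *not* emulate: mapping bias between alleles,
amplification artefacts, gene-length variation, correlated expression
programs between genes, and partial-stage asynchrony within an embryo.
Passing recovery tests therefore demonstrates the pipeline's correctness
and calibration under the design's statistical structure, not robustness
to every artefact of real libraries.

## Numerical and design choices

* `z = min(2p, 1)`: the doubled paternal fraction can exceed 1 under
  sampling noise; a transcript share is clipped to the unit interval.
  The clipping makes the estimator slightly conservative near `z = 1`
  (about 0.03 at 200-read depth), and unbiased away from the boundary.
* Paternal fractions are computed per embryo and then averaged across
  replicates, keeping the embryo as the biological unit; doubling a
  pooled fraction instead is available via the same building blocks.
* Bootstrap quantiles use R's default type-7 interpolation; with 1000
  resamples the quantile granularity is far below every effect size of
  interest.
* Degenerate inputs: a single-value bootstrap returns a zero-width CI;
  identical groups give Wilcoxon p = 1; empty chi-squared margins return
  a zero statistic; constant vectors yield `NA` correlations.
* Ties at the distance quartile boundary join the lower (near) group;
  gene position is the start coordinate, with midpoint as an option.
* Chromosome 3 carries ORF annotations only where it is a neo-sex
  chromosome; in the older karyotype it is an ordinary autosome and its
  genes carry `not_applicable`.

## Problem sizes used in validation

The packaged tests and the acceptance script validate against simulations
sized to balance precision and runtime: the dose-ratio recovery runs use
six replicate simulations of 1000–1040-gene X complements (standard error
of the reported mean ratio ≈ 0.02); onset-detection accuracy uses 100
simulations with 400 X-linked genes and a compensation step at ordinal
stage 6, and calibration uses 200 matched null simulations; bootstrap
coverage uses 1000 standard-normal samples of size 100; clustering-p
uniformity uses 400 random label draws against a 200-gene universe.

A note on the recovered dose ratios: with maternal co-deposition in the
generator, genes passing the 40%-paternal gate may retain up to roughly a
fifth maternal transcript, which depresses the uncompensated X ratio from
the idealized 2.0 to about 1.95 and the half-compensated mean from 1.5 to
about 1.47 — the same direction and magnitude of shrinkage that real
embryo timecourses show against the idealized two-fold expectation.

## Limitations

The pipeline consumes per-gene allele counts and RPKM tables; read-level
processing (alignment, SNP calling, allele assignment of individual
reads) is upstream and out of scope, as are ChIP-seq processing for
high-affinity sites and H4K16ac enrichment (consumed as given) and any
mechanistic model of MSL spreading. Between-species comparisons assume an
orthology map and morphologically matched stages; the
`stage_correspondence()` bootstrap checks the latter assumption rather
than guaranteeing it.
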