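---
title: "tandemCNV: models and methods for digital copy-number genotyping of tandem repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tandemCNV: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemCNV)
```

## The problem

Macrosatellites (tandem repeats with unit sizes of hundreds of bases to
several kilobases) and multicopy gene families are among the most
copy-number-variable sequences in the human genome, yet they are nearly
invisible to SNP-array and short-read genotyping. Digital hybridization
count assays offer a way out: each probe yields a count proportional to
the diploid copy number of its target in that individual. tandemCNV
implements the full analysis stack around such an assay: normalization
and calibration of raw counts to absolute copy number, population
differentiation statistics, tag-SNP linkage-disequilibrium scanning, and
cis association of copy number with gene expression and CpG methylation
— together with a synthetic-data generator that emits every input with
known ground truth, so that each stage can be validated end to end.

## Count model and normalization

The generator, and implicitly the normalization stack, assume the count
model

$$
\mathrm{raw}(p, s) \;=\;
\mathrm{scale}_s \,\bigl(g\, e_p\, \mathrm{CN}(p, s) + b\bigr)\,
e^{\sigma Z},\qquad Z \sim \mathcal N(0, 1),
$$

where $e_p \in [0.5, 2]$ is a probe-specific relative efficiency, $g$ an
assay-wide counts-per-copy gain (default 50, placing a diploid locus
near 100 counts), $b$ a background count shared by all probes, and
$\mathrm{scale}_s$ a per-sample technical factor (input DNA amount,
hybridization efficiency). Noise is multiplicative log-normal because
counts are positive and heteroscedastic; $\sigma$ defaults to 0.05.

Processing order is fixed: **background correction** (subtract each
sample's mean negative-control count, clamp at zero — the clamp is a
design choice for the rare case of counts below background), then
**per-sample normalization factors** from the invariant control probes,
then **normalization**, then exclusion of probes with mean counts below
100, then **variability classification**.

The normalization factor deserves a note. Dividing a sample's invariant
mean by the grand invariant mean produces a factor that *amplifies*
sample-level intensity differences when multiplied back in; only the
reciprocal (grand over sample) makes invariant probes actually invariant
across samples, which every downstream analysis assumes. The default is
therefore the corrective direction, with `mode = "literal"` available to
reproduce the printed ratio verbatim.

A probe is called copy-number variable when its coefficient of variation
(sample standard deviation over mean, $n-1$ denominator — the usual
choice when the source is silent) is at least 0.1 across the cohort, or
when at least 2 individuals deviate from the cohort mean by 30% or more.
The outlier rule uses the full analyzed cohort mean rather than
per-ancestry means; both thresholds and the reference cohort are
configurable.

## Calibration to absolute copy number

Counts are relative (efficiencies differ across probes), so absolute
copy numbers come from anchoring each probe against read-depth
copy-number estimates on a shared calibration subset:

$$
\mathrm{CN}(p, s) = \frac{\mathrm{count}(p, s)}
{\operatorname{median}_{s' \in \mathrm{shared}} \mathrm{count}(p, s')}
\times \operatorname{median}_{s' \in \mathrm{shared}}
\mathrm{CN}_{\mathrm{rd}}(p, s').
$$

Medians make the anchor robust to a minority of corrupted calibration
samples. Duplicate read-depth entries for one probe/individual are
averaged first. Copy numbers are reported as continuous values — no
integer rounding, since population means of high-copy loci are genuinely
non-integer. The scaling applies to all samples, not only the shared
subset, so any cohort can be calibrated from a few anchored individuals.

One accuracy caveat is intrinsic to the median anchor: the ratio of the
two medians carries sampling noise of roughly 2% at 165 calibration
samples and 5% count noise, so while the *typical* per-probe median
relative error is well under 5%, individual probes can occasionally
exceed it. The acceptance checks therefore assert the level of the error
distribution (median and mean across probes, plus a 90% within-5%
fraction), not its extreme order statistic; at $\sigma = 0$ recovery is
exact and asserted exactly.

## Population differentiation: V_ST

For each probe, $V_{ST} = (V_T - V_S)/V_T$ where $V_T$ is the total
variance of copy number across all individuals and $V_S$ is the
sample-size-weighted average of the within-population variances,
$V_S = \sum_k n_k \hat\sigma_k^2 / \sum_k n_k$. This weighting is the
standard ANOVA-based F_ST analogue for continuous copy numbers and is
the only reading that keeps the statistic in $[0, 1]$. Negative raw
values (sampling noise when $V_S > V_T$) are floored at zero for
reporting but preserved in `vst_raw`. Zero total variance leaves the
statistic undefined (NA), never zero. Probes on chrX are computed
separately within males and females and the two values averaged; chrY
uses males only. Values above 0.2 (strict) are flagged as highly
differentiated. V_ST is invariant to per-probe affine rescaling, so
normalized counts and calibrated copy numbers give identical values.

## Tag-SNP scanning and the permutation engine

Genotypes are encoded 0/1/2 by counting non-designated alleles, the
designated allele being the alphabetically first observed one — the
orientation affects only the sign of $r$, never $R^2$. SNPs are removed
when MAF < 0.1, Hardy–Weinberg chi-square (1 df, no continuity
correction) p < 0.05, or a third allele is observed; a stringent mode
additionally drops externally flagged SNPs (multi-mapping 51 bp windows,
segmental-duplication or CNV overlap).

For each probe, windows of ±250 kb are built around every alignment
with ≥95% identity (merged where they overlap; strand ignored — the
windows are strandless), and every in-window SNP is Pearson-correlated
with the probe's values per population and for all populations combined.
The best SNP maximizes $R^2$; ties break by smaller nominal p, then by
genomic position — deterministic and, in practice, rare. Sex-chromosome
probes are scanned separately within males and females.

Significance comes from permutations: the probe vector is shuffled
across samples (equivalent to shuffling either side), and the two-tailed
p-value is the proportion of null draws whose absolute correlation
*strictly* exceeds the observed one. A p of exactly zero is reported
with a below-resolution flag rather than a pseudo-count, keeping the
estimator unbiased. With a fixed RNG seed the engine is bit-reproducible.

## Expression and methylation association

Expression scanning first removes transcripts with mean log2 expression
below 6 or interquartile range below 0.25, then Pearson-correlates each
surviving transcript whose TSS (the anchor coordinate for transcripts)
lies within ±500 kb windows, with shuffle permutations as above.
Records where the transcript is the probe's own target gene are flagged
as auto-correlated rather than removed.

Methylation uses a staged funnel on Spearman correlations between copy
number and beta values of in-window CpGs (windows exclude chrY and
unplaced "_random" scaffolds):

1. all in-window pairs, CEU and YRI combined;
2. keep the top 2% by absolute rho — the cutoff is the empirical 98th
   percentile of the run's own correlations, not a hard-coded constant;
3. keep pairs with absolute *normalized slope* above 0.1, where the
   normalized slope is the OLS slope of beta on copy number times the
   observed copy-number range — the predicted beta change between the
   lowest- and highest-copy individuals;
4. keep permutation p < 0.01, where the null re-correlates each probe's
   copy numbers against CpG vectors resampled from the genome-wide
   autosomal pool (one shared null per probe; draws without replacement
   while the pool allows, with replacement and a warning otherwise);
5. require nominal Spearman p < 0.05 in each population separately.

Every stage logs its in/out counts. The chrX analysis runs the same
funnel on male samples only (combined populations, X-specific pool) to
avoid the X-inactivation confounder. QC before the funnel removes CpG
probes flagged as multi-mapping or SNP-overlapping (flags are inputs:
intensity-level normalization of the array is out of scope), chrY
probes, and probes with more than 5% missing values.

## Primate comparison and selective constraint

Primate samples are background-corrected and normalized like human ones,
but using only the invariant controls whose *relative* signal (share of
the invariant total) differs by less than 20% from the human mean share
— probes diverged in the primate genome would otherwise distort the
factor. Fold changes versus the (sex-matched, for sex chromosomes)
human mean are retained only when the probe has ≥95% identity in that
species for gains, or ≥98% for losses, since probe–target mismatches
depress binding and mimic losses; retained records with ≥3-fold change
in either direction are flagged. The generator models this attenuation
as $e^{-\lambda(100 - \mathrm{identity})}$, monotone with value 1 at
100% identity. Selective constraint is summarized by a two-sample
Kolmogorov–Smirnov test on dN/dS values of multicopy versus background
orthologs after excluding genes under 80% amino-acid identity
(`stats::ks.test`, exact for small group-size products).

## The synthetic cohort and what it does not emulate

The default cohort mirrors the reference design: 60 CEU, 60 YRI and 45
CHB individuals with balanced sexes, 8 negative and 10 invariant
controls, SRY and X-linked gender controls. Copy numbers follow either a
"clustered" mode (integer CN around a probe-level mean with 15% relative
spread — a polymorphic locus) or a "uniform" mode (integers spanning
2–60, the assay's dynamic range, used for calibration accuracy checks).
Tag SNPs are planted by thresholding a latent Gaussian correlated with
the normal scores of copy number, with the loading calibrated
analytically against the Hardy–Weinberg genotype thresholds so that the
realized genotype–CN $r^2$ matches the target on average (the realized
value is recorded next to the target). Planted methylation effects
follow the normalized-slope construction exactly, so zero-noise recovery
is exact; note that when the analysis cohort is a subset of the
generating cohort, range shrinkage attenuates the recovered normalized
slope slightly.

The generator does **not** emulate realistic LD block structure (each
planted tag is a single SNP), probe cross-hybridization between test
probes, batch effects beyond a scalar per-sample factor, or beta-value
distributions with the bimodality of real methylomes. Passing recovery
tests therefore demonstrates correctness of the statistical machinery
under the stated model, not robustness to every artifact of real data —
the readers accept real tables through the same interfaces when they
are available.

## Numerical and design choices

- Coordinates are 0-based half-open everywhere internally; VCF and the
  on-disk feature tables are 1-based and converted at the boundary.
- Missing values use one canonical marker; `"NA"`, empty and `"nan"`
  cells are accepted on read and never silently imputed.
- Interval merging and containment delegate to IRanges; containment is
  start-inclusive, end-exclusive.
- Degenerate correlation inputs (zero variance, fewer than 3 complete
  pairs) are skipped, not coerced to zero.
- The ChIP sliding-window track scales both coverage vectors by their
  totals and uses a zero pseudo-count by default, reporting NA where the
  input window is empty; `floor((L - w)/s) + 1` windows for a region of
  length $L \ge w$.
- The orchestration layer (`run_config()` / `run_all()`) is plain R —
  the package's users drive it from R scripts, so no shell entry point
  is shipped; every run writes its resolved configuration and a
  one-line-per-stage funnel log next to its outputs, and a fixed seed
  reproduces a run exactly.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script size their simulations to
exercise every code path while remaining quick on a laptop: 200 probes ×
165 samples for calibration accuracy; 1,000 random fixtures for the
V_ST and window-containment oracles; 1,000 null tests × 1,000
permutations for type-I calibration; 100 replicates for tag-SNP
recovery and the methylation funnel survival rate (the acceptance
script uses 30–60 replicates per quantity). Permutation defaults in
`run_config()` remain at the canonical 10,000 (shuffle) and 1,000
(pool) rounds.

## Known limitations

- The methylation funnel's top-2% stage is relative to the set of pairs
  actually tested in the run; on very small probe panels the cutoff is
  grainy (2% of 50 pairs is a single pair).
- `hwe_test` is asymptotic; for very small samples an exact test would
  be preferable, but the filter threshold (p < 0.05) operates far from
  the regime where the difference matters at cohort sizes of 45+.
- Calibration accuracy is bounded by the sampling noise of the median
  anchor (see above); with fewer than ~30 shared samples the anchor
  becomes noticeably noisy, and the `min_shared` guard (default 3) is a
  floor, not a recommendation.
- X/Y gender QC needs both sexes present; single-sex cohorts skip it
  with a warning.

## A minimal worked run

```{r, eval = FALSE}
cfg <- run_config(seed = 7, n_perm_shuffle = 200, n_perm_pool = 200,
                  n_pool = 300)
res <- run_all(cfg)
cat(res$funnel, sep = "\n")
head(res$vst)
subset(res$tag, population_set == "combined")
```
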