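# tandemCNV

Digital copy-number genotyping of multicopy genes and macrosatellite
repeats: an R analysis pipeline for multiplexed hybridization count
assays, from raw probe counts to absolute copy numbers, population
genetics and functional association.

Large tandem repeats and multicopy gene families (beta-defensins,
GSTM1, macrosatellites such as D4Z4-like arrays) are highly
copy-number polymorphic but poorly tagged by SNPs, making them
effectively invisible to standard GWAS. Digital count assays measure
them directly: each probe returns a count proportional to the diploid
copy number of its target. tandemCNV implements the analysis around
such an assay for anyone running (or simulating) one:

- **Counts**: background correction against negative-control probes,
  per-sample normalization from invariant-control probes, low-count
  exclusion, and variability classification (CV ≥ 0.1, or ≥ 30%
  deviation in ≥ 2 individuals), plus SRY/X-linked gender QC.
- **Calibration**: conversion of relative counts to absolute diploid
  copy number against read-depth anchors,
  `CN(p,s) = count(p,s) / median(count) × median(CN_readdepth)` over a
  shared calibration subset.
- **Population differentiation**: ANOVA-based
  `V_ST = (V_total − V_within)/V_total` with sample-size-weighted
  within-population variances, sex-stratified on chrX/chrY, flagging
  V_ST > 0.2.
- **Tag-SNP LD scan**: best Pearson R² between 0/1/2 genotype dosages
  and copy number within ±250 kb of each ≥95%-identity probe alignment,
  per population and combined, with shuffle-permutation p-values
  (MAF/HWE/tri-allelic filters, optional stringent flag filters).
- **cis association**: expression (±500 kb of the TSS, transcript
  filters, Pearson + permutations) and methylation (a five-stage
  Spearman funnel with a top-2% cutoff, normalized-slope > 0.1 filter,
  genome-wide resampling null, and per-population replication).
- **Primate comparison**: species-specific invariant-control
  renormalization, identity-thresholded retention (≥95% for gains,
  ≥98% for losses), ≥3-fold flagging; dN/dS distribution comparison by
  Kolmogorov–Smirnov test.
- **Synthetic data**: generators for every input with planted effects
  (probe efficiencies, sample scale factors, tag SNPs of chosen r²,
  expression slopes, methylation normalized slopes, primate
  identity attenuation) and ground truth recorded for recovery tests.

## Worked example

A deterministic end-to-end run on a small simulated cohort (165
individuals: 60 CEU, 60 YRI, 45 CHB; 12 probes; one planted tag SNP of
target r² 0.5, one planted expression effect, one planted methylation
effect on probe T001):

```r
library(tandemCNV)
res <- run_all(run_config(seed = 7, n_perm_shuffle = 200,
                          n_perm_pool = 200, n_pool = 300))
cat(res$funnel, sep = "\n")
#> simulate  probes=12 samples=165 snps=360
#> normalize probes_in=12 probes_after_low_count=12 probes_variable=12
#> calibrate calibrated=12 uncalibrated=0
#> vst       probes=12 differentiated=0
#> filter_snps input=360 tri_allelic=0 low_maf=8 hwe_fail=14 output=338
#> tag_snp_scan records=48
#> expression_scan records=384
#> methylation_pipeline stage1_tested=240 stage2_top_rho=5 stage3_slope=1
#>   stage4_perm=1 stage5_replicated=1
```

The funnel log shows 22 of 360 simulated SNPs removed by the MAF and
HWE filters, and the methylation funnel narrowing 240 tested
probe–CpG pairs to exactly the single planted effect. The planted tag
SNP is recovered as the best in-window marker:

```r
subset(res$tag, probe_id == "T001" & population_set == "combined")
#>  probe_id  feature_id        r2 p_perm   n
#>      T001 rs_T001_015 0.4156466      0 165
```

an R² of 0.42 against the planted target of 0.5 (p below the 1/200
permutation resolution), and the planted CpG survives all five
methylation filter stages with a strong positive correlation:

```r
res$methylation$records[, c("feature_id", "r", "normalized_slope", "p_perm")]
#>   feature_id         r normalized_slope p_perm
#>  cg_T001_014 0.8380096        0.2549439      0
```

The normalized slope of 0.25 is the predicted beta-value change
between the lowest- and highest-copy individuals (planted: 0.3,
attenuated by the CEU+YRI subset's narrower copy-number range). The
`vst` table gives each probe's population differentiation; in this
unshifted simulation all values sit near 0, and none exceeds the 0.2
flagging threshold.

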