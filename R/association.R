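# Tag-SNP LD scanning, cis expression correlation, staged cis methylation
# association, the shared permutation engine, and the ChIP sliding-window
# enrichment utility.

#' Encode allele-pair genotype calls as 0/1/2 dosages
#'
#' The designated allele is the alphabetically first observed allele; its
#' homozygote maps to 0, the heterozygote to 1, the other homozygote to 2
#' (the code counts non-designated alleles). Orientation only flips the
#' sign of downstream correlations, never R-squared. Missing calls stay NA.
#'
#' @param calls Character vector of allele pairs ("AA", "AG", ...) for one
#'   SNP.
#' @return Integer vector of codes with attribute `designated_allele`.
#' @export
encode_genotypes <- function(calls) {
  obs <- calls[!is.na(calls)]
  alleles <- sort(unique(unlist(strsplit(obs, ""))))
  if (length(alleles) > 2L)
    stop("more than two alleles after QC: ", paste(alleles, collapse = ","))
  codes <- rep(NA_integer_, length(calls))
  if (length(alleles)) {
    designated <- alleles[1L]
    codes[!is.na(calls)] <- vapply(strsplit(obs, ""), function(a)
      sum(a != designated), integer(1L))
  } else designated <- NA_character_
  attr(codes, "designated_allele") <- designated
  codes
}

#' Add a 0/1/2 dosage matrix to a SNP panel
#'
#' Tri-allelic SNPs get all-NA codes (they are removed by [filter_snps()]).
#'
#' @param panel `snp_panel`.
#' @return The panel with a `codes` integer matrix added.
#' @export
encode_panel <- function(panel) {
  codes <- matrix(NA_integer_, nrow(panel$calls), ncol(panel$calls),
                  dimnames = dimnames(panel$calls))
  for (i in seq_len(nrow(panel$calls)))
    if (!panel$snps$tri_allelic[i])
      codes[i, ] <- encode_genotypes(panel$calls[i, ])
  panel$codes <- codes
  panel
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' Chi-square with 1 degree of freedom against expected genotype counts
#' from the observed allele frequencies, no continuity correction.
#' Monomorphic sites return p = 1.
#'
#' @param n_AA,n_AB,n_BB Observed genotype counts.
#' @return p-value.
#' @export
hwe_test <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  if (n <= 0L) stop("no genotypes")
  p <- (2 * n_AA + n_AB) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((c(n_AA, n_AB, n_BB) - expd)^2 / expd)
  stats::pchisq(chisq, df = 1L, lower.tail = FALSE)
}

#' Filter a SNP panel for the LD analysis
#'
#' The basic filter removes SNPs with minor allele frequency below
#' `maf_min`, Hardy-Weinberg p below `hwe_alpha`, or a tri-allelic state.
#' The stringent mode additionally removes SNPs flagged as multi-mapping
#' (51 bp window), inside segmental duplications, or inside known CNV
#' regions (flags are inputs).
#'
#' @param panel Encoded `snp_panel` (see [encode_panel()]).
#' @param maf_min MAF threshold (strict <, default 0.1).
#' @param hwe_alpha HWE p threshold (strict <, default 0.05).
#' @param stringent Apply the flag-based filters too.
#' @return Filtered panel with attribute `funnel` (per-rule removal counts).
#' @export
filter_snps <- function(panel, maf_min = 0.1, hwe_alpha = 0.05,
                        stringent = FALSE) {
  if (is.null(panel$codes)) panel <- encode_panel(panel)
  n_snp <- nrow(panel$snps)
  maf <- apply(panel$codes, 1L, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    f <- mean(g) / 2
    min(f, 1 - f)
  })
  hwe_p <- apply(panel$codes, 1L, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  })
  panel$snps$maf <- maf
  panel$snps$hwe_p <- hwe_p
  drop_tri <- panel$snps$tri_allelic
  drop_maf <- !drop_tri & (is.na(maf) | maf < maf_min)
  drop_hwe <- !drop_tri & !drop_maf & !is.na(hwe_p) & hwe_p < hwe_alpha
  drop <- drop_tri | drop_maf | drop_hwe
  funnel <- c(input = n_snp, tri_allelic = sum(drop_tri),
              low_maf = sum(drop_maf), hwe_fail = sum(drop_hwe))
  if (stringent) {
    drop_flag <- !drop & (panel$snps$multi_mapped_51bp |
                            panel$snps$in_segdup | panel$snps$in_cnv)
    funnel <- c(funnel, flagged = sum(drop_flag))
    drop <- drop | drop_flag
  }
  keep <- which(!drop)
  out <- panel
  out$snps <- panel$snps[keep, , drop = FALSE]
  out$calls <- panel$calls[keep, , drop = FALSE]
  out$codes <- panel$codes[keep, , drop = FALSE]
  attr(out, "funnel") <- c(funnel, output = length(keep))
  out
}

#' Correlate a probe's values with one feature
#'
#' Pairwise complete observations; Pearson r (with p from the exact
#' t-reference) or Spearman rho (average ranks for ties, p from the
#' t-approximation). The slope is the ordinary least-squares regression of
#' the feature on the probe value.
#'
#' @param probe_values,feature_values Numeric vectors of equal length.
#' @param method "pearson" or "spearman".
#' @param min_n Minimum complete pairs (default 3).
#' @return list(r, r2, p_nominal, slope, n); degenerate input (zero
#'   variance on either side, or too few complete pairs) returns NULL and
#'   the pair is skipped by callers.
#' @export
correlate <- function(probe_values, feature_values,
                      method = c("pearson", "spearman"), min_n = 3L) {
  method <- match.arg(method)
  ok <- !is.na(probe_values) & !is.na(feature_values)
  x <- as.numeric(probe_values[ok]); y <- as.numeric(feature_values[ok])
  n <- length(x)
  fail <- function(reason) invisible(NULL)
  if (n < min_n) return(fail("too few complete pairs"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(fail("degenerate"))
  slope <- stats::cov(y, x) / stats::var(x)
  if (method == "pearson") {
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    rx <- rank(x); ry <- rank(y)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(fail("degenerate"))
    r <- stats::cor(rx, ry)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, r2 = r^2, p_nominal = p, slope = slope, n = n)
}

#' Permutation p-value for an observed correlation
#'
#' Two-tailed: the p-value is the proportion of null draws whose absolute
#' statistic strictly exceeds the observed absolute statistic. A p of
#' exactly zero is reported with a below-resolution flag rather than a
#' pseudo-count. Null kinds: `shuffle_samples` permutes the probe vector
#' across samples each round; `resample_features` draws feature vectors
#' from a genome-wide pool (rows sampled without replacement when the pool
#' is large enough, otherwise with replacement and a warning).
#'
#' @param observed_stat Observed correlation.
#' @param probe_values,feature_values Sample-aligned vectors (feature
#'   ignored for `resample_features`).
#' @param n_permutations Number of null draws (>= 1).
#' @param null_kind "shuffle_samples" or "resample_features".
#' @param method Correlation type for the null draws.
#' @param pool Feature pool matrix (features x samples, columns aligned
#'   with `probe_values`) for `resample_features`.
#' @param null_stats Optional precomputed null statistics (overrides
#'   drawing; used to share one null across pairs with a common probe).
#' @return list(p_perm, n_permutations, below_resolution, null_stats).
#' @export
permutation_p <- function(observed_stat, probe_values, feature_values = NULL,
                          n_permutations = 1000L,
                          null_kind = c("shuffle_samples", "resample_features"),
                          method = c("pearson", "spearman"),
                          pool = NULL, null_stats = NULL) {
  null_kind <- match.arg(null_kind)
  method <- match.arg(method)
  if (is.null(null_stats)) {
    stopifnot(n_permutations >= 1L)
    null_stats <- draw_null_stats(probe_values, feature_values, n_permutations,
                                  null_kind, method, pool)
  }
  p <- mean(abs(null_stats) > abs(observed_stat), na.rm = TRUE)
  list(p_perm = p, n_permutations = length(null_stats),
       below_resolution = p == 0, null_stats = null_stats)
}

#' Draw null correlation statistics
#'
#' Workhorse behind [permutation_p()], exposed so that one null set can be
#' shared across all features tested against the same probe.
#'
#' @inheritParams permutation_p
#' @return Numeric vector of null correlations.
#' @export
draw_null_stats <- function(probe_values, feature_values, n_permutations,
                            null_kind = c("shuffle_samples", "resample_features"),
                            method = c("pearson", "spearman"), pool = NULL) {
  null_kind <- match.arg(null_kind)
  method <- match.arg(method)
  if (null_kind == "shuffle_samples") {
    ok <- !is.na(probe_values) & !is.na(feature_values)
    x <- as.numeric(probe_values[ok]); y <- as.numeric(feature_values[ok])
    if (method == "spearman") { x <- rank(x); y <- rank(y) }
    x <- x - mean(x); y <- y - mean(y)
    denom_y <- sqrt(sum(y^2))
    vapply(seq_len(n_permutations), function(b) {
      xp <- x[sample.int(length(x))]
      sum(xp * y) / (sqrt(sum(xp^2)) * denom_y)
    }, numeric(1L))
  } else {
    if (is.null(pool) || nrow(pool) == 0L) stop("resample_features needs a non-empty pool")
    if (nrow(pool) >= n_permutations) {
      idx <- sample.int(nrow(pool), n_permutations)
    } else {
      warning("pool smaller than the number of permutation draws; sampling with replacement")
      idx <- sample.int(nrow(pool), n_permutations, replace = TRUE)
    }
    vapply(idx, function(i) {
      res <- correlate(probe_values, pool[i, ], method = method)
      if (is.null(res)) NA_real_ else res$r
    }, numeric(1L))
  }
}

# One empty association record, for binding.
.empty_record <- function() {
  data.frame(probe_id = character(), feature_id = character(),
             feature_kind = character(), population_set = character(),
             n = integer(), stat_kind = character(), r = numeric(),
             r2 = numeric(), slope = numeric(), normalized_slope = numeric(),
             p_nominal = numeric(), p_perm = numeric(),
             n_permutations = integer(), stringsAsFactors = FALSE)
}

# Default population sets over the three-population cohort.
default_population_sets <- function(populations = c("CEU", "YRI", "CHB")) {
  sets <- as.list(populations)
  names(sets) <- populations
  sets$combined <- populations
  sets
}

# Sample ids belonging to a population set, optionally one sex.
.set_samples <- function(samples, set, sex = NULL) {
  keep <- samples$population %in% set
  if (!is.null(sex)) keep <- keep & samples$sex == sex
  samples$sample_id[keep]
}

#' Scan for tag SNPs of a probe's copy number
#'
#' For every population set (each population plus all combined), each SNP
#' inside the probe's windows (built from alignments at >= 95% identity
#' with a 250 kb flank) is correlated with the probe's values using the
#' Pearson 0/1/2 dosage correlation; the best SNP is the one with maximal
#' R-squared (ties by smaller nominal p, then genomic position), and its
#' significance comes from sample-shuffling permutations. Probes on chrX
#' or chrY are analysed separately within males and within females.
#'
#' @param probe_values Named numeric vector (per sample).
#' @param panel Filtered, encoded `snp_panel`.
#' @param windows Window data.frame from [build_windows()].
#' @param samples Sample table (sample_id, population, sex).
#' @param probe_id Probe identifier carried into records.
#' @param chrom Probe chromosome (sex stratification for "chrX"/"chrY").
#' @param n_permutations Permutation rounds for the best SNP (default
#'   10000).
#' @param population_sets Named list of population sets; default the three
#'   populations and "combined".
#' @return data.frame of best-SNP association records, one row per
#'   population set (x sex stratum for sex chromosomes); SNP-less windows
#'   yield a row with NA feature_id. Attribute `n_snps_tested` gives the
#'   number of in-window SNPs.
#' @export
tag_snp_scan <- function(probe_values, panel, windows, samples,
                         probe_id = "probe", chrom = "autosome",
                         n_permutations = 10000L,
                         population_sets = NULL) {
  if (is.null(population_sets))
    population_sets <- default_population_sets(intersect(c("CEU", "YRI", "CHB"),
                                                         unique(samples$population)))
  snp_coords <- data.frame(feature_id = panel$snps$snp_id,
                           chrom = panel$snps$chrom, pos = panel$snps$pos,
                           stringsAsFactors = FALSE)
  in_win <- features_in_windows(windows, snp_coords)
  sexes <- if (sub("^chr", "", chrom) %in% c("X", "Y")) c("male", "female") else list(NULL)
  records <- list()
  for (set_name in names(population_sets)) {
    for (sex in sexes) {
      ids <- .set_samples(samples, population_sets[[set_name]], sex)
      ids <- intersect(ids, names(probe_values))
      ids <- intersect(ids, colnames(panel$codes))
      label <- if (is.null(sex)) set_name else paste(set_name, sex, sep = "_")
      rec <- .best_snp_record(probe_values[ids], panel, in_win, ids,
                              probe_id, label, n_permutations)
      records[[label]] <- rec
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  attr(out, "n_snps_tested") <- length(in_win)
  out
}

.best_snp_record <- function(pv, panel, snp_ids, sample_ids, probe_id,
                             label, n_permutations) {
  na_rec <- data.frame(probe_id = probe_id, feature_id = NA_character_,
                       feature_kind = "snp", population_set = label,
                       n = length(sample_ids), stat_kind = "pearson_r",
                       r = NA_real_, r2 = NA_real_, slope = NA_real_,
                       normalized_slope = NA_real_, p_nominal = NA_real_,
                       p_perm = NA_real_, n_permutations = 0L,
                       stringsAsFactors = FALSE)
  if (!length(snp_ids) || length(sample_ids) < 3L) return(na_rec)
  best <- NULL
  for (sid in snp_ids) {
    g <- panel$codes[sid, sample_ids]
    res <- correlate(pv, g, method = "pearson")
    if (is.null(res)) next
    pos <- panel$snps$pos[panel$snps$snp_id == sid]
    cand <- c(res, list(snp = sid, pos = pos))
    if (is.null(best) ||
        cand$r2 > best$r2 + 1e-15 ||
        (abs(cand$r2 - best$r2) <= 1e-15 &&
         (cand$p_nominal < best$p_nominal ||
          (cand$p_nominal == best$p_nominal && cand$pos < best$pos))))
      best <- cand
  }
  if (is.null(best)) return(na_rec)
  g <- panel$codes[best$snp, sample_ids]
  perm <- permutation_p(best$r, pv, g, n_permutations, "shuffle_samples", "pearson")
  data.frame(probe_id = probe_id, feature_id = best$snp, feature_kind = "snp",
             population_set = label, n = best$n, stat_kind = "pearson_r",
             r = best$r, r2 = best$r2, slope = best$slope,
             normalized_slope = NA_real_, p_nominal = best$p_nominal,
             p_perm = perm$p_perm, n_permutations = perm$n_permutations,
             stringsAsFactors = FALSE)
}

#' Filter transcripts before expression association
#'
#' Removes transcripts with mean log2 expression below `min_mean` or
#' interquartile range below `min_iqr` (both strict <), computed across
#' all samples.
#'
#' @param expr Numeric matrix transcripts x samples (log2 scale).
#' @param min_mean,min_iqr Thresholds (defaults 6 and 0.25).
#' @return Character vector of retained transcript ids.
#' @export
filter_transcripts <- function(expr, min_mean = 6, min_iqr = 0.25) {
  means <- rowMeans(expr, na.rm = TRUE)
  iqrs <- apply(expr, 1L, stats::IQR, na.rm = TRUE)
  rownames(expr)[means >= min_mean & iqrs >= min_iqr]
}

#' Cis expression association scan for one probe
#'
#' Transcripts passing [filter_transcripts()] whose TSS lies inside the
#' probe's 500 kb windows are correlated (Pearson) with the probe's values
#' per population and combined, with sample-shuffling permutation p-values.
#' A record whose transcript is the probe's own target gene is flagged as
#' auto-correlated.
#'
#' @param probe_values Named per-sample vector.
#' @param expr list(values, coords) as from [read_feature_matrix()]; coords
#'   anchor at the TSS.
#' @param windows Window data.frame (500 kb flank).
#' @param samples Sample table.
#' @param probe_id Probe id for the records.
#' @param target_gene Transcript/gene id targeted by the probe (for the
#'   auto-correlation flag).
#' @param n_permutations Permutation rounds (default 10000).
#' @param population_sets Named list; default per-population + combined.
#' @param min_mean,min_iqr Transcript filter thresholds.
#' @return data.frame of association records with an `auto_correlated`
#'   column; attribute `n_transcripts_tested`.
#' @export
expression_scan <- function(probe_values, expr, windows, samples,
                            probe_id = "probe", target_gene = NULL,
                            n_permutations = 10000L, population_sets = NULL,
                            min_mean = 6, min_iqr = 0.25) {
  if (is.null(population_sets))
    population_sets <- default_population_sets(intersect(c("CEU", "YRI", "CHB"),
                                                         unique(samples$population)))
  keep <- filter_transcripts(expr$values, min_mean, min_iqr)
  coords <- expr$coords[expr$coords$feature_id %in% keep, , drop = FALSE]
  in_win <- features_in_windows(windows, coords)
  records <- .empty_record()
  records$auto_correlated <- logical()
  for (set_name in names(population_sets)) {
    ids <- .set_samples(samples, population_sets[[set_name]])
    ids <- intersect(intersect(ids, names(probe_values)), colnames(expr$values))
    pv <- probe_values[ids]
    for (tid in in_win) {
      ev <- expr$values[tid, ids]
      res <- correlate(pv, ev, method = "pearson")
      if (is.null(res)) next
      perm <- permutation_p(res$r, pv, ev, n_permutations, "shuffle_samples", "pearson")
      records <- rbind(records, data.frame(
        probe_id = probe_id, feature_id = tid, feature_kind = "transcript",
        population_set = set_name, n = res$n, stat_kind = "pearson_r",
        r = res$r, r2 = res$r2, slope = res$slope,
        normalized_slope = NA_real_, p_nominal = res$p_nominal,
        p_perm = perm$p_perm, n_permutations = perm$n_permutations,
        auto_correlated = !is.null(target_gene) && tid %in% target_gene,
        stringsAsFactors = FALSE))
    }
  }
  rownames(records) <- NULL
  attr(records, "n_transcripts_tested") <- length(in_win)
  records
}

#' Normalized slope of methylation on copy number
#'
#' The predicted beta-value change between the lowest and highest observed
#' copy number under the best linear fit: the OLS slope of beta on CN
#' multiplied by the observed CN range, sign preserved. A zero CN range
#' returns 0 with a `zero_range` attribute.
#'
#' @param beta_values,cn_values Sample-aligned numeric vectors.
#' @param min_n Minimum complete pairs (default 3).
#' @return Numeric scalar.
#' @export
normalized_slope <- function(beta_values, cn_values, min_n = 3L) {
  ok <- !is.na(beta_values) & !is.na(cn_values)
  b <- beta_values[ok]; cn <- cn_values[ok]
  if (length(b) < min_n) stop("fewer than ", min_n, " complete pairs")
  rng <- max(cn) - min(cn)
  if (rng == 0) {
    out <- 0
    attr(out, "zero_range") <- TRUE
    return(out)
  }
  slope <- stats::cov(b, cn) / stats::var(cn)
  slope * rng
}

#' QC filter for a methylation beta-value matrix
#'
#' Removes probes flagged as multi-locus mappers or as overlapping a
#' common SNP near the probe 3' end or at the target CpG (flags are
#' inputs), probes on chrY, and probes with more than `missing_threshold`
#' missing values; then partitions the survivors into autosomal and chrX
#' matrices.
#'
#' @param values Beta matrix CpGs x samples.
#' @param coords data.frame feature_id, chrom, pos.
#' @param flags Optional data.frame with feature_id plus logical columns
#'   `multi_loci` and/or `snp_overlap`.
#' @param missing_threshold Missingness cutoff (strict >, default 0.05).
#' @return list(autosomal = list(values, coords), chrx = list(values,
#'   coords), log = named counts).
#' @export
methylation_qc <- function(values, coords, flags = NULL,
                           missing_threshold = 0.05) {
  stopifnot(identical(rownames(values), coords$feature_id))
  n0 <- nrow(values)
  drop_flag <- rep(FALSE, n0)
  if (!is.null(flags)) {
    i <- match(coords$feature_id, flags$feature_id)
    for (col in intersect(c("multi_loci", "snp_overlap"), colnames(flags))) {
      f <- flags[[col]][i]
      drop_flag <- drop_flag | (!is.na(f) & f)
    }
  }
  drop_y <- coords$chrom %in% c("chrY", "Y")
  miss <- rowMeans(is.na(values))
  drop_miss <- miss > missing_threshold
  keep <- !(drop_flag | drop_y | drop_miss)
  vals <- values[keep, , drop = FALSE]
  crd <- coords[keep, , drop = FALSE]
  is_x <- crd$chrom %in% c("chrX", "X")
  list(autosomal = list(values = vals[!is_x, , drop = FALSE],
                        coords = crd[!is_x, , drop = FALSE]),
       chrx = list(values = vals[is_x, , drop = FALSE],
                   coords = crd[is_x, , drop = FALSE]),
       log = c(input = n0, flagged = sum(drop_flag), chrY = sum(drop_y & !drop_flag),
               high_missing = sum(drop_miss & !drop_flag & !drop_y),
               autosomal = sum(keep & !is_x), chrx = sum(keep & is_x)))
}

#' Staged cis methylation association pipeline
#'
#' For each probe, Spearman correlations between copy number and every
#' in-window CpG in the combined population are computed, then filtered in
#' stages: (1) all in-window pairs tested; (2) retain the top
#' `1 - top_quantile` fraction by absolute rho across all tested pairs
#' (default top 2%); (3) retain absolute normalized slope >
#' `slope_min`; (4) permutation p below `perm_p_max`, where the null
#' re-correlates each probe's copy number against CpG vectors resampled
#' from a genome-wide pool; (5) nominal Spearman p below `pop_p_max` in
#' every population separately. The X-chromosome analysis is the same
#' pipeline invoked on male samples only with an X-specific pool.
#'
#' @param cn Matrix probes x samples of copy numbers (or normalized
#'   counts).
#' @param meth list(values, coords) of QC-passed beta values.
#' @param windows_by_probe Named list of window data.frames (500 kb flank,
#'   unplaced scaffolds and chrY excluded).
#' @param pool Genome-wide beta matrix (CpGs x samples) for the resampling
#'   null.
#' @param samples Sample table restricted to the analysis populations.
#' @param populations Populations required at stage 5 (default CEU, YRI).
#' @param top_quantile Quantile of |rho| defining stage 2 (default 0.98).
#' @param slope_min Normalized-slope cutoff (default 0.1).
#' @param n_permutations Null draws per probe (default 1000).
#' @param perm_p_max Stage-4 threshold (default 0.01).
#' @param pop_p_max Stage-5 per-population threshold (default 0.05).
#' @return list(records, funnel, rho_cutoff). `records` carries one row
#'   per surviving probe-CpG pair with per-population p-values appended.
#' @export
methylation_pipeline <- function(cn, meth, windows_by_probe, pool, samples,
                                 populations = c("CEU", "YRI"),
                                 top_quantile = 0.98, slope_min = 0.1,
                                 n_permutations = 1000L, perm_p_max = 0.01,
                                 pop_p_max = 0.05) {
  sample_ids <- intersect(colnames(cn), colnames(meth$values))
  samples <- samples[samples$sample_id %in% sample_ids, , drop = FALSE]
  sample_ids <- samples$sample_id
  # stage 1: all in-window Spearman correlations, combined population
  stage1 <- list()
  for (p in rownames(cn)) {
    w <- windows_by_probe[[p]]
    if (is.null(w)) next
    cpgs <- features_in_windows(w, meth$coords)
    pv <- cn[p, sample_ids]
    for (cg in cpgs) {
      res <- correlate(pv, meth$values[cg, sample_ids], method = "spearman")
      if (is.null(res)) next
      ns <- normalized_slope(meth$values[cg, sample_ids], pv)
      stage1[[length(stage1) + 1L]] <- data.frame(
        probe_id = p, feature_id = cg, feature_kind = "cpg",
        population_set = "combined", n = res$n, stat_kind = "spearman_rho",
        r = res$r, r2 = res$r2, slope = res$slope,
        normalized_slope = as.numeric(ns), p_nominal = res$p_nominal,
        p_perm = NA_real_, n_permutations = 0L, stringsAsFactors = FALSE)
    }
  }
  funnel <- c(stage1_tested = length(stage1))
  if (!length(stage1))
    return(list(records = .empty_record(), funnel = funnel, rho_cutoff = NA_real_))
  recs <- do.call(rbind, stage1)
  # stage 2: top |rho| quantile over all tested pairs
  cutoff <- stats::quantile(abs(recs$r), top_quantile, names = FALSE, type = 7)
  recs <- recs[abs(recs$r) >= cutoff, , drop = FALSE]
  funnel <- c(funnel, stage2_top_rho = nrow(recs))
  # stage 3: large predicted beta change
  recs <- recs[abs(recs$normalized_slope) > slope_min, , drop = FALSE]
  funnel <- c(funnel, stage3_slope = nrow(recs))
  # stage 4: pool-resampling permutation null, shared per probe
  if (nrow(recs)) {
    null_by_probe <- list()
    pool_sub <- pool[, sample_ids, drop = FALSE]
    for (p in unique(recs$probe_id))
      null_by_probe[[p]] <- draw_null_stats(cn[p, sample_ids], NULL,
                                            n_permutations, "resample_features",
                                            "spearman", pool_sub)
    for (k in seq_len(nrow(recs))) {
      perm <- permutation_p(recs$r[k], NULL, NULL,
                            null_stats = null_by_probe[[recs$probe_id[k]]])
      recs$p_perm[k] <- perm$p_perm
      recs$n_permutations[k] <- perm$n_permutations
    }
    recs <- recs[recs$p_perm < perm_p_max, , drop = FALSE]
  }
  funnel <- c(funnel, stage4_perm = nrow(recs))
  # stage 5: nominal replication in each population separately
  if (nrow(recs)) {
    keep <- rep(TRUE, nrow(recs))
    for (pop in populations) {
      ids <- samples$sample_id[samples$population == pop]
      pcol <- paste0("p_", pop)
      recs[[pcol]] <- NA_real_
      for (k in seq_len(nrow(recs))) {
        res <- correlate(cn[recs$probe_id[k], ids],
                         meth$values[recs$feature_id[k], ids],
                         method = "spearman")
        recs[[pcol]][k] <- if (is.null(res)) NA_real_ else res$p_nominal
      }
      keep <- keep & !is.na(recs[[pcol]]) & recs[[pcol]] < pop_p_max
    }
    recs <- recs[keep, , drop = FALSE]
  }
  funnel <- c(funnel, stage5_replicated = nrow(recs))
  rownames(recs) <- NULL
  list(records = recs, funnel = funnel, rho_cutoff = cutoff)
}

#' Sliding-window ChIP enrichment track
#'
#' Both coverage tracks are scaled by their totals, then the enrichment
#' ratio is computed over windows `[k*step, k*step + window)` (plus an
#' optional pseudo-count), giving `floor((L - window)/step) + 1` windows
#' for a region of length `L >= window`; shorter regions give an empty
#' track. With the default `eps = 0`, windows with zero input coverage get
#' an NA ratio.
#'
#' @param chip_coverage,input_coverage Per-base coverage vectors of equal
#'   length.
#' @param window Window width in bp (default 170).
#' @param step Slide in bp (default 85).
#' @param eps Pseudo-count added to both scaled sums (default 0).
#' @return data.frame(start, end, chip, input, ratio) with 0-based
#'   half-open window coordinates relative to the region start.
#' @export
sliding_window_enrichment <- function(chip_coverage, input_coverage,
                                      window = 170L, step = 85L, eps = 0) {
  stopifnot(length(chip_coverage) == length(input_coverage))
  L <- length(chip_coverage)
  empty <- data.frame(start = integer(), end = integer(), chip = numeric(),
                      input = numeric(), ratio = numeric())
  if (L < window) return(empty)
  tc <- sum(chip_coverage); ti <- sum(input_coverage)
  if (tc <= 0 || ti <= 0) stop("coverage totals must be positive")
  chip <- chip_coverage / tc
  input <- input_coverage / ti
  n_win <- (L - window) %/% step + 1L
  starts <- (seq_len(n_win) - 1L) * step
  cs_chip <- c(0, cumsum(chip)); cs_input <- c(0, cumsum(input))
  chip_sum <- cs_chip[starts + window + 1L] - cs_chip[starts + 1L]
  input_sum <- cs_input[starts + window + 1L] - cs_input[starts + 1L]
  ratio <- (chip_sum + eps) / (input_sum + eps)
  ratio[input_sum + eps == 0] <- NA_real_
  data.frame(start = starts, end = starts + window,
             chip = chip_sum, input = input_sum, ratio = ratio)
}
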