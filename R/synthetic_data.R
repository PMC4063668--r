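# Generators for every input the pipeline consumes, with known ground
# truth, so each stage can be validated end-to-end without external data.

#' Default simulated cohort
#'
#' Mirrors the three-population reference design: 60 CEU, 60 YRI and 45
#' CHB unrelated individuals with balanced sexes.
#'
#' @param n_per_pop Named integer vector of samples per population.
#' @return Sample table data.frame (sample_id, population, sex, species).
#' @export
default_sample_table <- function(n_per_pop = c(CEU = 60L, YRI = 60L, CHB = 45L)) {
  pops <- rep(names(n_per_pop), n_per_pop)
  n <- length(pops)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             population = pops,
             sex = rep_len(c("male", "female"), n),
             species = "human", stringsAsFactors = FALSE)
}

#' Simulation ground truth for the count assay
#'
#' Draws per-probe mean copy numbers, per-sample integer copy numbers
#' around them, probe efficiencies, per-sample technical scale factors and
#' background level. Optional per-population mean shifts plant population
#' differentiation for V_ST recovery tests.
#'
#' @param n_test Number of test probes.
#' @param samples Sample table; default [default_sample_table()].
#' @param cn_min,cn_max Range of diploid copy numbers.
#' @param cn_sd_frac Within-cohort CN standard deviation as a fraction of
#'   the probe mean (default 0.15; `clustered` mode).
#' @param cn_dist "clustered" (default): per-sample CN varies around a
#'   probe-level mean, mimicking a polymorphic locus; "uniform": per-sample
#'   CN drawn uniformly from the integers [cn_min, cn_max], spanning the
#'   assay's full dynamic range.
#' @param efficiency_range Probe efficiency bounds (default 0.5 to 2).
#' @param scale_sd SD of log-normal per-sample scale factors (default 0.1).
#' @param assay_gain Overall counts-per-copy gain of the assay (default
#'   50), so a diploid locus at efficiency 1 yields ~100 counts.
#' @param background_mean Mean background count (default 10).
#' @param sigma Multiplicative log-normal count noise SD (default 0.05).
#' @param pop_shift Optional named list probe_id -> named vector of
#'   per-population additive CN shifts.
#' @param probe_chrom Chromosome per test probe (default chr1); chrX/chrY
#'   probes get sex-aware handling downstream.
#' @param seed Optional RNG seed.
#' @return `sim_truth` object.
#' @export
simulate_truth <- function(n_test = 20L, samples = default_sample_table(),
                           cn_min = 2, cn_max = 60, cn_sd_frac = 0.15,
                           efficiency_range = c(0.5, 2), scale_sd = 0.1,
                           assay_gain = 50, background_mean = 10, sigma = 0.05,
                           pop_shift = NULL, probe_chrom = "chr1",
                           cn_dist = c("clustered", "uniform"),
                           seed = NULL) {
  cn_dist <- match.arg(cn_dist)
  if (!is.null(seed)) set.seed(seed)
  if (sigma < 0) stop("sigma must be >= 0")
  n_s <- nrow(samples)
  probe_ids <- sprintf("T%03d", seq_len(n_test))
  probe_chrom <- rep_len(probe_chrom, n_test)
  probe_mean <- stats::runif(n_test, cn_min, cn_max)
  cn <- matrix(0, n_test, n_s, dimnames = list(probe_ids, samples$sample_id))
  for (i in seq_len(n_test)) {
    v <- if (cn_dist == "uniform")
      sample(seq(ceiling(cn_min), floor(cn_max)), n_s, replace = TRUE)
    else stats::rnorm(n_s, probe_mean[i], probe_mean[i] * cn_sd_frac)
    if (!is.null(pop_shift[[probe_ids[i]]])) {
      sh <- pop_shift[[probe_ids[i]]]
      v <- v + as.numeric(sh[samples$population])
    }
    cn[i, ] <- pmax(0, round(v))
  }
  structure(list(
    true_cn = cn,
    probe_mean = stats::setNames(probe_mean, probe_ids),
    probe_chrom = stats::setNames(probe_chrom, probe_ids),
    probe_efficiency = stats::setNames(
      stats::runif(n_test, efficiency_range[1L], efficiency_range[2L]), probe_ids),
    sample_scale = stats::setNames(
      exp(stats::rnorm(n_s, 0, scale_sd)), samples$sample_id),
    assay_gain = assay_gain,
    background_mean = background_mean,
    sigma = sigma,
    samples = samples,
    planted_tags = NULL, planted_expr_effects = NULL,
    planted_meth_effects = NULL, seed = seed), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d test probes x %d samples (sigma = %g)\n",
              nrow(x$true_cn), ncol(x$true_cn), x$sigma))
  invisible(x)
}

#' Genomic anchors of the simulated test probes
#'
#' Each probe gets one alignment on its chromosome, spaced widely enough
#' that 500 kb windows never merge across probes.
#'
#' @param truth `sim_truth`.
#' @param spacing Distance between consecutive probe anchors (default 2 Mb).
#' @param probe_len Probe alignment length in bp.
#' @return data.frame(probe_id, chrom, start, end).
#' @export
probe_positions <- function(truth, spacing = 2e6L, probe_len = 100L) {
  ids <- rownames(truth$true_cn)
  data.frame(probe_id = ids, chrom = unname(truth$probe_chrom[ids]),
             start = spacing * seq_along(ids),
             end = spacing * seq_along(ids) + probe_len,
             stringsAsFactors = FALSE)
}

#' Simulate a raw count matrix and its probe annotation
#'
#' Count model: `raw(p, s) = scale_s * (gain * efficiency_p * cn(p, s) +
#' background) * exp(sigma * z)` with standard-normal z, where `gain` is
#' the assay-wide counts-per-copy factor. Negative controls
#' see background only; invariant controls carry a true copy number of 2;
#' gender controls track sex (SRY-type: 1 copy in males, 0 in females;
#' X-type: 1 in males, 2 in females).
#'
#' @param truth `sim_truth`.
#' @param n_negative,n_invariant Numbers of control probes (defaults 8 and
#'   10).
#' @param control_efficiency Efficiency applied to control probes (default
#'   1.2, near the top of the test-probe range).
#' @param seed Optional RNG seed.
#' @return list(raw, annotation, samples, truth).
#' @export
simulate_counts <- function(truth, n_negative = 8L, n_invariant = 10L,
                            control_efficiency = 1.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  samples <- truth$samples
  n_s <- nrow(samples)
  pos <- probe_positions(truth)
  test_ids <- rownames(truth$true_cn)
  neg_ids <- sprintf("NEG%02d", seq_len(n_negative))
  inv_ids <- sprintf("INV%02d", seq_len(n_invariant))
  gender_ids <- c("SRY", "XINV")
  male <- samples$sex == "male"
  cn_all <- rbind(
    truth$true_cn,
    matrix(0, n_negative, n_s, dimnames = list(neg_ids, samples$sample_id)),
    matrix(2, n_invariant, n_s, dimnames = list(inv_ids, samples$sample_id)),
    rbind(SRY = ifelse(male, 1, 0), XINV = ifelse(male, 1, 2)))
  eff <- c(truth$probe_efficiency,
           stats::setNames(rep(control_efficiency, n_negative + n_invariant + 2L),
                           c(neg_ids, inv_ids, gender_ids)))
  gain <- if (is.null(truth$assay_gain)) 1 else truth$assay_gain
  raw <- (gain * eff[rownames(cn_all)] * cn_all + truth$background_mean)
  raw <- sweep(raw, 2L, truth$sample_scale[samples$sample_id], `*`)
  if (truth$sigma > 0)
    raw <- raw * exp(matrix(stats::rnorm(length(raw), 0, truth$sigma),
                            nrow(raw), ncol(raw)))
  aln <- data.frame(chrom = pos$chrom, start = pos$start, end = pos$end,
                    probe_id = pos$probe_id, percent_identity = 98,
                    strand = "+", stringsAsFactors = FALSE)
  classes <- data.frame(
    probe_id = c(test_ids, neg_ids, inv_ids, gender_ids),
    target_name = c(test_ids, neg_ids, inv_ids, gender_ids),
    probe_class = c(rep("test", length(test_ids)), rep("negative", n_negative),
                    rep("invariant", n_invariant), rep("gender", 2L)),
    locus_type = "unknown", stringsAsFactors = FALSE)
  list(raw = raw, annotation = probe_annotation(aln, classes),
       samples = samples, truth = truth)
}

# Latent-threshold construction of a genotype correlated with a CN vector.
# Thresholds come from Hardy-Weinberg genotype proportions at allele
# frequency `maf`; the latent loading is calibrated analytically so the
# genotype-CN squared correlation approximates target_r2.
.plant_tag <- function(cn, target_r2, maf) {
  n <- length(cn)
  z_cn <- stats::qnorm((rank(cn, ties.method = "average") - 0.5) / n)
  p0 <- (1 - maf)^2; p1 <- 2 * maf * (1 - maf); p2 <- maf^2
  a1 <- stats::qnorm(p0); a2 <- stats::qnorm(p0 + p1)
  if (target_r2 >= 1) {
    # deterministic monotone function of CN quantiles
    codes <- as.integer(cut(rank(cn, ties.method = "first"),
                            breaks = c(0, p0 * n, (p0 + p1) * n, n + 1),
                            labels = FALSE)) - 1L
    return(codes)
  }
  sd_g <- sqrt(p1 + 4 * p2 - (p1 + 2 * p2)^2)
  cor_gz <- (stats::dnorm(a1) + stats::dnorm(a2)) / sd_g
  r_cn_z <- stats::cor(cn, z_cn)
  load <- sqrt(target_r2) / (cor_gz * r_cn_z)
  load <- min(load, 1)
  z <- load * z_cn + sqrt(1 - load^2) * stats::rnorm(n)
  as.integer((z > a1) + (z > a2))
}

#' Simulate a SNP panel with optional planted tag SNPs
#'
#' Untagged SNPs are drawn under Hardy-Weinberg equilibrium at uniform
#' minor allele frequencies, independent of copy number. Each planted tag
#' is built by thresholding a latent variable correlated with the probe's
#' copy number so that the genotype-CN squared correlation approximates
#' the target; the realized value is recorded in the returned truth.
#'
#' @param truth `sim_truth` (copy numbers and probe positions).
#' @param n_snps_per_probe SNPs placed inside each probe's 250 kb
#'   neighbourhood (default 50).
#' @param maf_range Uniform MAF bounds for untagged SNPs (default 0.1-0.5).
#' @param planted_tags Optional data.frame (probe_id, target_r2, maf
#'   optional, default 0.4).
#' @param flank Placement flank around each probe (default 250 kb).
#' @param seed Optional RNG seed.
#' @return list(panel = `snp_panel`, planted = data.frame with realized_r2).
#' @export
simulate_snps <- function(truth, n_snps_per_probe = 50L,
                          maf_range = c(0.1, 0.5), planted_tags = NULL,
                          flank = 250000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(planted_tags) &&
      any(planted_tags$target_r2 <= 0 | planted_tags$target_r2 > 1))
    stop("target_r2 must lie in (0, 1]")
  pos <- probe_positions(truth)
  samples <- truth$samples
  n_s <- nrow(samples)
  snps <- list(); codes <- list()
  planted_out <- NULL
  for (i in seq_len(nrow(pos))) {
    p <- pos$probe_id[i]
    locs <- sort(sample.int(2L * flank, n_snps_per_probe)) + pos$start[i] - flank
    locs <- pmax(locs, 0L)
    ids <- sprintf("rs_%s_%03d", p, seq_len(n_snps_per_probe))
    g <- matrix(NA_integer_, n_snps_per_probe, n_s)
    for (k in seq_len(n_snps_per_probe)) {
      maf <- stats::runif(1L, maf_range[1L], maf_range[2L])
      g[k, ] <- stats::rbinom(n_s, 2L, maf)
    }
    if (!is.null(planted_tags) && p %in% planted_tags$probe_id) {
      row <- planted_tags[planted_tags$probe_id == p, ][1L, ]
      maf <- if (!is.null(row$maf) && !is.na(row$maf)) row$maf else 0.4
      tag_codes <- .plant_tag(truth$true_cn[p, ], row$target_r2, maf)
      k <- sample.int(n_snps_per_probe, 1L)
      g[k, ] <- tag_codes
      planted_out <- rbind(planted_out, data.frame(
        probe_id = p, snp_id = ids[k], target_r2 = row$target_r2,
        realized_r2 = stats::cor(tag_codes, truth$true_cn[p, ])^2,
        stringsAsFactors = FALSE))
    }
    snps[[p]] <- data.frame(snp_id = ids, chrom = pos$chrom[i], pos = locs,
                            stringsAsFactors = FALSE)
    codes[[p]] <- g
  }
  snp_df <- do.call(rbind, snps)
  code_mat <- do.call(rbind, codes)
  calls <- matrix(c("AA", "AG", "GG")[code_mat + 1L], nrow(code_mat),
                  dimnames = list(snp_df$snp_id, samples$sample_id))
  rownames(snp_df) <- NULL
  list(panel = snp_panel(snp_df, calls), planted = planted_out)
}

#' Simulate a cis expression matrix with planted copy-number effects
#'
#' Planted transcripts follow `expr = intercept + slope * cn + noise` on a
#' log2 scale; all other transcripts are independent of copy number.
#' Transcript TSSs are placed inside each probe's 500 kb neighbourhood.
#'
#' @param truth `sim_truth`.
#' @param n_transcripts_per_probe Default 10.
#' @param planted_effects Optional data.frame (probe_id, slope).
#' @param base_mean,base_sd Background expression distribution (defaults 8
#'   and 1, comfortably above the mean-expression filter).
#' @param noise_sd Residual SD for planted transcripts (default 0.5).
#' @param flank Placement flank (default 500 kb).
#' @param seed Optional RNG seed.
#' @return list(expr = list(values, coords), planted = data.frame with
#'   transcript ids).
#' @export
simulate_expression <- function(truth, n_transcripts_per_probe = 10L,
                                planted_effects = NULL, base_mean = 8,
                                base_sd = 1, noise_sd = 0.5,
                                flank = 500000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- probe_positions(truth)
  samples <- truth$samples
  n_s <- nrow(samples)
  vals <- list(); coords <- list(); planted_out <- NULL
  for (i in seq_len(nrow(pos))) {
    p <- pos$probe_id[i]
    ids <- sprintf("tx_%s_%02d", p, seq_len(n_transcripts_per_probe))
    tss <- sort(sample.int(2L * flank, n_transcripts_per_probe)) + pos$start[i] - flank
    m <- matrix(stats::rnorm(n_transcripts_per_probe * n_s, base_mean, base_sd),
                n_transcripts_per_probe, n_s)
    # keep the transcript filter permeable: inflate IQR via sample spread
    if (!is.null(planted_effects) && p %in% planted_effects$probe_id) {
      row <- planted_effects[planted_effects$probe_id == p, ][1L, ]
      k <- sample.int(n_transcripts_per_probe, 1L)
      cnv <- truth$true_cn[p, ]
      m[k, ] <- base_mean + row$slope * (cnv - mean(cnv)) +
        stats::rnorm(n_s, 0, noise_sd)
      planted_out <- rbind(planted_out, data.frame(
        probe_id = p, transcript_id = ids[k], slope = row$slope,
        stringsAsFactors = FALSE))
    }
    dimnames(m) <- list(ids, samples$sample_id)
    vals[[p]] <- m
    coords[[p]] <- data.frame(feature_id = ids, chrom = pos$chrom[i],
                              pos = pmax(tss, 0L), stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, vals)
  crd <- do.call(rbind, coords); rownames(crd) <- NULL
  list(expr = list(values = values, coords = crd), planted = planted_out)
}

#' Simulate a methylation beta-value matrix with planted effects
#'
#' Planted CpGs follow the normalized-slope construction: the per-copy
#' slope is the target normalized slope divided by the observed CN range,
#' and the intercept centres the fitted line at beta 0.5, so with zero
#' noise the recovered normalized slope equals the target exactly. All
#' values are clipped to [0, 1]. A pool of independent autosomal CpGs is
#' returned for the resampling permutation null.
#'
#' @param truth `sim_truth`.
#' @param n_cpgs_per_probe In-window CpGs per probe (default 30).
#' @param planted_effects Optional data.frame (probe_id, normalized_slope).
#' @param noise_sd Beta-value noise SD (default 0.02).
#' @param n_pool Independent pool CpGs (default 2000).
#' @param flank Placement flank (default 500 kb).
#' @param seed Optional RNG seed.
#' @return list(meth = list(values, coords), pool = matrix, planted =
#'   data.frame with cpg ids).
#' @export
simulate_methylation <- function(truth, n_cpgs_per_probe = 30L,
                                 planted_effects = NULL, noise_sd = 0.02,
                                 n_pool = 2000L, flank = 500000L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- probe_positions(truth)
  samples <- truth$samples
  n_s <- nrow(samples)
  clip01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }
  vals <- list(); coords <- list(); planted_out <- NULL
  for (i in seq_len(nrow(pos))) {
    p <- pos$probe_id[i]
    ids <- sprintf("cg_%s_%03d", p, seq_len(n_cpgs_per_probe))
    locs <- sort(sample.int(2L * flank, n_cpgs_per_probe)) + pos$start[i] - flank
    base <- stats::runif(n_cpgs_per_probe, 0.2, 0.8)
    m <- clip01(matrix(stats::rnorm(n_cpgs_per_probe * n_s, base, noise_sd),
                       n_cpgs_per_probe, n_s))
    if (!is.null(planted_effects) && p %in% planted_effects$probe_id) {
      row <- planted_effects[planted_effects$probe_id == p, ][1L, ]
      cnv <- truth$true_cn[p, ]
      rng <- max(cnv) - min(cnv)
      slope_per_copy <- row$normalized_slope / rng
      intercept <- 0.5 - slope_per_copy * (min(cnv) + max(cnv)) / 2
      k <- sample.int(n_cpgs_per_probe, 1L)
      m[k, ] <- clip01(intercept + slope_per_copy * cnv +
                         stats::rnorm(n_s, 0, noise_sd))
      planted_out <- rbind(planted_out, data.frame(
        probe_id = p, cpg_id = ids[k],
        normalized_slope = row$normalized_slope, stringsAsFactors = FALSE))
    }
    dimnames(m) <- list(ids, samples$sample_id)
    vals[[p]] <- m
    coords[[p]] <- data.frame(feature_id = ids, chrom = pos$chrom[i],
                              pos = pmax(locs, 0L), stringsAsFactors = FALSE)
  }
  pool <- clip01(matrix(stats::rnorm(n_pool * n_s,
                                     stats::runif(n_pool, 0.2, 0.8), noise_sd),
                        n_pool, n_s,
                        dimnames = list(sprintf("pool_cg_%04d", seq_len(n_pool)),
                                        samples$sample_id)))
  crd <- do.call(rbind, coords); rownames(crd) <- NULL
  list(meth = list(values = do.call(rbind, vals), coords = crd),
       pool = pool, planted = planted_out)
}

#' Simulate read-depth copy-number records for calibration
#'
#' `rd = true_cn * exp(sigma * z)`; a configurable fraction of
#' probe-sample cells is emitted twice to exercise duplicate collapsing.
#'
#' @param truth `sim_truth`.
#' @param noise_cv Multiplicative noise SD (default 0).
#' @param dup_fraction Fraction of cells with a duplicate record.
#' @param sample_ids Samples covered by the read-depth study; default all.
#' @param seed Optional RNG seed.
#' @return data.frame (probe_id, sample_id, cn).
#' @export
simulate_readdepth <- function(truth, noise_cv = 0, dup_fraction = 0,
                               sample_ids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sample_ids)) sample_ids <- colnames(truth$true_cn)
  cn <- truth$true_cn[, sample_ids, drop = FALSE]
  grid <- expand.grid(probe_id = rownames(cn), sample_id = sample_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  noise <- function(n) if (noise_cv > 0) exp(stats::rnorm(n, 0, noise_cv)) else 1
  grid$cn <- cn[cbind(grid$probe_id, grid$sample_id)] * noise(nrow(grid))
  if (dup_fraction > 0) {
    extra <- grid[sample.int(nrow(grid), ceiling(dup_fraction * nrow(grid))), ]
    extra$cn <- cn[cbind(extra$probe_id, extra$sample_id)] * noise(nrow(extra))
    grid <- rbind(grid, extra)
  }
  grid
}

#' Simulate primate count data with identity-dependent attenuation
#'
#' Probe binding efficiency decays with sequence divergence:
#' `attenuation(identity) = exp(-rate * (100 - identity))`, monotone
#' non-decreasing in identity with attenuation(100) = 1. The primate raw
#' count follows the human count model with the species copy number and
#' the attenuated efficiency.
#'
#' @param truth `sim_truth` (for probe efficiencies and background).
#' @param species_cn Named per-probe species copy numbers.
#' @param identities Named per-probe percent identity in the species.
#' @param rate Attenuation rate per identity point (default 0.05).
#' @param sigma Count noise SD (default truth's sigma).
#' @param n_invariant Invariant controls (default 10, identity 100).
#' @param seed Optional RNG seed.
#' @return list(raw = one-column matrix of counts, identities).
#' @export
simulate_primate <- function(truth, species_cn, identities, rate = 0.05,
                             sigma = NULL, n_invariant = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma)) sigma <- truth$sigma
  att <- function(idt) exp(-rate * (100 - idt))
  ids <- names(species_cn)
  eff <- truth$probe_efficiency[ids]
  inv_ids <- sprintf("INV%02d", seq_len(n_invariant))
  all_ids <- c(ids, inv_ids)
  cn <- c(species_cn, stats::setNames(rep(2, n_invariant), inv_ids))
  idt <- c(identities[ids], stats::setNames(rep(100, n_invariant), inv_ids))
  eff_all <- c(eff, stats::setNames(rep(1.2, n_invariant), inv_ids))
  gain <- if (is.null(truth$assay_gain)) 1 else truth$assay_gain
  raw <- (gain * eff_all * att(idt) * cn + truth$background_mean)
  if (sigma > 0) raw <- raw * exp(stats::rnorm(length(raw), 0, sigma))
  list(raw = matrix(raw, ncol = 1L, dimnames = list(all_ids, "primate1")),
       identities = idt)
}
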