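# Background correction, invariant-probe normalization, low-count
# exclusion, variability classification and gender QC of raw count
# matrices. Pipeline order is fixed: background -> factors -> normalize ->
# low-count exclusion -> variability.

#' Background-correct a raw count matrix
#'
#' Per sample, subtracts the mean count of the negative-control probes from
#' every probe and clamps at zero. Negative-control rows are retained in
#' the output for QC.
#'
#' @param raw Numeric matrix probes x samples.
#' @param negative_ids Row names of the negative-control probes (>= 1).
#' @return Matrix of corrected counts with attribute `background_per_sample`.
#' @export
background_correct <- function(raw, negative_ids) {
  negative_ids <- intersect(negative_ids, rownames(raw))
  if (length(negative_ids) == 0L)
    stop("no negative-control probes present in the matrix")
  bg <- colMeans(raw[negative_ids, , drop = FALSE], na.rm = TRUE)
  corrected <- pmax(sweep(raw, 2L, bg, `-`), 0)
  attr(corrected, "background_per_sample") <- bg
  corrected
}

#' Per-sample normalization factors from invariant-control probes
#'
#' The default ("corrective") factor is grand mean of the invariant probes
#' over all samples divided by that sample's invariant-probe mean, so that
#' multiplying a sample's counts by its factor equalizes invariant probes
#' across samples. The "literal" mode computes the reciprocal ratio
#' (sample mean over grand mean) instead.
#'
#' @param corrected Background-corrected matrix.
#' @param invariant_ids Row names of the invariant control probes (>= 1).
#' @param mode "corrective" (default) or "literal".
#' @return Named numeric vector of per-sample factors.
#' @export
normalization_factors <- function(corrected, invariant_ids,
                                  mode = c("corrective", "literal")) {
  mode <- match.arg(mode)
  invariant_ids <- intersect(invariant_ids, rownames(corrected))
  if (length(invariant_ids) == 0L) stop("no invariant control probes present")
  inv <- corrected[invariant_ids, , drop = FALSE]
  sample_mean <- colMeans(inv, na.rm = TRUE)
  grand_mean <- mean(inv, na.rm = TRUE)
  zero <- sample_mean <= 0 | is.na(sample_mean)
  if (any(zero))
    stop("zero invariant-probe mean in sample(s): ",
         paste(colnames(corrected)[zero], collapse = ", "))
  if (mode == "corrective") grand_mean / sample_mean else sample_mean / grand_mean
}

#' Apply per-sample normalization factors
#'
#' @param corrected Background-corrected matrix.
#' @param factors Named per-sample factors covering every column.
#' @return `norm_counts` object: the normalized matrix with attributes
#'   `normalization_factor` and `background_per_sample`.
#' @export
normalize_counts <- function(corrected, factors) {
  missing <- setdiff(colnames(corrected), names(factors))
  if (length(missing))
    stop("no normalization factor for sample(s): ", paste(missing, collapse = ", "))
  out <- sweep(corrected, 2L, factors[colnames(corrected)], `*`)
  attr(out, "normalization_factor") <- factors[colnames(corrected)]
  attr(out, "background_per_sample") <- attr(corrected, "background_per_sample")
  class(out) <- c("norm_counts", class(out))
  out
}

#' @export
print.norm_counts <- function(x, ...) {
  cat(sprintf("norm_counts: %d probes x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Exclude probes with low mean counts
#'
#' A probe is dropped when its mean normalized count across all samples is
#' strictly below `min_mean` (default 100); a mean exactly at the threshold
#' is kept.
#'
#' @param normalized Matrix of normalized counts.
#' @param min_mean Exclusion threshold.
#' @return list(kept = matrix, dropped = character vector of probe ids).
#' @export
exclude_low_count_probes <- function(normalized, min_mean = 100) {
  means <- rowMeans(normalized, na.rm = TRUE)
  drop <- means < min_mean
  list(kept = normalized[!drop, , drop = FALSE],
       dropped = rownames(normalized)[drop])
}

#' Classify copy-number variability per probe
#'
#' A probe is called variable when its coefficient of variation (sample sd
#' with n-1 denominator over mean, across all samples) meets `cv_threshold`,
#' or when at least `min_individuals` samples deviate from the cohort mean
#' by at least `deviation` (fractional, two-sided, boundary included).
#' Probes with non-positive mean have undefined CV and are flagged, never
#' called variable.
#'
#' @param normalized Matrix of normalized counts (>= 2 samples).
#' @param cv_threshold CV cutoff (default 0.1).
#' @param deviation Fractional deviation defining an outlier sample
#'   (default 0.30).
#' @param min_individuals Minimum outlier samples (default 2).
#' @return data.frame per probe: probe_id, cv, n_outlier_samples,
#'   is_variable, degenerate.
#' @export
classify_variability <- function(normalized, cv_threshold = 0.1,
                                 deviation = 0.30, min_individuals = 2L) {
  if (ncol(normalized) < 2L) stop("need >= 2 samples")
  out <- data.frame(probe_id = rownames(normalized), cv = NA_real_,
                    n_outlier_samples = 0L, is_variable = FALSE,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(normalized))) {
    v <- normalized[i, ]
    v <- v[!is.na(v)]
    m <- mean(v)
    if (!length(v) || m <= 0) { out$degenerate[i] <- TRUE; next }
    cv <- stats::sd(v) / m
    n_out <- sum(v >= m * (1 + deviation) | v <= m * (1 - deviation))
    out$cv[i] <- cv
    out$n_outlier_samples[i] <- n_out
    out$is_variable[i] <- (cv >= cv_threshold) || (n_out >= min_individuals)
  }
  out
}

#' Gender QC against SRY-type and X-linked control probes
#'
#' A female sample fails when its SRY-type count exceeds `sry_fraction` of
#' the male median SRY count. A male sample fails when its X-linked count
#' lies outside `x_band` times the female median (males are expected at
#' half the female X dosage, so the default band (0.25, 0.75) brackets 0.5).
#'
#' @param normalized Matrix of normalized counts.
#' @param sry_ids,x_ids Row ids of the SRY-type and X-linked control probes.
#' @param samples Sample table with sample_id and sex.
#' @param sry_fraction Female SRY failure threshold as a fraction of the
#'   male median (default 0.1).
#' @param x_band Length-2 multiplier band on the female median for male X
#'   counts (default c(0.25, 0.75)).
#' @return data.frame sample_id, sex, pass, reason; or NULL (with a
#'   warning) when no gender probes are present.
#' @export
qc_gender <- function(normalized, sry_ids, x_ids, samples,
                      sry_fraction = 0.1, x_band = c(0.25, 0.75)) {
  sry_ids <- intersect(sry_ids, rownames(normalized))
  x_ids <- intersect(x_ids, rownames(normalized))
  if (!length(sry_ids) && !length(x_ids)) {
    warning("no gender control probes present; gender QC skipped")
    return(NULL)
  }
  samples <- samples[match(colnames(normalized), samples$sample_id), ]
  male <- samples$sex == "male"
  female <- samples$sex == "female"
  out <- data.frame(sample_id = samples$sample_id, sex = samples$sex,
                    pass = TRUE, reason = NA_character_, stringsAsFactors = FALSE)
  if (length(sry_ids) && any(male) && any(female)) {
    sry <- colMeans(normalized[sry_ids, , drop = FALSE], na.rm = TRUE)
    male_median <- stats::median(sry[male], na.rm = TRUE)
    bad <- female & sry > sry_fraction * male_median
    out$pass[bad] <- FALSE
    out$reason[bad] <- "female with male-level SRY signal"
  }
  if (length(x_ids) && any(male) && any(female)) {
    xv <- colMeans(normalized[x_ids, , drop = FALSE], na.rm = TRUE)
    female_median <- stats::median(xv[female], na.rm = TRUE)
    bad <- male & (xv <= x_band[1L] * female_median | xv >= x_band[2L] * female_median)
    out$pass[bad] <- FALSE
    out$reason[bad] <- ifelse(is.na(out$reason[bad]),
                              "male X-linked signal outside expected band",
                              paste(out$reason[bad], "male X-linked signal outside expected band",
                                    sep = "; "))
  }
  out
}

#' Run the full count-processing pipeline
#'
#' Fixed stage order: background correction, normalization factors,
#' normalization, low-count exclusion, variability classification.
#'
#' @param raw Raw count matrix.
#' @param annotation `probe_annotation` identifying probe classes.
#' @param samples Sample table (for gender QC; optional).
#' @param min_mean Low-count exclusion threshold.
#' @param cv_threshold,deviation,min_individuals Variability parameters.
#' @param mode Normalization mode, see [normalization_factors()].
#' @return list(normalized, kept, dropped, variability, gender_qc, funnel).
#' @export
process_counts <- function(raw, annotation, samples = NULL, min_mean = 100,
                           cv_threshold = 0.1, deviation = 0.30,
                           min_individuals = 2L,
                           mode = c("corrective", "literal")) {
  mode <- match.arg(mode)
  cls <- annotation$probes
  neg <- cls$probe_id[cls$probe_class == "negative"]
  inv <- cls$probe_id[cls$probe_class == "invariant"]
  corrected <- background_correct(raw, neg)
  f <- normalization_factors(corrected, inv, mode = mode)
  norm <- normalize_counts(corrected, f)
  test_ids <- intersect(rownames(norm), cls$probe_id[cls$probe_class == "test"])
  excl <- exclude_low_count_probes(norm[test_ids, , drop = FALSE], min_mean)
  var_call <- classify_variability(excl$kept, cv_threshold, deviation, min_individuals)
  gq <- NULL
  if (!is.null(samples)) {
    gender <- cls$probe_id[cls$probe_class == "gender"]
    sry <- grep("SRY", gender, value = TRUE, ignore.case = TRUE)
    xg <- setdiff(gender, sry)
    if (length(sry) || length(xg))
      gq <- qc_gender(norm, sry, xg, samples)
  }
  funnel <- c(probes_in = length(test_ids),
              probes_after_low_count = nrow(excl$kept),
              probes_variable = sum(var_call$is_variable))
  list(normalized = norm, kept = excl$kept, dropped = excl$dropped,
       variability = var_call, gender_qc = gq, funnel = funnel)
}
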