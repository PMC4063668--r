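# Conversion of relative normalized counts to absolute diploid copy
# numbers, anchored on read-depth estimates over a shared calibration
# subset of samples.

#' Collapse duplicate read-depth entries
#'
#' Where a probe or individual has more than one read-depth record, the
#' mean copy number is used.
#'
#' @param rd data.frame with columns probe_id, sample_id, cn.
#' @return Numeric matrix probes x samples (NA where no record exists).
#' @export
collapse_readdepth <- function(rd) {
  stopifnot(all(c("probe_id", "sample_id", "cn") %in% colnames(rd)))
  probes <- unique(rd$probe_id)
  samples <- unique(rd$sample_id)
  agg <- stats::aggregate(cn ~ probe_id + sample_id, data = rd, FUN = mean)
  m <- matrix(NA_real_, length(probes), length(samples),
              dimnames = list(probes, samples))
  m[cbind(match(agg$probe_id, probes), match(agg$sample_id, samples))] <- agg$cn
  m
}

#' Calibrate normalized counts to absolute diploid copy number
#'
#' For each probe present in both datasets, computes the median normalized
#' count and the median read-depth copy number over the shared calibration
#' samples, then scales every sample's count:
#' `CN(p, s) = count(p, s) / median_count(p) * median_rd_cn(p)`.
#' The scaling applies to all samples, not only the calibration subset.
#' Medians are robust: corrupting a minority of calibration samples leaves
#' them unchanged.
#'
#' @param normalized Matrix of normalized counts probes x samples.
#' @param rd Collapsed read-depth matrix from [collapse_readdepth()].
#' @param shared_samples Optional explicit calibration sample set; defaults
#'   to the samples present in both matrices.
#' @param min_shared Minimum calibration samples with complete data per
#'   probe (default 3).
#' @return `cn_estimates` object: list with `cn` (matrix over all
#'   normalized-count samples), `stats` (per-probe median_ns, median_rd_cn,
#'   n_calibration_samples), and `uncalibrated` (probe_id + reason).
#' @export
calibrate <- function(normalized, rd, shared_samples = NULL, min_shared = 3L) {
  if (is.null(shared_samples))
    shared_samples <- intersect(colnames(normalized), colnames(rd))
  shared_samples <- Reduce(intersect, list(shared_samples, colnames(normalized), colnames(rd)))
  probes <- intersect(rownames(normalized), rownames(rd))
  skipped_probes <- setdiff(rownames(normalized), probes)
  cn <- matrix(NA_real_, nrow = length(probes), ncol = ncol(normalized),
               dimnames = list(probes, colnames(normalized)))
  st <- data.frame(probe_id = probes, median_ns = NA_real_,
                   median_rd_cn = NA_real_, n_calibration_samples = 0L,
                   stringsAsFactors = FALSE)
  bad <- character(); reason <- character()
  for (k in seq_along(probes)) {
    p <- probes[k]
    ns <- normalized[p, shared_samples]
    rdv <- rd[p, shared_samples]
    ok <- !is.na(ns) & !is.na(rdv)
    st$n_calibration_samples[k] <- sum(ok)
    if (sum(ok) < min_shared) {
      bad <- c(bad, p); reason <- c(reason, "too few shared calibration samples")
      next
    }
    med_ns <- stats::median(ns[ok])
    med_rd <- stats::median(rdv[ok])
    if (med_ns <= 0) {
      bad <- c(bad, p); reason <- c(reason, "zero median count")
      next
    }
    st$median_ns[k] <- med_ns
    st$median_rd_cn[k] <- med_rd
    cn[p, ] <- normalized[p, ] / med_ns * med_rd
  }
  if (length(skipped_probes)) {
    bad <- c(bad, skipped_probes)
    reason <- c(reason, rep("absent from read-depth data", length(skipped_probes)))
  }
  structure(list(cn = cn,
                 stats = st,
                 uncalibrated = data.frame(probe_id = bad, reason = reason,
                                           stringsAsFactors = FALSE)),
            class = "cn_estimates")
}

#' @export
print.cn_estimates <- function(x, ...) {
  cat(sprintf("cn_estimates: %d probes x %d samples (%d uncalibratable)\n",
              nrow(x$cn), ncol(x$cn), nrow(x$uncalibrated)))
  invisible(x)
}

#' Summarize diploid copy numbers per probe
#'
#' Per-probe mean/median CN plus the overall mean/median of per-probe
#' means, as reported in copy-number audit tables.
#'
#' @param cn Copy-number matrix or `cn_estimates`.
#' @return list(per_probe, mean_of_means, median_of_means).
#' @export
summarize_copy_numbers <- function(cn) {
  if (inherits(cn, "cn_estimates")) cn <- cn$cn
  per <- data.frame(probe_id = rownames(cn),
                    mean_cn = rowMeans(cn, na.rm = TRUE),
                    median_cn = apply(cn, 1L, stats::median, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  list(per_probe = per,
       mean_of_means = mean(per$mean_cn, na.rm = TRUE),
       median_of_means = stats::median(per$mean_cn, na.rm = TRUE))
}
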