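# Population differentiation (V_ST), primate comparative fold change with
# identity-based retention, and dN/dS distribution comparison.

#' ANOVA-based population differentiation (V_ST) for one probe
#'
#' `V_ST = (V_total - V_within) / V_total`, where `V_total` is the
#' variance of all values (n-1 denominator) and `V_within` the
#' sample-size-weighted mean of the within-population variances:
#' `sum(n_k * var_k) / sum(n_k)`. Negative raw values (sampling noise) are
#' floored at zero in `vst`; the raw value is kept in `vst_raw`.
#'
#' @param values Per-sample copy numbers (or normalized counts; V_ST is
#'   invariant to per-probe affine rescaling).
#' @param groups Population label per sample.
#' @param min_per_group Minimum samples per group (default 2); groups below
#'   it are dropped, and >= 2 groups must remain.
#' @return One-row data.frame: vst, vst_raw, v_total, v_within, n, n_groups.
#'   `vst` is NA when the total variance is zero.
#' @export
vst <- function(values, groups, min_per_group = 2L) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  sizes <- table(groups)
  keep <- names(sizes)[sizes >= min_per_group]
  if (length(keep) < 2L) stop("need >= 2 groups with >= ", min_per_group, " samples")
  sel <- groups %in% keep
  values <- values[sel]; groups <- groups[sel]
  n <- length(values)
  v_total <- stats::var(values)
  nk <- tapply(values, groups, length)
  vk <- tapply(values, groups, stats::var)
  v_within <- sum(nk * vk) / sum(nk)
  raw <- if (v_total > 0) (v_total - v_within) / v_total else NA_real_
  data.frame(vst = if (is.na(raw)) NA_real_ else max(0, raw),
             vst_raw = raw, v_total = v_total, v_within = v_within,
             n = n, n_groups = length(keep))
}

#' Sex-stratified V_ST for sex-chromosome probes
#'
#' For chrX the statistic is computed separately within males and within
#' females and the reported value is the mean of the two; when one stratum
#' is undefined (zero variance) the other is reported and flagged. chrY
#' uses males only, with no averaging.
#'
#' @param values,groups As in [vst()].
#' @param sexes Per-sample sex ("male"/"female").
#' @param chrom "chrX" or "chrY" (also accepts "X"/"Y").
#' @return One-row data.frame: vst, vst_male, vst_female, one_sex_only.
#' @export
vst_sex_aware <- function(values, groups, sexes, chrom) {
  chrom <- sub("^chr", "", chrom)
  if (!chrom %in% c("X", "Y")) stop("vst_sex_aware is for chrX/chrY probes")
  sexes <- as.character(sexes)
  male <- sexes == "male"
  if (chrom == "Y") {
    if (!any(male)) stop("no male samples for a chrY probe")
    v <- vst(values[male], groups[male])
    return(data.frame(vst = v$vst, vst_male = v$vst, vst_female = NA_real_,
                      one_sex_only = TRUE))
  }
  female <- sexes == "female"
  if (!any(male) || !any(female)) stop("both sexes required for chrX")
  vm <- tryCatch(vst(values[male], groups[male])$vst, error = function(e) NA_real_)
  vf <- tryCatch(vst(values[female], groups[female])$vst, error = function(e) NA_real_)
  both <- !is.na(vm) && !is.na(vf)
  reported <- if (both) mean(c(vm, vf)) else if (!is.na(vm)) vm else vf
  data.frame(vst = reported, vst_male = vm, vst_female = vf,
             one_sex_only = !both)
}

#' Flag probes with elevated population differentiation
#'
#' Strictly greater than the threshold (default 0.2).
#'
#' @param records data.frame with columns probe_id and vst.
#' @param threshold V_ST cutoff.
#' @return The flagged subset.
#' @export
flag_differentiated <- function(records, threshold = 0.2) {
  records[!is.na(records$vst) & records$vst > threshold, , drop = FALSE]
}

#' Species-specific invariant-control subset for primate normalization
#'
#' Probes hybridize less efficiently against diverged genomes, so a
#' species' normalization uses only invariant controls whose relative
#' signal (each probe's share of the invariant-probe total in that sample)
#' differs by less than `tolerance` from the mean relative signal of that
#' probe across the human cohort.
#'
#' @param primate_counts Background-corrected counts for one primate sample
#'   (named vector over invariant probe ids, or 1-column matrix).
#' @param human_counts Background-corrected human matrix (invariant probe
#'   rows x samples).
#' @param invariant_ids Invariant control probe ids.
#' @param tolerance Relative-difference cutoff (default 0.20, strict <).
#' @param min_controls Minimum passing controls (default 3).
#' @return Character vector of retained invariant probe ids.
#' @export
primate_invariant_subset <- function(primate_counts, human_counts,
                                     invariant_ids, tolerance = 0.20,
                                     min_controls = 3L) {
  if (is.matrix(primate_counts)) primate_counts <- primate_counts[, 1L]
  pv <- primate_counts[invariant_ids]
  rel_primate <- pv / sum(pv)
  hm <- human_counts[invariant_ids, , drop = FALSE]
  rel_human <- sweep(hm, 2L, colSums(hm), `/`)
  rel_human_mean <- rowMeans(rel_human, na.rm = TRUE)
  keep <- abs(rel_primate - rel_human_mean) / rel_human_mean < tolerance
  out <- invariant_ids[keep]
  if (length(out) < min_controls)
    stop("only ", length(out), " invariant controls pass; species normalization aborted")
  out
}

#' Primate-versus-human copy-number fold change with identity retention
#'
#' Fold change is the species' normalized value over the human mean for
#' that probe (sex-matched human mean for sex-chromosome probes, supplied
#' by the caller). Gains (fold > 1) are retained when the probe has >= 95%
#' sequence identity in that species; losses require >= 98% because probe
#' mismatches depress binding and mimic loss. Retained records with a
#' >= 3-fold change in either direction are flagged.
#'
#' @param species_values Named vector of species-normalized values per probe.
#' @param human_mean Named vector of human mean CN (or normalized counts)
#'   per probe.
#' @param identities Named vector of percent identity of each probe in the
#'   species.
#' @param species Species label carried into the output.
#' @param gain_min_identity,loss_min_identity Identity thresholds.
#' @param fold_flag Flagging threshold (default 3).
#' @return data.frame of primate records: probe_id, species,
#'   percent_identity, normalized_count, human_mean, fold_change,
#'   direction, retained, flagged_3fold. Probes with human mean 0 are
#'   skipped (attribute `skipped`).
#' @export
primate_fold_change <- function(species_values, human_mean, identities,
                                species = "primate",
                                gain_min_identity = 95,
                                loss_min_identity = 98,
                                fold_flag = 3) {
  probes <- intersect(names(species_values), names(human_mean))
  skipped <- probes[is.na(human_mean[probes]) | human_mean[probes] <= 0]
  probes <- setdiff(probes, skipped)
  fc <- as.numeric(species_values[probes]) / as.numeric(human_mean[probes])
  idt <- as.numeric(identities[probes])
  direction <- ifelse(fc > 1, "gain", "loss")
  retained <- ifelse(direction == "gain", idt >= gain_min_identity,
                     idt >= loss_min_identity)
  retained[is.na(retained)] <- FALSE
  out <- data.frame(probe_id = probes, species = rep(species, length(probes)),
                    percent_identity = idt,
                    normalized_count = as.numeric(species_values[probes]),
                    human_mean = as.numeric(human_mean[probes]),
                    fold_change = fc, direction = direction,
                    retained = retained,
                    flagged_3fold = retained & (fc >= fold_flag | fc <= 1 / fold_flag),
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Compare dN/dS distributions of multicopy versus background genes
#'
#' Applies the amino-acid identity filter, then a two-sample
#' Kolmogorov-Smirnov test between the dN/dS values of multicopy genes and
#' the remaining orthologs, and reports per-group fractions with
#' dN/dS > 1. `stats::ks.test` uses the exact two-sample distribution for
#' small products of group sizes and the asymptotic one otherwise.
#'
#' @param table data.frame with columns gene, dnds, percent_aa_identity,
#'   is_multicopy.
#' @param min_aa_identity Exclusion threshold (default 80, strict <
#'   excluded).
#' @return list(ks_statistic, ks_p, frac_gt1_multicopy,
#'   frac_gt1_background, n_multicopy, n_background).
#' @export
dnds_compare <- function(table, min_aa_identity = 80) {
  t2 <- table[!is.na(table$dnds) & table$percent_aa_identity >= min_aa_identity, ]
  mc <- t2$dnds[t2$is_multicopy]
  bg <- t2$dnds[!t2$is_multicopy]
  if (length(mc) < 2L || length(bg) < 2L)
    stop("a group is empty (or has < 2 genes) after the identity filter")
  ks <- suppressWarnings(stats::ks.test(mc, bg))
  list(ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
       frac_gt1_multicopy = mean(mc > 1), frac_gt1_background = mean(bg > 1),
       n_multicopy = length(mc), n_background = length(bg))
}
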