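# Orchestration: a single run over synthetic (or user-supplied) inputs
# with one resolved configuration, structured per-stage funnel logging and
# deterministic seeding.

#' Build and validate a run configuration
#'
#' Thresholds default to the pipeline's canonical values: CV 0.1,
#' outlier deviation 0.30 in >= 2 individuals, MAF 0.1, HWE 0.05, flanks
#' 250 kb (SNPs) and 500 kb (expression/methylation), V_ST 0.2, top-|rho|
#' quantile 0.98, normalized slope 0.1, 10000 shuffle permutations and
#' 1000 pool permutations, identity retention 95 (gain) / 98 (loss),
#' 3-fold flagging.
#'
#' @param seed Integer seed for every stochastic stage.
#' @param outdir Output directory (created); NULL to skip writing.
#' @param ... Overrides for any default listed above, plus generator sizes
#'   `n_test`, `n_snps_per_probe`, `n_transcripts_per_probe`,
#'   `n_cpgs_per_probe`, `n_pool`, `sigma`.
#' @return Validated `run_config` list.
#' @export
run_config <- function(seed = 1L, outdir = NULL, ...) {
  cfg <- list(
    seed = as.integer(seed), outdir = outdir,
    cv_threshold = 0.1, deviation = 0.30, min_individuals = 2L,
    min_mean = 100, maf_min = 0.1, hwe_alpha = 0.05,
    flank_snp = 250000L, flank_feature = 500000L,
    vst_threshold = 0.2, top_quantile = 0.98, slope_min = 0.1,
    n_perm_shuffle = 10000L, n_perm_pool = 1000L,
    gain_min_identity = 95, loss_min_identity = 98, fold_flag = 3,
    n_test = 12L, n_snps_per_probe = 30L, n_transcripts_per_probe = 8L,
    n_cpgs_per_probe = 20L, n_pool = 1000L, sigma = 0.05)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  num_pos <- c("cv_threshold", "deviation", "min_mean", "maf_min", "hwe_alpha",
               "flank_snp", "flank_feature", "vst_threshold", "slope_min",
               "n_perm_shuffle", "n_perm_pool", "fold_flag")
  for (f in num_pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || is.na(cfg[[f]]) ||
        cfg[[f]] < 0)
      stop("config field '", f, "' must be a non-negative number")
  if (cfg$top_quantile <= 0 || cfg$top_quantile >= 1)
    stop("top_quantile must lie in (0, 1)")
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline on simulated inputs
#'
#' Stages, in fixed order: simulate inputs; background-correct, normalize
#' and classify counts; calibrate to absolute copy number against
#' simulated read-depth anchors; V_ST per probe; tag-SNP scan; expression
#' scan; staged methylation pipeline. Every stage appends a line to the
#' funnel log; any stage failure aborts with the stage named. With a fixed
#' seed the entire run is deterministic. When `config$outdir` is set, the
#' resolved configuration (YAML) and all result tables (TSV) are written
#' there.
#'
#' @param config `run_config` object.
#' @return list(truth, counts, cn, vst, tag, expression, methylation,
#'   funnel).
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  funnel <- character()
  log_stage <- function(stage, detail)
    funnel <<- c(funnel, sprintf("%s\t%s", stage, detail))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  sim <- run_stage("simulate", {
    truth <- simulate_truth(n_test = config$n_test, sigma = config$sigma)
    planted <- data.frame(probe_id = rownames(truth$true_cn)[1L], target_r2 = 0.5)
    expr_eff <- data.frame(probe_id = rownames(truth$true_cn)[1L], slope = 0.05)
    meth_eff <- data.frame(probe_id = rownames(truth$true_cn)[1L],
                           normalized_slope = 0.3)
    counts <- simulate_counts(truth)
    snps <- simulate_snps(truth, n_snps_per_probe = config$n_snps_per_probe,
                          planted_tags = planted)
    expr <- simulate_expression(truth,
                                n_transcripts_per_probe = config$n_transcripts_per_probe,
                                planted_effects = expr_eff)
    meth <- simulate_methylation(truth, n_cpgs_per_probe = config$n_cpgs_per_probe,
                                 planted_effects = meth_eff, n_pool = config$n_pool)
    rd <- simulate_readdepth(truth, noise_cv = 0.05,
                             sample_ids = colnames(truth$true_cn)[1:85])
    list(truth = truth, counts = counts, snps = snps, expr = expr,
         meth = meth, rd = rd)
  })
  log_stage("simulate", sprintf("probes=%d samples=%d snps=%d",
                                config$n_test, ncol(sim$truth$true_cn),
                                nrow(sim$snps$panel$snps)))

  proc <- run_stage("normalize", {
    process_counts(sim$counts$raw, sim$counts$annotation, sim$counts$samples,
                   min_mean = config$min_mean, cv_threshold = config$cv_threshold,
                   deviation = config$deviation,
                   min_individuals = config$min_individuals)
  })
  log_stage("normalize", paste(names(proc$funnel), proc$funnel,
                               sep = "=", collapse = " "))

  cne <- run_stage("calibrate", {
    calibrate(proc$kept, collapse_readdepth(sim$rd))
  })
  log_stage("calibrate", sprintf("calibrated=%d uncalibrated=%d",
                                 nrow(cne$cn), nrow(cne$uncalibrated)))

  vst_tab <- run_stage("vst", {
    do.call(rbind, lapply(rownames(cne$cn), function(p) {
      v <- vst(cne$cn[p, ], sim$counts$samples$population)
      cbind(probe_id = p, v)
    }))
  })
  log_stage("vst", sprintf("probes=%d differentiated=%d", nrow(vst_tab),
                           nrow(flag_differentiated(vst_tab, config$vst_threshold))))

  panel <- run_stage("filter_snps", {
    filter_snps(encode_panel(sim$snps$panel), maf_min = config$maf_min,
                hwe_alpha = config$hwe_alpha)
  })
  log_stage("filter_snps", paste(names(attr(panel, "funnel")),
                                 attr(panel, "funnel"), sep = "=", collapse = " "))

  pos <- probe_positions(sim$truth)
  win_snp <- lapply(rownames(cne$cn), function(p)
    build_windows(data.frame(chrom = pos$chrom[pos$probe_id == p],
                             start = pos$start[pos$probe_id == p],
                             end = pos$end[pos$probe_id == p],
                             probe_id = p, percent_identity = 98),
                  flank_bp = config$flank_snp))
  names(win_snp) <- rownames(cne$cn)
  tag <- run_stage("tag_snp_scan", {
    do.call(rbind, lapply(rownames(cne$cn), function(p)
      tag_snp_scan(cne$cn[p, ], panel, win_snp[[p]], sim$counts$samples,
                   probe_id = p, n_permutations = config$n_perm_shuffle)))
  })
  log_stage("tag_snp_scan", sprintf("records=%d", nrow(tag)))

  win_feat <- lapply(rownames(cne$cn), function(p)
    build_windows(data.frame(chrom = pos$chrom[pos$probe_id == p],
                             start = pos$start[pos$probe_id == p],
                             end = pos$end[pos$probe_id == p],
                             probe_id = p, percent_identity = 98),
                  flank_bp = config$flank_feature, exclude_unplaced = TRUE))
  names(win_feat) <- rownames(cne$cn)
  expr_rec <- run_stage("expression_scan", {
    do.call(rbind, lapply(rownames(cne$cn), function(p)
      expression_scan(cne$cn[p, ], sim$expr$expr, win_feat[[p]],
                      sim$counts$samples, probe_id = p,
                      n_permutations = config$n_perm_shuffle)))
  })
  log_stage("expression_scan", sprintf("records=%d", nrow(expr_rec)))

  meth_res <- run_stage("methylation_pipeline", {
    ceu_yri <- sim$counts$samples[sim$counts$samples$population %in% c("CEU", "YRI"), ]
    methylation_pipeline(cne$cn[, ceu_yri$sample_id, drop = FALSE],
                         sim$meth$meth, win_feat,
                         sim$meth$pool[, ceu_yri$sample_id, drop = FALSE],
                         ceu_yri,
                         top_quantile = config$top_quantile,
                         slope_min = config$slope_min,
                         n_permutations = config$n_perm_pool)
  })
  log_stage("methylation_pipeline",
            paste(names(meth_res$funnel), meth_res$funnel, sep = "=", collapse = " "))

  out <- list(truth = sim$truth, counts = proc, cn = cne, vst = vst_tab,
              tag = tag, expression = expr_rec, methylation = meth_res,
              funnel = funnel, config = config)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(unclass(config)[setdiff(names(config), "outdir")],
                     file.path(config$outdir, "config.yaml"))
    write_count_matrix(cne$cn, file.path(config$outdir, "copy_number.tsv"))
    write_records(vst_tab, file.path(config$outdir, "vst.tsv"))
    write_records(tag, file.path(config$outdir, "tag_snps.tsv"))
    write_records(expr_rec, file.path(config$outdir, "expression.tsv"))
    write_records(meth_res$records, file.path(config$outdir, "methylation.tsv"))
    writeLines(funnel, file.path(config$outdir, "funnel.log"))
  }
  out
}

#' Fold reduction in SNP density from mean marker spacings
#'
#' Mean spacing inside the assayed regions divided by the genome-wide mean
#' spacing; spacings may be given directly or derived as region length
#' over SNP count.
#'
#' @param region_spacing_bp Mean bp per SNP inside the regions.
#' @param genome_spacing_bp Genome-wide mean bp per SNP.
#' @return Fold reduction (dimensionless).
#' @export
snp_density_fold_reduction <- function(region_spacing_bp, genome_spacing_bp) {
  stopifnot(region_spacing_bp > 0, genome_spacing_bp > 0)
  region_spacing_bp / genome_spacing_bp
}
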