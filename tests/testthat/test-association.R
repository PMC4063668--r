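test_that("genotype encoding designates the alphabetically first allele", {
  codes <- encode_genotypes(c("AA", "AG", "GG", NA))
  expect_equal(as.integer(codes), c(0L, 1L, 2L, NA))
  expect_equal(attr(codes, "designated_allele"), "A")
  expect_error(encode_genotypes(c("AA", "AG", "AT")), "more than two")
  # monomorphic is fine here (dropped later by the MAF filter)
  expect_equal(as.integer(encode_genotypes(c("AA", "AA"))), c(0L, 0L))
})

test_that("allele orientation flips the sign of r but never R-squared", {
  set.seed(51)
  codes <- stats::rbinom(40, 2, 0.4)
  y <- codes * 2 + stats::rnorm(40, 0, 0.5)
  a <- correlate(codes, y)
  b <- correlate(2L - codes, y)
  expect_equal(b$r, -a$r, tolerance = 1e-12)
  expect_equal(b$r2, a$r2, tolerance = 1e-12)
})

test_that("HWE chi-square test matches the expected-count formula", {
  expect_equal(hwe_test(25, 50, 25), 1)
  p0 <- hwe_test(0, 100, 0)  # chi-square = 100
  expect_lt(p0, 1e-20)
  expect_equal(p0, stats::pchisq(100, 1, lower.tail = FALSE))
  expect_equal(hwe_test(30, 0, 0), 1)  # monomorphic
  set.seed(52)
  for (i in 1:20) {
    n3 <- as.integer(stats::rmultinom(1, 80, c(0.3, 0.5, 0.2)))
    expect_equal(hwe_test(n3[1], n3[2], n3[3]),
                 oracle_hwe_p(n3[1], n3[2], n3[3]), tolerance = 1e-12)
  }
})

test_that("SNP filtering applies MAF, HWE and tri-allelic rules like the oracle", {
  set.seed(53)
  n_s <- 80
  snps <- data.frame(snp_id = paste0("rs", 1:30), chrom = "chr1",
                     pos = seq_len(30) * 100L)
  calls <- matrix("AA", 30, n_s, dimnames = list(snps$snp_id, paste0("s", 1:n_s)))
  for (i in 1:30) {
    maf <- stats::runif(1, 0.02, 0.5)
    g <- stats::rbinom(n_s, 2, maf)
    calls[i, ] <- c("AA", "AG", "GG")[g + 1]
  }
  calls[5, 1] <- "AT"  # make rs5 tri-allelic
  calls[9, ] <- rep(c("AA", "GG"), n_s / 2)  # het deficit: HWE failure
  panel <- encode_panel(snp_panel(snps, calls))
  filtered <- filter_snps(panel, maf_min = 0.1, hwe_alpha = 0.05)
  # rule-by-rule oracle
  keep_oracle <- vapply(1:30, function(i) {
    if (length(unique(unlist(strsplit(calls[i, ], "")))) > 2) return(FALSE)
    g <- encode_genotypes(calls[i, ])
    f <- mean(g) / 2
    if (min(f, 1 - f) < 0.1) return(FALSE)
    oracle_hwe_p(sum(g == 0), sum(g == 1), sum(g == 2)) >= 0.05
  }, TRUE)
  expect_setequal(filtered$snps$snp_id, snps$snp_id[keep_oracle])
  expect_false("rs5" %in% filtered$snps$snp_id)
  expect_false("rs9" %in% filtered$snps$snp_id)
  fn <- attr(filtered, "funnel")
  expect_equal(unname(fn["input"] - fn["tri_allelic"] - fn["low_maf"] - fn["hwe_fail"]),
               unname(fn["output"]))
})

test_that("stringent filtering additionally drops externally flagged SNPs", {
  snps <- data.frame(snp_id = c("ok", "seg", "cnv"), chrom = "chr1",
                     pos = c(100L, 200L, 300L),
                     in_segdup = c(FALSE, TRUE, FALSE),
                     in_cnv = c(FALSE, FALSE, TRUE))
  set.seed(54)
  g <- matrix(stats::rbinom(3 * 60, 2, 0.4), 3, 60)
  calls <- matrix(c("AA", "AG", "GG")[g + 1], 3, 60,
                  dimnames = list(snps$snp_id, paste0("s", 1:60)))
  panel <- snp_panel(snps, calls)
  basic <- filter_snps(panel)
  strict <- filter_snps(panel, stringent = TRUE)
  expect_true(all(c("seg", "cnv") %in% basic$snps$snp_id))
  expect_equal(strict$snps$snp_id, "ok")
})

test_that("correlate recovers exact linear relations and skips degenerate input", {
  x <- c(1, 2, 3, 4, 5, 6)
  res <- correlate(x, 2 * x)
  expect_equal(res$r, 1)
  expect_equal(res$slope, 2)
  rho <- correlate(x, x^3, method = "spearman")
  expect_equal(rho$r, 1)  # monotone
  expect_null(correlate(x, rep(3, 6)))
  expect_null(correlate(x[1:2], (2 * x)[1:2]))  # too few pairs
})

test_that("spearman rho equals the rank-then-Pearson oracle with ties", {
  set.seed(55)
  for (i in 1:20) {
    x <- sample(1:4, 10, replace = TRUE)  # ties guaranteed
    y <- stats::rnorm(10)
    res <- correlate(x, y, method = "spearman")
    expect_equal(res$r, oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("pearson and spearman match textbook oracles on random fixtures", {
  set.seed(56)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    res <- correlate(x, y)
    mx <- mean(x); my <- mean(y)
    r_oracle <- sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
    expect_equal(res$r, r_oracle, tolerance = 1e-12)
    expect_equal(res$slope, sum((x - mx) * (y - my)) / sum((x - mx)^2),
                 tolerance = 1e-12)
  }
})

test_that("permutation p-values use the strict two-tailed rule with a zero flag", {
  set.seed(57)
  x <- 1:20 + stats::rnorm(20, 0, 0.01)
  y <- 1:20
  obs <- correlate(x, y)$r
  perm <- permutation_p(obs, x, y, n_permutations = 200)
  expect_equal(perm$p_perm, 0)
  expect_true(perm$below_resolution)
  # an observed statistic of 0 on continuous data is never beaten by fewer
  # than all draws
  perm0 <- permutation_p(0, stats::rnorm(20), stats::rnorm(20), 200)
  expect_gt(perm0$p_perm, 0.9)
})

test_that("fixed seeds reproduce permutation p-values bit-for-bit", {
  x <- stats::rnorm(30); y <- stats::rnorm(30)
  obs <- correlate(x, y)$r
  set.seed(58); p1 <- permutation_p(obs, x, y, 500)$p_perm
  set.seed(58); p2 <- permutation_p(obs, x, y, 500)$p_perm
  expect_identical(p1, p2)
})

test_that("statistics are invariant under a common sample relabeling", {
  set.seed(59)
  x <- stats::rnorm(25); y <- x + stats::rnorm(25)
  perm <- sample(25)
  a <- correlate(x, y); b <- correlate(x[perm], y[perm])
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_equal(normalized_slope(y, x), normalized_slope(y[perm], x[perm]),
               tolerance = 1e-12)
})

test_that("normalized slope is OLS slope times observed CN range", {
  cn <- c(0, 2, 4, 6, 8, 10)
  beta <- 0.01 * cn + 0.2
  expect_equal(as.numeric(normalized_slope(beta, cn)), 0.1)
  expect_equal(as.numeric(normalized_slope(rep(0.4, 6), cn)), 0)
  z <- normalized_slope(c(0.1, 0.2, 0.3), c(5, 5, 5))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "zero_range"))
  set.seed(60)
  cnn <- stats::runif(30, 2, 20); b <- 0.02 * cnn + stats::rnorm(30, 0, 0.01)
  fit <- stats::lm(b ~ cnn)
  expect_equal(as.numeric(normalized_slope(b, cnn)),
               unname(stats::coef(fit)[2]) * (max(cnn) - min(cnn)),
               tolerance = 1e-12)
})

test_that("a planted perfect tag is found with R-squared 1", {
  set.seed(61)
  truth <- simulate_truth(n_test = 1, sigma = 0)
  sim <- simulate_snps(truth, n_snps_per_probe = 15,
                       planted_tags = data.frame(probe_id = "T001", target_r2 = 1))
  panel <- filter_snps(encode_panel(sim$panel))
  pos <- data.frame(chrom = "chr1", start = 2e6, end = 2e6 + 100,
                    probe_id = "T001", percent_identity = 98)
  w <- build_windows(pos, flank_bp = 250000)
  rec <- tag_snp_scan(truth$true_cn["T001", ], panel, w, truth$samples,
                      probe_id = "T001", n_permutations = 100)
  comb <- rec[rec$population_set == "combined", ]
  # genotype is a deterministic monotone function of CN quantile groups;
  # with a continuous CN spread the dosage correlation is high, not exact
  expect_equal(comb$feature_id, sim$planted$snp_id)
  expect_gt(comb$r2, 0.7)
  expect_lt(comb$p_perm, 0.05)
})

test_that("sex-chromosome probes are scanned per sex within populations", {
  set.seed(62)
  truth <- simulate_truth(n_test = 1, sigma = 0, probe_chrom = "chrX")
  sim <- simulate_snps(truth, n_snps_per_probe = 5)
  panel <- filter_snps(encode_panel(sim$panel))
  w <- data.frame(chrom = "chrX", start = 0L, end = 5e6L)
  rec <- tag_snp_scan(truth$true_cn["T001", ], panel, w, truth$samples,
                      probe_id = "T001", chrom = "chrX", n_permutations = 50)
  expect_true(all(grepl("_(male|female)$", rec$population_set)))
  expect_equal(nrow(rec), 8L)  # 4 population sets x 2 sexes
})

test_that("transcript filters remove low-expression and low-IQR transcripts", {
  n <- 20
  expr <- rbind(low_mean = stats::rnorm(n, 5.9, 1),
                low_iqr = rep(7, n),
                ok = stats::rnorm(n, 8, 1))
  # force exact filter conditions
  expr["low_mean", ] <- expr["low_mean", ] - mean(expr["low_mean", ]) + 5.9
  expr["low_iqr", ] <- 7 + seq(-0.1, 0.1, length.out = n) * 0.2  # IQR ~ 0.02
  colnames(expr) <- paste0("s", 1:n)
  kept <- filter_transcripts(expr)
  expect_equal(kept, "ok")
  # boundary: mean exactly 6 and IQR exactly 0.25 are kept (rules are strict <)
  e2 <- rbind(at_mean = rep(c(5, 7), n / 2), at_iqr = rep(c(7, 7.25), n / 2))
  colnames(e2) <- paste0("s", 1:n)
  expect_equal(stats::IQR(e2["at_iqr", ]), 0.25)
  expect_setequal(filter_transcripts(e2), c("at_mean", "at_iqr"))
})

test_that("a planted cis expression effect is recovered with the right sign", {
  set.seed(63)
  truth <- simulate_truth(n_test = 1, sigma = 0)
  sim <- simulate_expression(truth, n_transcripts_per_probe = 6,
                             planted_effects = data.frame(probe_id = "T001",
                                                          slope = -0.08),
                             noise_sd = 0.3)
  w <- data.frame(chrom = "chr1", start = 1.5e6, end = 2.6e6)
  rec <- expression_scan(truth$true_cn["T001", ], sim$expr, w, truth$samples,
                         probe_id = "T001", target_gene = sim$planted$transcript_id,
                         n_permutations = 200)
  hit <- rec[rec$feature_id == sim$planted$transcript_id &
               rec$population_set == "combined", ]
  expect_lt(hit$r, 0)
  expect_lt(hit$p_perm, 0.05)
  expect_true(hit$auto_correlated)
  null_hits <- rec[rec$feature_id != sim$planted$transcript_id, ]
  expect_false(any(null_hits$auto_correlated))
})

test_that("methylation QC removes flagged, chrY and high-missingness probes", {
  set.seed(64)
  ids <- paste0("cg", 1:6)
  vals <- matrix(stats::runif(6 * 50), 6, 50, dimnames = list(ids, paste0("s", 1:50)))
  vals["cg4", 1:3] <- NA  # 6% missing
  coords <- data.frame(feature_id = ids,
                       chrom = c("chr1", "chrY", "chrX", "chr2", "chr2", "chr3"),
                       pos = 1:6 * 1000L)
  flags <- data.frame(feature_id = c("cg5", "cg6"),
                      multi_loci = c(TRUE, FALSE),
                      snp_overlap = c(FALSE, TRUE))
  qc <- methylation_qc(vals, coords, flags)
  expect_setequal(rownames(qc$autosomal$values), "cg1")
  expect_setequal(rownames(qc$chrx$values), "cg3")
  expect_equal(unname(qc$log["input"]), 6)
  # exactly 5% missing is kept (rule is > 5%)
  vals2 <- vals; vals2["cg4", ] <- stats::runif(50); vals2["cg4", 1:2] <- NA
  expect_lt(mean(is.na(vals2["cg4", ])), 0.05)
  qc2 <- methylation_qc(vals2, coords, flags)
  expect_true("cg4" %in% rownames(qc2$autosomal$values))
})

test_that("the staged methylation pipeline keeps a strong planted CpG only", {
  set.seed(65)
  samples <- default_sample_table(c(CEU = 30L, YRI = 30L))
  truth <- simulate_truth(n_test = 2, samples = samples, sigma = 0)
  sim <- simulate_methylation(truth, n_cpgs_per_probe = 40,
                              planted_effects = data.frame(probe_id = "T001",
                                                           normalized_slope = 0.3),
                              noise_sd = 0.02, n_pool = 1200)
  pos <- probe_positions(truth)
  wins <- lapply(seq_len(nrow(pos)), function(i)
    data.frame(chrom = pos$chrom[i], start = pos$start[i] - 5e5,
               end = pos$end[i] + 5e5))
  names(wins) <- pos$probe_id
  res <- methylation_pipeline(truth$true_cn, sim$meth, wins, sim$pool, samples,
                              n_permutations = 1000)
  expect_equal(unname(res$funnel["stage1_tested"]), 80)
  expect_true(sim$planted$cpg_id %in% res$records$feature_id)
  expect_true(all(abs(res$records$normalized_slope) > 0.1))
  expect_true(all(res$records$p_perm < 0.01))
  expect_true(all(res$records$p_CEU < 0.05 & res$records$p_YRI < 0.05))
  # funnel is monotone non-increasing
  expect_true(all(diff(res$funnel) <= 0))
})

test_that("a CpG below the top-rho cutoff is eliminated at stage 2", {
  set.seed(66)
  samples <- default_sample_table(c(CEU = 20L, YRI = 20L))
  truth <- simulate_truth(n_test = 1, samples = samples, sigma = 0)
  sim <- simulate_methylation(truth, n_cpgs_per_probe = 50, n_pool = 1200)
  pos <- probe_positions(truth)
  wins <- list(T001 = data.frame(chrom = pos$chrom, start = pos$start - 5e5,
                                 end = pos$end + 5e5))
  res <- methylation_pipeline(truth$true_cn, sim$meth, wins, sim$pool, samples,
                              n_permutations = 1000)
  # under the null, the top-2% stage keeps at most one of 50 pairs
  expect_lte(unname(res$funnel["stage2_top_rho"]), 1)
})

test_that("sliding-window enrichment: ratios, counts and the uniform-factor property", {
  L <- 1000L
  chip <- rep(1, L); input <- rep(1, L)
  tr <- sliding_window_enrichment(chip, input)
  expect_equal(nrow(tr), 10L)  # floor((1000 - 170)/85) + 1
  expect_true(all(abs(tr$ratio - 1) < 1e-12))
  # a uniform chip = 2 x input factor cancels after total-normalization
  tr2 <- sliding_window_enrichment(2 * input, input)
  expect_true(all(abs(tr2$ratio - 1) < 1e-12))
  # a local doubling shows up only in its windows
  chip3 <- input; chip3[1:170] <- 2
  tr3 <- sliding_window_enrichment(chip3, input)
  expect_gt(tr3$ratio[1], 1)
  expect_lt(tr3$ratio[10], 1)  # total-normalization depresses the rest
  # short regions yield an empty track; the window-count formula holds on a grid
  expect_equal(nrow(sliding_window_enrichment(rep(1, 100), rep(1, 100))), 0L)
  for (L in c(170, 171, 254, 255, 340, 1003)) {
    n <- nrow(sliding_window_enrichment(rep(1, L), rep(1, L)))
    expect_equal(n, (L - 170L) %/% 85L + 1L)
  }
})
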