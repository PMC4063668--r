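# Independent oracles, written by direct summation / brute force so they
# never share code paths with the package implementation.

# One-way variance decomposition by explicit sums.
oracle_vst <- function(values, groups) {
  groups <- as.character(groups)
  n <- length(values)
  m <- sum(values) / n
  v_total <- sum((values - m)^2) / (n - 1)
  v_within_num <- 0
  for (g in unique(groups)) {
    x <- values[groups == g]
    mg <- sum(x) / length(x)
    v_within_num <- v_within_num + length(x) * (sum((x - mg)^2) / (length(x) - 1))
  }
  v_within <- v_within_num / n
  (v_total - v_within) / v_total
}

# All-pairs containment scan (half-open windows).
oracle_features_in_windows <- function(windows, features) {
  hits <- character()
  for (i in seq_len(nrow(features))) {
    for (j in seq_len(nrow(windows))) {
      if (features$chrom[i] == windows$chrom[j] &&
          features$pos[i] >= windows$start[j] &&
          features$pos[i] < windows$end[j]) {
        hits <- c(hits, features$feature_id[i])
        break
      }
    }
  }
  unique(hits)
}

# Pairwise overlap check of annotation records for multicopy discovery.
oracle_is_multicopy <- function(annotation, gene) {
  rec <- annotation[annotation$gene_name == gene, , drop = FALSE]
  base <- sub("_random$", "", rec$chrom)
  for (i in seq_len(nrow(rec))) for (j in seq_len(nrow(rec))) {
    if (i == j || base[i] != base[j]) next
    disjoint <- rec$chrom[i] != rec$chrom[j] ||
      rec$end[i] <= rec$start[j] || rec$end[j] <= rec$start[i]
    if (disjoint) return(TRUE)
  }
  FALSE
}

# Rank-then-Pearson Spearman rho by explicit formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Sup-difference of empirical CDFs evaluated on the pooled support.
oracle_ks_D <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t), 0)))
}

# Brute-force variability classification.
oracle_classify <- function(mat, cv_threshold = 0.1, deviation = 0.30,
                            min_individuals = 2) {
  t(apply(mat, 1, function(v) {
    m <- mean(v)
    cv <- sqrt(sum((v - m)^2) / (length(v) - 1)) / m
    n_out <- 0
    for (x in v) if (x >= m * (1 + deviation) || x <= m * (1 - deviation))
      n_out <- n_out + 1
    c(cv = cv, n_out = n_out,
      variable = as.numeric(cv >= cv_threshold || n_out >= min_individuals))
  }))
}

# HWE chi-square p by the textbook expected-count route.
oracle_hwe_p <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  p <- (2 * nAA + nAB) / (2 * n)
  q <- 1 - p
  if (p <= 0 || q <= 0) return(1)
  e <- c(n * p^2, 2 * n * p * q, n * q^2)
  stats::pchisq(sum((c(nAA, nAB, nBB) - e)^2 / e), 1, lower.tail = FALSE)
}

# A tiny synthetic raw-count fixture shared by several tests.
make_small_run <- function(seed = 42, n_test = 6, sigma = 0.05, ...) {
  set.seed(seed)
  truth <- simulate_truth(n_test = n_test, sigma = sigma, ...)
  list(truth = truth, counts = simulate_counts(truth))
}
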