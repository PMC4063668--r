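# Canonical missing-value markers accepted on read; written back as "NA".
.missing_markers <- c("NA", "", "nan", "NaN")

#' Read a probes-by-samples count matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of probe
#' identifiers. Cells must be numeric or one of the accepted missing markers
#' (`"NA"`, empty, `"nan"`); missing cells become `NA`, never zero.
#'
#' @param path Path to a tab-delimited file.
#' @return Numeric matrix with probe row names and sample column names.
#' @export
read_count_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("count matrix needs a probe id column plus >=1 sample")
  probe_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(probe_ids))
    stop("duplicate probe ids: ", paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  m <- matrix(NA_real_, nrow = length(probe_ids), ncol = length(sample_ids),
              dimnames = list(probe_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    is_missing <- col %in% .missing_markers | is.na(col)
    vals <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(vals) & !is_missing)
    if (length(bad))
      stop(sprintf("malformed numeric cell at row '%s', column '%s': '%s'",
                   probe_ids[bad[1L]], sample_ids[j], col[bad[1L]]))
    vals[is_missing] <- NA_real_
    m[, j] <- vals
  }
  m
}

#' Write a numeric matrix as TSV
#'
#' Inverse of [read_count_matrix()]: first column holds row ids, header row
#' holds column ids, missing values written as `NA`.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the id column.
#' @export
write_count_matrix <- function(m, path, id_col = "probe_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read probe alignments from a BED-like TSV
#'
#' Columns: chrom, start, end, probe_id, percent_identity (score slot),
#' strand. Coordinates are 0-based half-open, the BED convention. A side
#' table supplies probe class and locus architecture.
#'
#' @param path Alignment BED path (no header).
#' @param class_path Optional TSV with header columns `probe_id`,
#'   `target_name`, `probe_class` (test/negative/invariant/gender) and
#'   `locus_type` (tandem/dispersed/unknown). Probes absent from the side
#'   table default to class "test", locus "unknown".
#' @return An object of class `probe_annotation`: list with `probes`
#'   (one row per probe) and `alignments` (one row per alignment).
#' @export
read_probe_bed <- function(path, class_path = NULL) {
  aln <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(aln) < 6L) stop("expected 6 columns: chrom start end probe_id identity strand")
  aln <- aln[, 1:6]
  colnames(aln) <- c("chrom", "start", "end", "probe_id", "percent_identity", "strand")
  aln$start <- as.integer(aln$start)
  aln$end <- as.integer(aln$end)
  aln$percent_identity <- as.numeric(aln$percent_identity)
  validate_alignments(aln)
  classes <- NULL
  if (!is.null(class_path))
    classes <- utils::read.delim(class_path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  probe_annotation(aln, classes)
}

#' Construct a probe annotation object
#'
#' @param alignments data.frame with columns chrom, start, end, probe_id,
#'   percent_identity, strand (0-based half-open coordinates).
#' @param probes Optional data.frame with probe_id, target_name, probe_class,
#'   locus_type; missing probes are filled with defaults. Probes with no
#'   alignments (negative/invariant controls) are allowed.
#' @return `probe_annotation` object.
#' @export
probe_annotation <- function(alignments, probes = NULL) {
  validate_alignments(alignments)
  ids <- unique(c(alignments$probe_id, probes$probe_id))
  tab <- data.frame(probe_id = ids,
                    target_name = ids,
                    probe_class = "test",
                    locus_type = "unknown",
                    stringsAsFactors = FALSE)
  if (!is.null(probes)) {
    if (anyDuplicated(probes$probe_id)) stop("duplicate probe_id in class table")
    i <- match(tab$probe_id, probes$probe_id)
    for (col in intersect(c("target_name", "probe_class", "locus_type"), colnames(probes))) {
      hit <- !is.na(i)
      tab[[col]][hit] <- probes[[col]][i[hit]]
    }
  }
  bad <- !tab$probe_class %in% c("test", "negative", "invariant", "gender")
  if (any(bad)) stop("unknown probe_class: ", paste(unique(tab$probe_class[bad]), collapse = ", "))
  n_aln <- table(factor(alignments$probe_id, levels = tab$probe_id))
  if (any(tab$probe_class == "test" & n_aln[tab$probe_id] == 0L))
    stop("test probes must have >=1 alignment")
  structure(list(probes = tab, alignments = alignments), class = "probe_annotation")
}

validate_alignments <- function(aln) {
  if (any(aln$start < 0L)) stop("negative alignment start")
  if (any(aln$start >= aln$end)) stop("alignment start >= end")
  if (any(aln$percent_identity < 0 | aln$percent_identity > 100))
    stop("percent_identity outside [0,100]")
  invisible(aln)
}

#' @export
print.probe_annotation <- function(x, ...) {
  cat(sprintf("probe_annotation: %d probes (%s), %d alignments\n",
              nrow(x$probes),
              paste(sprintf("%d %s", table(x$probes$probe_class),
                            names(table(x$probes$probe_class))), collapse = ", "),
              nrow(x$alignments)))
  invisible(x)
}

#' Read a sample table
#'
#' @param path TSV with header columns sample_id, population, sex and
#'   optionally species (default "human").
#' @return data.frame with validated, unique sample ids.
#' @export
read_sample_table <- function(path) {
  s <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (anyDuplicated(s$sample_id)) stop("duplicate sample_id")
  if (is.null(s$species)) s$species <- "human"
  if (is.null(s$sex)) s$sex <- "unknown"
  s
}

#' Read SNP genotypes from TSV or a VCF subset
#'
#' The TSV dialect has header columns `snp_id`, `chrom`, `pos` (1-based on
#' disk, stored 0-based) followed by one column per sample holding allele
#' pairs such as `"AA"` or `"AG"`. The VCF reader handles the GT field only
#' and converts numeric genotypes to allele pairs using REF/ALT.
#'
#' @param path Input path.
#' @param format "tsv" or "vcf".
#' @return A `snp_panel`: list with `snps` (snp_id, chrom, pos, alleles,
#'   tri_allelic flag and placeholders for external flags) and `calls`
#'   (character matrix SNPs x samples of allele pairs, NA for missing).
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    g <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
    need <- c("snp_id", "chrom", "pos")
    if (!all(need %in% colnames(g)[1:3])) stop("genotype TSV needs snp_id, chrom, pos columns")
    calls <- as.matrix(g[, -(1:3), drop = FALSE])
    calls[calls %in% c(.missing_markers, "NN", "--", "./.", "..")] <- NA_character_
    rownames(calls) <- g$snp_id
    snps <- data.frame(snp_id = g$snp_id, chrom = g$chrom,
                       pos = as.integer(g$pos) - 1L, stringsAsFactors = FALSE)
  } else {
    parsed <- .read_vcf_gt(path)
    snps <- parsed$snps
    calls <- parsed$calls
  }
  snp_panel(snps, calls)
}

# VCF v4.x subset via vcfR: CHROM/POS/ID/REF/ALT plus the per-sample GT
# subfield. Positions converted from 1-based to 0-based.
.read_vcf_gt <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(vcf)),
                dimnames = dimnames(vcfR::getFIX(vcf)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  snps <- data.frame(snp_id = unname(fix[, "ID"]),
                     chrom = unname(fix[, "CHROM"]),
                     pos = as.integer(fix[, "POS"]) - 1L,
                     stringsAsFactors = FALSE)
  calls <- matrix(NA_character_, nrow = nrow(snps), ncol = ncol(gt),
                  dimnames = list(snps$snp_id, colnames(gt)))
  for (i in seq_len(nrow(snps))) {
    alleles <- c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]])
    parts <- strsplit(gt[i, ], "[/|]")
    calls[i, ] <- vapply(parts, function(p) {
      if (length(p) != 2L || anyNA(p) || any(p == ".")) return(NA_character_)
      paste0(alleles[as.integer(p) + 1L], collapse = "")
    }, "")
  }
  list(snps = snps, calls = calls)
}

#' Construct a SNP panel
#'
#' Computes the per-SNP allele inventory and flags tri-allelic sites.
#' External annotation flags (multi-mapping within 51 bp, segmental
#' duplication overlap, CNV overlap) default to FALSE and are inputs, not
#' computed here.
#'
#' @param snps data.frame with snp_id, chrom, pos (0-based).
#' @param calls Character matrix SNPs x samples of allele pairs.
#' @return `snp_panel` object.
#' @export
snp_panel <- function(snps, calls) {
  if (anyDuplicated(snps$snp_id)) {
    dup <- snps$snp_id[duplicated(snps$snp_id)]
    conflict <- vapply(unique(dup), function(id) {
      i <- snps$snp_id == id
      length(unique(paste(snps$chrom[i], snps$pos[i]))) > 1L
    }, TRUE)
    if (any(conflict))
      stop("position conflict for SNP id(s): ", paste(unique(dup)[conflict], collapse = ", "))
    stop("duplicate SNP ids: ", paste(unique(dup), collapse = ", "))
  }
  inventory <- apply(calls, 1L, function(row) {
    alleles <- unlist(strsplit(row[!is.na(row)], ""))
    sort(unique(alleles))
  }, simplify = FALSE)
  snps$alleles <- vapply(inventory, paste, "", collapse = ",")
  snps$tri_allelic <- lengths(inventory) > 2L
  for (fl in c("multi_mapped_51bp", "in_segdup", "in_cnv"))
    if (is.null(snps[[fl]])) snps[[fl]] <- FALSE
  structure(list(snps = snps, calls = calls), class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("snp_panel: %d SNPs x %d samples (%d tri-allelic)\n",
              nrow(x$snps), ncol(x$calls), sum(x$snps$tri_allelic)))
  invisible(x)
}

#' Write association (or any) records to TSV
#'
#' Stable column order, floats at fixed precision, missing values as "NA".
#'
#' @param records data.frame.
#' @param path Output path.
#' @param digits Significant digits for numeric columns.
#' @export
write_records <- function(records, path, digits = 6L) {
  out <- records
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read records written by [write_records()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_records <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a positioned feature matrix (expression or methylation)
#'
#' @param path TSV whose first three columns are feature_id, chrom, pos
#'   (1-based anchor on disk: TSS or CpG position), followed by samples.
#' @return list with `values` (numeric matrix), `coords` (data.frame
#'   feature_id, chrom, pos 0-based).
#' @export
read_feature_matrix <- function(path) {
  g <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("feature_id", "chrom", "pos")
  if (!all(need %in% colnames(g)[1:3])) stop("feature matrix needs feature_id, chrom, pos")
  if (anyDuplicated(g$feature_id)) stop("duplicate feature ids")
  vals <- g[, -(1:3), drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(g$feature_id, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    col <- vals[[j]]
    miss <- col %in% .missing_markers | is.na(col)
    v <- suppressWarnings(as.numeric(col))
    if (any(is.na(v) & !miss))
      stop(sprintf("malformed numeric cell in column '%s'", colnames(vals)[j]))
    v[miss] <- NA_real_
    m[, j] <- v
  }
  list(values = m,
       coords = data.frame(feature_id = g$feature_id, chrom = g$chrom,
                           pos = as.integer(g$pos) - 1L, stringsAsFactors = FALSE))
}

#' Write a positioned feature matrix
#' @param values Numeric matrix features x samples.
#' @param coords data.frame feature_id, chrom, pos (0-based in memory).
#' @param path Output path.
#' @export
write_feature_matrix <- function(values, coords, path) {
  stopifnot(identical(rownames(values), coords$feature_id))
  df <- data.frame(feature_id = coords$feature_id, chrom = coords$chrom,
                   pos = coords$pos + 1L, values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
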