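# Multicopy-gene discovery and analysis-window construction around probe
# alignments. All coordinates are 0-based half-open.

#' Discover multicopy genes from a gene annotation table
#'
#' A gene qualifies when it has at least two annotation records at
#' non-overlapping positions on the same chromosome, counting a
#' chromosome's "_random" scaffold together with its placed sequence.
#' Overlapping records (isoforms of one locus) collapse to a single copy;
#' the copy count is the size of a maximal set of mutually non-overlapping
#' records, found by greedy interval scheduling on end-sorted records.
#'
#' @param annotation data.frame with columns gene_name, chrom, start, end
#'   (0-based half-open). May contain many overlapping isoform records.
#' @return data.frame (gene_name, copy_count) for genes with copy_count >= 2,
#'   sorted by gene_name. Empty annotation yields an empty result.
#' @export
discover_multicopy_genes <- function(annotation) {
  if (nrow(annotation) == 0L)
    return(data.frame(gene_name = character(), copy_count = integer()))
  stopifnot(all(annotation$start < annotation$end))
  base_chrom <- sub("_random$", "", annotation$chrom)
  key <- paste(annotation$gene_name, base_chrom, sep = "\r")
  counts <- vapply(split(seq_len(nrow(annotation)), key), function(idx) {
    rec <- annotation[idx, , drop = FALSE]
    # records on different scaffolds (chrN vs chrN_random) never overlap
    sum(vapply(split(seq_len(nrow(rec)), rec$chrom), function(i) {
      r <- rec[i, , drop = FALSE]
      ord <- order(r$end, r$start, r$gene_name)
      n <- 0L; last_end <- -Inf
      for (k in ord) {
        if (r$start[k] >= last_end) { n <- n + 1L; last_end <- r$end[k] }
      }
      n
    }, integer(1L)))
  }, integer(1L))
  gene <- vapply(strsplit(names(counts), "\r", fixed = TRUE), `[`, "", 1L)
  per_gene <- vapply(split(counts, gene), max, integer(1L))
  hit <- per_gene >= 2L
  out <- data.frame(gene_name = names(per_gene)[hit],
                    copy_count = as.integer(per_gene[hit]),
                    stringsAsFactors = FALSE)
  out[order(out$gene_name), , drop = FALSE]
}

#' Build flanking analysis windows around a probe's alignments
#'
#' One window per qualifying alignment, `[start - flank, end + flank)`
#' clipped at zero; windows overlapping on the same chromosome are merged.
#' Alignments below the identity threshold are excluded, as are chrY and
#' "_random" scaffold alignments when `exclude_unplaced = TRUE` (used for
#' the methylation analysis).
#'
#' @param probe A `probe_annotation`, or a data.frame of alignments with
#'   columns chrom, start, end, percent_identity (and probe_id).
#' @param probe_id Which probe to build windows for (required when `probe`
#'   holds several).
#' @param flank_bp Flank in bp on each side (> 0); 250 kb for the tag-SNP
#'   scan, 500 kb for expression/methylation.
#' @param min_identity Minimum percent identity for an alignment to seed a
#'   window (default 95).
#' @param exclude_unplaced Drop chrY and "*_random" alignments.
#' @return data.frame (chrom, start, end) of merged, disjoint windows,
#'   sorted by chrom then start, with attribute `probe_id`. Zero qualifying
#'   alignments give an empty set with a warning.
#' @export
build_windows <- function(probe, flank_bp, min_identity = 95,
                          exclude_unplaced = FALSE, probe_id = NULL) {
  stopifnot(flank_bp > 0)
  aln <- if (inherits(probe, "probe_annotation")) probe$alignments else probe
  if (!is.null(probe_id)) aln <- aln[aln$probe_id == probe_id, , drop = FALSE]
  else if (!is.null(aln$probe_id) && length(unique(aln$probe_id)) == 1L)
    probe_id <- aln$probe_id[1L]
  keep <- aln$percent_identity >= min_identity
  if (exclude_unplaced)
    keep <- keep & aln$chrom != "chrY" & !grepl("_random$", aln$chrom)
  aln <- aln[keep, , drop = FALSE]
  if (nrow(aln) == 0L) {
    warning("no qualifying alignments for probe ",
            if (is.null(probe_id)) "<unnamed>" else probe_id)
    out <- data.frame(chrom = character(), start = integer(), end = integer())
    attr(out, "probe_id") <- probe_id
    return(out)
  }
  start <- pmax(0L, aln$start - as.integer(flank_bp))
  end <- aln$end + as.integer(flank_bp)
  merged <- do.call(rbind, lapply(split(seq_along(start), aln$chrom), function(i) {
    # IRanges works on closed integer intervals; represent [s, e) as [s, e-1]
    r <- IRanges::reduce(IRanges::IRanges(start = start[i], end = end[i] - 1L))
    data.frame(chrom = aln$chrom[i[1L]],
               start = IRanges::start(r), end = IRanges::end(r) + 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]
  attr(merged, "probe_id") <- probe_id
  merged
}

#' Features whose anchor falls inside a window set
#'
#' Containment is half-open: a feature at the window start is included, one
#' at the window end coordinate is not. Each feature is returned at most
#' once even when covered by several windows. Features lacking coordinates
#' are skipped (count reported via message).
#'
#' @param windows data.frame (chrom, start, end) as from [build_windows()].
#' @param features data.frame with feature_id, chrom, pos (0-based single
#'   anchor: SNP position, TSS, or CpG position).
#' @return Character vector of feature ids, in `features` order.
#' @export
features_in_windows <- function(windows, features) {
  no_coord <- is.na(features$chrom) | is.na(features$pos)
  if (any(no_coord))
    message(sum(no_coord), " feature(s) without coordinates skipped")
  feats <- features[!no_coord, , drop = FALSE]
  if (nrow(windows) == 0L || nrow(feats) == 0L) return(character())
  hit <- logical(nrow(feats))
  for (chr in unique(windows$chrom)) {
    w <- windows[windows$chrom == chr, , drop = FALSE]
    fi <- which(feats$chrom == chr)
    if (!length(fi)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = feats$pos[fi], width = 1L),
      IRanges::IRanges(start = w$start, end = w$end - 1L))
    hit[fi[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  unique(feats$feature_id[hit])
}

#' Summarize alignments per probe
#'
#' Mean and median number of genomic alignments per probe at an identity
#' threshold, as reported for probe-design audit tables.
#'
#' @param annotation `probe_annotation` or alignment data.frame.
#' @param min_identity Only count alignments at or above this identity
#'   (default 0: all).
#' @return list(mean, median, n_probes, per_probe).
#' @export
summarize_alignments <- function(annotation, min_identity = 0) {
  aln <- if (inherits(annotation, "probe_annotation")) annotation$alignments else annotation
  aln <- aln[aln$percent_identity >= min_identity, , drop = FALSE]
  per <- table(aln$probe_id)
  list(mean = mean(per), median = stats::median(as.numeric(per)),
       n_probes = length(per), per_probe = per)
}
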