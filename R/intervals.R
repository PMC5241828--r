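#' Read a BED-family file as an interval set
#'
#' Supports BED3, BED6 and the ENCODE 10-column narrowPeak dialect (all
#' tab-separated, no header, 0-based half-open coordinates). Parsing is
#' delegated to [rtracklayer::import]; intervals are then validated against
#' the genome and returned in canonical sort order.
#'
#' Intervals on chromosomes absent from `genome` are handled per
#' `on_unknown_chrom`: `"drop"` (default) removes them with a warning giving
#' the count -- mirroring the exclusion of peaks on unlocalized contigs from
#' a final peak set -- while `"strict"` raises an error.
#'
#' @param path Path to the file.
#' @param genome A `Seqinfo` genome.
#' @param format One of `"bed3"`, `"bed6"`, `"narrowPeak"`.
#' @param on_unknown_chrom `"drop"` or `"strict"`.
#' @return A `GRanges` on `genome`, canonically sorted.
#' @export
read_bed <- function(path, genome, format = c("bed3", "bed6", "narrowPeak"),
                     on_unknown_chrom = c("drop", "strict")) {
  format <- match.arg(format)
  on_unknown_chrom <- match.arg(on_unknown_chrom)
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- if (format == "narrowPeak") {
    rtracklayer::import(path, format = "BED",
      extraCols = c(signalValue = "numeric", pValue = "numeric",
                    qValue = "numeric", peak = "integer"))
  } else {
    rtracklayer::import(path, format = "BED")
  }
  known <- as.character(GenomicRanges::seqnames(gr)) %in%
    GenomeInfoDb::seqnames(genome)
  if (any(!known)) {
    if (on_unknown_chrom == "strict")
      stop("intervals on unknown chromosome(s): ",
           paste(unique(as.character(GenomicRanges::seqnames(gr))[!known]),
                 collapse = ", "))
    warning(sum(!known), " interval(s) on unknown chromosomes dropped")
    gr <- gr[known]
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  mc <- S4Vectors::mcols(gr)
  out <- interval_set(df$chrom, df$start, df$end, genome)
  keep <- intersect(colnames(mc), c("name", "score", "signalValue",
                                    "pValue", "qValue", "peak"))
  if (format == "bed3") keep <- character(0)
  if (length(keep)) {
    ord <- order(factor(df$chrom, levels = GenomeInfoDb::seqnames(genome)),
                 df$start, df$end)
    S4Vectors::mcols(out) <- mc[ord, keep, drop = FALSE]
  }
  out
}

#' Write an interval set as BED
#'
#' BED6 when `name`/`score` metadata is present (missing fields filled with
#' `"."` / `0`), BED3 otherwise. Tab-separated, no header, 0-based
#' half-open.
#'
#' @param x A `GRanges` interval set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- as_bed_frame(x)
  cols <- df[, c("chrom", "start", "end")]
  if (any(c("name", "score") %in% names(df))) {
    cols$name <- if ("name" %in% names(df)) as.character(df$name) else "."
    cols$name[is.na(cols$name)] <- "."
    cols$score <- if ("score" %in% names(df)) df$score else 0
    cols$score[is.na(cols$score)] <- 0
    cols$strand <- "."
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge an interval set
#'
#' Returns the minimal set of non-overlapping, non-abutting intervals
#' covering exactly the same bases. Under the half-open convention abutting
#' intervals (e.g. `[0,100)` and `[100,200)`) coalesce.
#'
#' @param x A `GRanges` interval set.
#' @return A merged `GRanges`.
#' @export
merge_intervals <- function(x) {
  GenomicRanges::reduce(x)
}

#' Base-level intersection of two interval sets
#'
#' @param a,b `GRanges` on the same genome.
#' @return Merged `GRanges` of the bases present in both.
#' @export
intersect_intervals <- function(a, b) {
  check_same_genome(a, b)
  GenomicRanges::intersect(a, b)
}

# total bases of each query interval covered by the (merged) reference set
total_overlap_bp <- function(query, reference_merged) {
  hits <- GenomicRanges::findOverlaps(query, reference_merged)
  out <- numeric(length(query))
  if (length(hits)) {
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      query[S4Vectors::queryHits(hits)],
      reference_merged[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

check_same_genome <- function(...) {
  sets <- list(...)
  ref <- GenomeInfoDb::seqinfo(sets[[1L]])
  for (s in sets[-1L]) {
    si <- GenomeInfoDb::seqinfo(s)
    if (!identical(GenomeInfoDb::seqnames(ref), GenomeInfoDb::seqnames(si)) ||
        !identical(GenomeInfoDb::seqlengths(ref), GenomeInfoDb::seqlengths(si)))
      stop("interval sets are on different genomes")
  }
  invisible(TRUE)
}

#' Peak-level control subtraction
#'
#' Drops every peak covered by the control set over at least
#' `min_overlap_bp` bases in total; peaks are kept or removed whole. This
#' is the peak-level analogue of subtracting a mock/control pulldown (e.g.
#' GST alone) from a binding-site set.
#'
#' @param peaks,control `GRanges` on the same genome.
#' @param min_overlap_bp Minimum overlap in bp for a peak to be removed
#'   (>= 1).
#' @return The surviving peaks, in input form (not merged).
#' @export
subtract_control <- function(peaks, control, min_overlap_bp = 1L) {
  check_same_genome(peaks, control)
  if (min_overlap_bp < 1) stop("min_overlap_bp must be >= 1")
  if (length(control) == 0L) return(peaks)
  ov <- total_overlap_bp(peaks, merge_intervals(control))
  peaks[ov < min_overlap_bp]
}

#' Replicate-consensus binding sites
#'
#' The union-of-common-sites operator: every pair of replicate peaks
#' overlapping by at least `min_overlap_bp` contributes a consensus site.
#' With `mode = "union"` (default) the site is the union span of the pair;
#' `"intersection"` keeps the shared bases; `"rep1"`/`"rep2"` keep the
#' coordinates of the respective replicate's member of the pair. Emitted
#' sites are merged.
#'
#' @param rep1,rep2 `GRanges` on the same genome.
#' @param min_overlap_bp Minimum reciprocal overlap in bp (>= 1).
#' @param mode Consensus coordinate rule; see Details.
#' @return Merged `GRanges` of consensus sites.
#' @export
consensus_union <- function(rep1, rep2, min_overlap_bp = 1L,
                            mode = c("union", "intersection", "rep1", "rep2")) {
  mode <- match.arg(mode)
  check_same_genome(rep1, rep2)
  if (min_overlap_bp < 1) stop("min_overlap_bp must be >= 1")
  hits <- GenomicRanges::findOverlaps(rep1, rep2,
                                      minoverlap = min_overlap_bp)
  if (length(hits) == 0L)
    return(merge_intervals(rep1[0]))
  i <- rep1[S4Vectors::queryHits(hits)]
  j <- rep2[S4Vectors::subjectHits(hits)]
  out <- switch(mode,
    union = GenomicRanges::punion(i, j, fill.gap = TRUE),
    intersection = GenomicRanges::pintersect(i, j),
    rep1 = i,
    rep2 = j
  )
  merge_intervals(out)
}

#' Count query intervals overlapping a reference set
#'
#' A query interval counts as overlapping when at least `min_overlap_bp`
#' of its bases are covered by the merged reference set (the overlap may
#' be split across reference intervals).
#'
#' @param query,reference `GRanges` on the same genome.
#' @param min_overlap_bp Minimum overlap in bp (>= 1).
#' @return Named numeric vector `c(n_overlapping, n_total)`.
#' @export
overlap_counts <- function(query, reference, min_overlap_bp = 1L) {
  check_same_genome(query, reference)
  if (min_overlap_bp < 1) stop("min_overlap_bp must be >= 1")
  ov <- total_overlap_bp(query, merge_intervals(reference))
  c(n_overlapping = sum(ov >= min_overlap_bp), n_total = length(query))
}

#' Fraction of the genome covered by an interval set
#'
#' Merged base count of `regions` divided by total genome size; the
#' "expected by chance" denominator for region enrichment.
#'
#' @param regions A `GRanges` interval set.
#' @param genome A `Seqinfo` genome (defaults to the set's own).
#' @return Fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(regions, genome = GenomeInfoDb::seqinfo(regions)) {
  covered <- sum(as.numeric(GenomicRanges::width(merge_intervals(regions))))
  covered / genome_size(genome)
}
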