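#' Construct a genome (ordered chromosomes with lengths)
#'
#' The genome is the coordinate frame for all interval work. It is
#' represented as a [GenomeInfoDb::Seqinfo] object, the standard
#' Bioconductor container for chromosome names and lengths. Chromosome
#' order is the order given here and governs the canonical sort order of
#' every interval set built on the genome.
#'
#' @param names Character vector of unique, non-empty chromosome names.
#' @param lengths Integer vector of chromosome lengths in bp (all > 0).
#' @return A `Seqinfo` object.
#' @examples
#' g <- make_genome(c("chr1", "chr2"), c(10000, 5000))
#' genome_size(g)
#' @export
make_genome <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) == 0L) stop("genome must have at least one chromosome")
  if (anyDuplicated(names)) stop("chromosome names must be unique")
  if (any(!nzchar(names))) stop("chromosome names must be non-empty")
  if (length(lengths) != length(names))
    stop("names and lengths must have equal length")
  if (any(!is.finite(lengths)) || any(lengths <= 0) ||
      any(lengths != floor(lengths)))
    stop("chromosome lengths must be positive integers")
  GenomeInfoDb::Seqinfo(seqnames = names, seqlengths = as.integer(lengths))
}

#' Read a chrom.sizes table
#'
#' Two-column tab-separated file (chromosome name, length in bp), no header
#' -- the UCSC `chrom.sizes` convention.
#'
#' @param path Path to the file.
#' @return A `Seqinfo` genome.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("name", "length"),
                           colClasses = c("character", "numeric"))
  make_genome(tab$name, tab$length)
}

#' Total genome size in bp
#'
#' @param genome A `Seqinfo` genome.
#' @return Numeric scalar, the sum of chromosome lengths.
#' @export
genome_size <- function(genome) {
  sum(as.numeric(GenomeInfoDb::seqlengths(genome)))
}

#' One full-length interval per chromosome
#'
#' @param genome A `Seqinfo` genome.
#' @return A `GRanges` covering every chromosome end to end.
#' @export
genome_ranges <- function(genome) {
  GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(genome),
    ranges = IRanges::IRanges(1L, GenomeInfoDb::seqlengths(genome)),
    seqinfo = genome
  )
}

#' Build an interval set from 0-based half-open coordinates
#'
#' Interval sets are [GenomicRanges::GRanges] objects carrying the genome as
#' their `seqinfo`. `GRanges` uses 1-based closed coordinates internally;
#' this constructor (and the BED readers) take 0-based half-open coordinates
#' -- the BED convention used in all printed output -- and convert.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors; 0-based inclusive start, exclusive end.
#' @param genome A `Seqinfo` genome; every `chrom` must exist in it.
#' @param name,score Optional per-interval annotation.
#' @param sort Sort into canonical order (genome chromosome order, then
#'   start, then end)? Default `TRUE`.
#' @return A `GRanges` on `genome`.
#' @examples
#' g <- make_genome("chr1", 1000)
#' interval_set("chr1", 0, 100, g)
#' @export
interval_set <- function(chrom, start, end, genome, name = NULL,
                         score = NULL, sort = TRUE) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  bad <- !(chrom %in% GenomeInfoDb::seqnames(genome))
  if (any(bad))
    stop("unknown chromosome(s): ", paste(unique(chrom[bad]), collapse = ", "))
  if (any(start < 0) || any(start >= end))
    stop("invalid interval: require 0 <= start < end")
  len <- GenomeInfoDb::seqlengths(genome)[chrom]
  if (any(end > len))
    stop("interval end exceeds chromosome length")
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = GenomeInfoDb::seqnames(genome)),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    seqinfo = genome
  )
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- as.character(name)
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- as.numeric(score)
  if (sort) gr <- GenomicRanges::sort(gr)
  gr
}

#' Interval coordinates as a 0-based half-open data frame
#'
#' @param x A `GRanges` interval set.
#' @return A data frame with columns `chrom`, `start`, `end` (BED
#'   convention) plus any metadata columns.
#' @export
as_bed_frame <- function(x) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end = GenomicRanges::end(x),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(x))
  if (ncol(mc)) df <- cbind(df, mc)
  df
}
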