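#' Construct a genome layout
#'
#' A genome layout is the coordinate frame every genomic feature in the
#' package lives on: an ordered set of named chromosomes with positive
#' integer lengths.  It is represented as a [GenomeInfoDb::Seqinfo] object,
#' the standard Bioconductor container for this purpose, so layouts can be
#' attached directly to `GRanges` objects as their `seqinfo`.
#'
#' @param chroms character vector of chromosome names (unique).
#' @param lengths integer vector of chromosome lengths in bp (positive).
#' @return A `Seqinfo` object.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  if (anyDuplicated(chroms)) {
    stop("chromosome names must be unique")
  }
  lengths <- as.numeric(lengths)
  if (length(lengths) != length(chroms)) {
    stop("chroms and lengths must have equal length")
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0) || any(lengths != round(lengths))) {
    stop("chromosome lengths must be positive integers")
  }
  GenomeInfoDb::Seqinfo(seqnames = chroms, seqlengths = as.integer(lengths))
}

#' Build a GRanges from BED-style (0-based half-open) coordinates
#'
#' All interchange in this package is in the BED convention (0-based,
#' half-open).  In memory we use `GRanges` (1-based closed); this helper and
#' [granges_to_bed()] do the conversion at the boundary.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors, 0-based half-open.
#' @param layout optional `Seqinfo`; when given, intervals are validated
#'   against chromosome bounds.
#' @param ... further vectors stored as metadata columns (e.g. `id`, `score`).
#' @return A `GRanges`.
#' @export
bed_granges <- function(chrom, start, end, layout = NULL, ...) {
  if (any(start < 0) || any(end <= start)) {
    stop("require 0 <= start < end for all intervals")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.numeric(start) + 1, end = as.numeric(end)),
    ...
  )
  if (!is.null(layout)) {
    missing_chr <- setdiff(unique(as.character(chrom)), GenomeInfoDb::seqnames(layout))
    if (length(missing_chr)) {
      stop("chromosomes not in layout: ", paste(missing_chr, collapse = ", "))
    }
    too_long <- end >
      GenomeInfoDb::seqlengths(layout)[as.character(chrom)]
    if (any(too_long)) {
      stop(sum(too_long), " interval(s) exceed chromosome bounds")
    }
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(layout)
    GenomeInfoDb::seqinfo(gr) <- layout
  }
  sort(gr)
}

#' Convert a GRanges to a BED-style data.frame (0-based half-open)
#' @param gr a `GRanges`.
#' @return `data.frame` with columns chrom, start, end plus metadata columns.
#' @export
granges_to_bed <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  df
}

# shared check that two feature sets were built on the same coordinate frame
check_same_layout <- function(a, b) {
  la <- GenomeInfoDb::seqlengths(a)
  lb <- GenomeInfoDb::seqlengths(b)
  common <- intersect(names(la), names(lb))
  if (length(common) == 0 ||
      !identical(la[common], lb[common])) {
    stop("layout-mismatch: feature sets are not on the same genome layout")
  }
  invisible(TRUE)
}

# whole-genome GRanges for a layout
layout_granges <- function(layout) {
  GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(layout),
    ranges = IRanges::IRanges(1, GenomeInfoDb::seqlengths(layout)),
    seqinfo = layout
  )
}
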