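#' Tile a genome into non-overlapping windows
#'
#' Divides every chromosome into consecutive windows of `size` bp starting at
#' position 0.  A final window shorter than `size` is emitted and flagged
#' `partial`; window-scale statistics exclude partial windows by default to
#' avoid length-biased estimates.
#'
#' @param layout a `Seqinfo` from [genome_layout()].
#' @param size window size in bp (> 0), e.g. 250e3, 500e3, 1e6.
#' @return `GRanges` with a logical metadata column `partial`.
#' @examples
#' tile_windows(genome_layout("chr1", 1.2e6), 5e5)
#' @export
tile_windows <- function(layout, size) {
  if (!is.numeric(size) || length(size) != 1 || !is.finite(size) || size <= 0) {
    stop("invalid-parameter: window size must be a positive number")
  }
  size <- as.integer(size)
  tiles <- GenomicRanges::tileGenome(
    GenomeInfoDb::seqlengths(layout),
    tilewidth = size,
    cut.last.tile.in.chrom = TRUE
  )
  GenomeInfoDb::seqinfo(tiles) <- layout
  S4Vectors::mcols(tiles)$partial <- GenomicRanges::width(tiles) < size
  tiles
}

#' Count query intervals overlapping a subject set
#'
#' Number of query intervals sharing at least `min_bp` bases with one or more
#' subject intervals; each query counts at most once however many subjects it
#' touches.  Abutting half-open intervals do not overlap.
#'
#' @param query,subject `GRanges` on the same layout.
#' @param min_bp minimum shared bases to call an overlap (default 1).
#' @return integer count.
#' @export
count_overlapping <- function(query, subject, min_bp = 1L) {
  check_same_layout(query, subject)
  sum(GenomicRanges::countOverlaps(query, subject, minoverlap = min_bp) > 0)
}

#' Distance from each query interval to its nearest subject interval
#'
#' Returns 0 for overlapping (or abutting) intervals, otherwise the gap in bp
#' between the closest ends.  Queries on chromosomes carrying no subject
#' interval get `NA`.
#'
#' @param query,subject `GRanges`.
#' @return numeric vector, one distance per query interval (`NA` where
#'   undefined).
#' @export
distance_to_nearest <- function(query, subject) {
  out <- rep(NA_real_, length(query))
  if (length(subject) == 0) {
    warning("empty subject set: all distances undefined")
    return(out)
  }
  hits <- GenomicRanges::distanceToNearest(query, subject)
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out
}

#' Complement of an interval set over a genome layout
#'
#' Maximal intervals covering every base not in `x`.  The union of `x` and
#' its complement tiles the genome exactly once.
#'
#' @param layout a `Seqinfo`.
#' @param x `GRanges` (may be empty).
#' @return `GRanges` of the uncovered space.
#' @export
interval_complement <- function(layout, x) {
  genome <- layout_granges(layout)
  if (length(x) == 0) return(genome)
  GenomeInfoDb::seqlevels(x) <- GenomeInfoDb::seqlevels(layout)
  GenomeInfoDb::seqinfo(x) <- layout
  GenomicRanges::setdiff(genome, GenomicRanges::reduce(x), ignore.strand = TRUE)
}

# Place intervals of the given lengths uniformly over the eligible space.
# eligible: reduced GRanges of allowed space; every placed interval lies
# entirely within one eligible interval.  Vectorized over unique lengths:
# for length L an eligible interval of width w offers max(w - L + 1, 0)
# start positions; we pick an interval capacity-weighted, then a uniform
# offset.  This direct construction cannot reject, so no retry loop is
# needed.
place_lengths <- function(lengths, eligible, layout) {
  n <- length(lengths)
  chrom <- character(n)
  start0 <- numeric(n)
  ewidth <- GenomicRanges::width(eligible)
  echrom <- as.character(GenomicRanges::seqnames(eligible))
  estart0 <- GenomicRanges::start(eligible) - 1
  for (L in unique(lengths)) {
    idx <- which(lengths == L)
    cap <- pmax(ewidth - L + 1, 0)
    total <- sum(cap)
    if (total == 0) {
      stop("placement-failure: no eligible space for interval length ", L)
    }
    cum <- cumsum(as.numeric(cap))
    u <- runif(length(idx)) * total
    j <- findInterval(u, cum) + 1L       # eligible interval index
    off <- floor(u - c(0, cum)[j])       # uniform offset within capacity
    chrom[idx] <- echrom[j]
    start0[idx] <- estart0[j] + off
  }
  bed_granges(chrom, start0, start0 + lengths, layout = layout)
}

#' Sample length-matched control regions from excluded-free genome space
#'
#' Draws `n` random intervals whose lengths reproduce the length distribution
#' of `template` (the exact length multiset when `n` equals the template
#' size, otherwise lengths resampled with replacement), placed uniformly over
#' all start positions at which the interval fits entirely outside
#' `excluded`.  This is the construction behind "expected" overlap counts:
#' random regions from hotspot-free sequence keeping the genomic length
#' distribution identical to the hotspots.
#'
#' @param template `GRanges` whose lengths are matched.
#' @param layout a `Seqinfo`.
#' @param excluded `GRanges` of forbidden space (e.g. the hotspots
#'   themselves).
#' @param n number of control regions (default 1e6).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return `GRanges` of `n` control regions, none intersecting `excluded`.
#' @export
sample_control_regions <- function(template, layout, excluded, n = 1e6, seed) {
  if (!missing(seed)) set.seed(seed)
  tlen <- GenomicRanges::width(template)
  lengths <- if (n == length(tlen)) {
    tlen[sample.int(length(tlen))]
  } else {
    tlen[sample.int(length(tlen), n, replace = TRUE)]
  }
  eligible <- interval_complement(layout, excluded)
  place_lengths(lengths, eligible, layout)
}
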