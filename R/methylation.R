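#' Fractional methylation of a single cytosine
#'
#' The per-site methylation estimate from bisulfite sequencing read counts:
#' C reads / (C reads + T reads).
#'
#' @param c_reads,t_reads non-negative read counts (vectorized).
#' @return fraction(s) in `[0, 1]`.
#' @examples
#' site_fraction(3, 1)  # 0.75
#' @export
site_fraction <- function(c_reads, t_reads) {
  if (any(c_reads < 0) || any(t_reads < 0)) {
    stop("read counts must be non-negative")
  }
  total <- c_reads + t_reads
  if (any(total < 1)) {
    stop("undefined-site: zero total depth")
  }
  c_reads / total
}

#' Construct a per-cytosine methylation track
#'
#' Sites are width-1 `GRanges` carrying `c_reads` / `t_reads` metadata
#' columns.  Sites below `min_depth` total coverage are dropped at
#' construction.
#'
#' @param chrom,pos chromosome names and 0-based positions.
#' @param c_reads,t_reads read counts.
#' @param layout optional `Seqinfo`.
#' @param min_depth minimum total reads per retained site (default 1).
#' @return `GRanges` (sorted, unique positions) with counts.
#' @export
methylation_track <- function(chrom, pos, c_reads, t_reads, layout = NULL,
                              min_depth = 1L) {
  chrom <- rep(as.character(chrom), length.out = length(pos))
  keep <- (c_reads + t_reads) >= min_depth
  gr <- bed_granges(chrom[keep], pos[keep], pos[keep] + 1, layout = layout,
                    c_reads = c_reads[keep], t_reads = t_reads[keep])
  if (anyDuplicated(gr) > 0) {
    stop("duplicate cytosine sites at identical positions")
  }
  gr
}

#' Mean fractional methylation of regions
#'
#' For each region, the unweighted mean of per-site fractional methylation
#' over all covered cytosines in the region (each mapped cytosine counts
#' once, regardless of its read depth).  Regions with fewer than `min_sites`
#' covered cytosines get `NA`.
#'
#' @param track a methylation track from [methylation_track()].
#' @param regions `GRanges`.
#' @param min_sites minimum covered cytosines per region (default 1).
#' @param weight_by_depth weight sites by total read depth instead
#'   (default `FALSE`; the unweighted mean is the package convention).
#' @return numeric vector, one value per region (`NA` where undefined), with
#'   attribute `n_sites` giving covered-site counts.
#' @export
regional_methylation <- function(track, regions, min_sites = 1L,
                                 weight_by_depth = FALSE) {
  frac <- site_fraction(S4Vectors::mcols(track)$c_reads,
                        S4Vectors::mcols(track)$t_reads)
  hits <- GenomicRanges::findOverlaps(track, regions, ignore.strand = TRUE)
  si <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  n_sites <- tabulate(ri, nbins = length(regions))
  if (weight_by_depth) {
    depth <- S4Vectors::mcols(track)$c_reads + S4Vectors::mcols(track)$t_reads
    num <- rowsum_vec(frac[si] * depth[si], ri, length(regions))
    den <- rowsum_vec(depth[si], ri, length(regions))
    m <- num / den
  } else {
    m <- rowsum_vec(frac[si], ri, length(regions)) / n_sites
  }
  m[n_sites < min_sites] <- NA_real_
  attr(m, "n_sites") <- n_sites
  m
}

# sum of x grouped by integer index g over 1..n (0 where no members)
rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(x, g)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Interspecies methylation difference over paired regions
#'
#' Difference in regional mean methylation (`a` minus `b`, e.g.
#' human − chimpanzee) over region pairs already expressed in each track's
#' own coordinates (pair regions via synteny projection beforehand).
#'
#' @param track_a,track_b methylation tracks.
#' @param regions_a,regions_b paired `GRanges` of equal length.
#' @param min_sites minimum covered cytosines on each side.
#' @return numeric vector of differences (`NA` where either side undefined).
#' @export
methylation_difference <- function(track_a, track_b, regions_a, regions_b,
                                   min_sites = 1L) {
  if (length(regions_a) != length(regions_b)) {
    stop("pairing-error: region lists have different lengths")
  }
  as.numeric(regional_methylation(track_a, regions_a, min_sites = min_sites)) -
    as.numeric(regional_methylation(track_b, regions_b, min_sites = min_sites))
}
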