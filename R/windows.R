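#' bp-weighted mean recombination rate over regions
#'
#' The rate of a region is the mean of the rates of the map segments
#' overlapping it, weighted by the number of bases each segment contributes.
#' Invariant to splitting a map segment into abutting pieces with the same
#' rate.  Regions with no overlapping segment get `NA`.
#'
#' @param rec_map `GRanges` of non-overlapping segments with numeric
#'   metadata column `score` (cM/Mb).
#' @param regions `GRanges`.
#' @return numeric vector, one rate per region.
#' @export
region_recombination_rate <- function(rec_map, regions) {
  hits <- GenomicRanges::findOverlaps(regions, rec_map, ignore.strand = TRUE)
  ov <- GenomicRanges::pintersect(
    regions[S4Vectors::queryHits(hits)],
    rec_map[S4Vectors::subjectHits(hits)]
  )
  w <- GenomicRanges::width(ov)
  r <- S4Vectors::mcols(rec_map)$score[S4Vectors::subjectHits(hits)]
  num <- rowsum_vec(w * r, S4Vectors::queryHits(hits), length(regions))
  den <- rowsum_vec(w, S4Vectors::queryHits(hits), length(regions))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Build the per-window feature table
#'
#' Tiles the genome into windows of `size` bp and assembles, per full
#' window, the response and predictors of the window-scale analyses:
#' bp-weighted mean recombination rate, mean fractional methylation,
#' covered-cytosine count, and (when a sequence source / repeat annotation is
#' supplied) G+C content, CpG count, CpG O/E and repeat fraction.
#'
#' Partial terminal windows are excluded by default; windows with fewer than
#' `min_sites` covered cytosines keep their row but have `NA` methylation
#' (model fits drop them listwise).
#'
#' @param layout a `Seqinfo`.
#' @param size window size in bp.
#' @param rec_map recombination map (`GRanges` with `score`, cM/Mb).
#' @param meth_track methylation track, or `NULL` to skip.
#' @param seq_source named `DNAStringSet` of chromosome sequences, or `NULL`
#'   to skip sequence features.
#' @param repeats `GRanges` of repeats, or `NULL` to skip.
#' @param min_sites minimum covered cytosines per window (default 5).
#' @param include_partial keep partial terminal windows (default `FALSE`).
#' @return `data.frame` with columns chrom, start, end (0-based half-open),
#'   recombination_rate, methylation, covered_sites and any sequence feature
#'   columns.
#' @export
build_window_table <- function(layout, size, rec_map, meth_track = NULL,
                               seq_source = NULL, repeats = NULL,
                               min_sites = 5L, include_partial = FALSE) {
  win <- tile_windows(layout, size)
  if (!is.null(rec_map)) check_same_layout(win, rec_map)
  if (!is.null(meth_track)) check_same_layout(win, meth_track)
  if (!include_partial) win <- win[!S4Vectors::mcols(win)$partial]
  tab <- granges_to_bed(win)
  tab$partial <- NULL
  tab$recombination_rate <- region_recombination_rate(rec_map, win)
  if (!is.null(meth_track)) {
    m <- regional_methylation(meth_track, win, min_sites = min_sites)
    tab$methylation <- as.numeric(m)
    tab$covered_sites <- attr(m, "n_sites")
  }
  if (!is.null(seq_source)) {
    missing_chr <- setdiff(unique(tab$chrom), names(seq_source))
    if (length(missing_chr)) {
      stop("layout-mismatch: no sequence for ", paste(missing_chr, collapse = ", "))
    }
    seqs <- Biostrings::DNAStringSet(Map(
      function(ch, s, e) Biostrings::subseq(seq_source[[ch]], s + 1, e),
      tab$chrom, tab$start, tab$end
    ))
    tab$gc <- gc_content(seqs)
    tab$cpg_count <- cpg_count(seqs)
    tab$cpg_oe <- cpg_oe(seqs)
  }
  if (!is.null(repeats)) {
    tab$repeat_fraction <- repeat_fraction(win, repeats)
  }
  tab
}
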