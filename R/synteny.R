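#' Construct a synteny map between two genomes
#'
#' A simplified chain model of a whole-genome alignment: an ordered list of
#' gap-free blocks in which source and destination spans have equal length.
#' Intervals are projected block-wise (the role liftOver plays for real
#' assemblies); full UCSC chain/net parsing is deliberately out of scope.
#'
#' @param blocks data.frame with columns `src_chrom`, `src_start`, `src_end`,
#'   `dst_chrom`, `dst_start`, `dst_end`, `strand` (`+` or `-`); coordinates
#'   0-based half-open.
#' @param src_layout,dst_layout optional `Seqinfo` objects for the two
#'   genomes.
#' @param min_mapped_fraction default minimum fraction of bases that must lie
#'   in blocks for an interval to map (liftOver's -minMatch analogue).
#' @return A `synteny_map` object (validated data.frame).
#' @export
synteny_map <- function(blocks, src_layout = NULL, dst_layout = NULL,
                        min_mapped_fraction = 0.95) {
  need <- c("src_chrom", "src_start", "src_end",
            "dst_chrom", "dst_start", "dst_end", "strand")
  if (!all(need %in% names(blocks))) {
    stop("invalid-map: blocks need columns ", paste(need, collapse = ", "))
  }
  blocks <- as.data.frame(blocks)[need]
  if (any(blocks$src_end <= blocks$src_start) ||
      any(blocks$dst_end <= blocks$dst_start)) {
    stop("invalid-map: empty or reversed block")
  }
  if (any((blocks$src_end - blocks$src_start) !=
          (blocks$dst_end - blocks$dst_start))) {
    stop("invalid-map: src and dst spans of a block must have equal length")
  }
  if (!all(blocks$strand %in% c("+", "-"))) {
    stop("invalid-map: strand must be '+' or '-'")
  }
  # source blocks must not overlap
  o <- order(blocks$src_chrom, blocks$src_start)
  b <- blocks[o, ]
  same <- b$src_chrom[-1] == b$src_chrom[-nrow(b)]
  if (nrow(b) > 1 && any(same & b$src_start[-1] < b$src_end[-nrow(b)])) {
    stop("invalid-map: overlapping source blocks")
  }
  structure(b,
            class = c("synteny_map", "data.frame"),
            src_layout = src_layout, dst_layout = dst_layout,
            min_mapped_fraction = min_mapped_fraction,
            row.names = seq_len(nrow(b)))
}

#' Invert a synteny map
#'
#' Swaps source and destination genomes.  For an invertible (indel-free on
#' the aligned bases) map, projecting through the map and its inverse returns
#' any fully covered interval to itself.
#'
#' @param map a `synteny_map`.
#' @return the inverted `synteny_map`.
#' @export
invert_synteny <- function(map) {
  synteny_map(
    data.frame(
      src_chrom = map$dst_chrom, src_start = map$dst_start, src_end = map$dst_end,
      dst_chrom = map$src_chrom, dst_start = map$src_start, dst_end = map$src_end,
      strand = map$strand, stringsAsFactors = FALSE
    ),
    src_layout = attr(map, "dst_layout"),
    dst_layout = attr(map, "src_layout"),
    min_mapped_fraction = attr(map, "min_mapped_fraction")
  )
}

#' Project intervals between genomes through a synteny map
#'
#' An interval maps if and only if at least `min_fraction` of its bases lie
#' in blocks that project to a single destination chromosome and strand; the
#' mapped interval spans the minimum to maximum projected base coordinates.
#' All other intervals are reported unmapped (never silently dropped).
#'
#' @param x `GRanges` on the map's source genome.
#' @param map a `synteny_map`.
#' @param min_fraction minimum mapped base fraction (default: the map's
#'   `min_mapped_fraction`, itself defaulting to 0.95).
#' @return list with `mapped` (`GRanges` with metadata column `orig` giving
#'   the index of the source interval, other metadata carried over) and
#'   `unmapped` (integer indices of source intervals that failed to map).
#' @export
map_via_synteny <- function(x, map, min_fraction = NULL) {
  if (is.null(min_fraction)) {
    min_fraction <- attr(map, "min_mapped_fraction")
    if (is.null(min_fraction)) min_fraction <- 0.95
  }
  dst_layout <- attr(map, "dst_layout")
  empty <- GenomicRanges::GRanges()
  if (length(x) == 0) return(list(mapped = empty, unmapped = integer(0)))

  src <- GenomicRanges::GRanges(
    map$src_chrom, IRanges::IRanges(map$src_start + 1, map$src_end)
  )
  # suppress the seqlevel-mismatch note when x and the map cover
  # different chromosome subsets
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(x, src, ignore.strand = TRUE)
  )
  if (length(hits) == 0) {
    return(list(mapped = empty, unmapped = seq_along(x)))
  }
  q <- S4Vectors::queryHits(hits)
  b <- S4Vectors::subjectHits(hits)
  # intersection pieces in 0-based half-open coords
  ps <- pmax(GenomicRanges::start(x)[q] - 1, map$src_start[b])
  pe <- pmin(GenomicRanges::end(x)[q], map$src_end[b])
  dt <- data.table::data.table(
    q = q,
    dst_chrom = map$dst_chrom[b],
    strand = map$strand[b],
    cov = pe - ps,
    d1 = ifelse(map$strand[b] == "+",
                map$dst_start[b] + (ps - map$src_start[b]),
                map$dst_end[b] - (pe - map$src_start[b])),
    d2 = ifelse(map$strand[b] == "+",
                map$dst_start[b] + (pe - map$src_start[b]),
                map$dst_end[b] - (ps - map$src_start[b]))
  )
  grp <- dt[, .(cov = sum(cov), d1 = min(d1), d2 = max(d2)),
            by = .(q, dst_chrom, strand)]
  # best destination (chromosome, strand) group per query
  data.table::setorder(grp, q, -cov)
  best <- grp[!duplicated(q)]
  wid <- GenomicRanges::width(x)[best$q]
  ok <- best$cov >= min_fraction * wid
  best <- best[ok]
  if (nrow(best) == 0) {
    return(list(mapped = empty, unmapped = seq_along(x)))
  }
  mapped <- bed_granges(best$dst_chrom, best$d1, best$d2, layout = dst_layout,
                        orig = best$q)
  mc <- S4Vectors::mcols(x)
  if (ncol(mc)) {
    S4Vectors::mcols(mapped) <- cbind(
      S4Vectors::mcols(mapped),
      mc[S4Vectors::mcols(mapped)$orig, , drop = FALSE]
    )
  }
  list(mapped = mapped,
       unmapped = setdiff(seq_along(x), best$q))
}

#' Read / write a synteny map as 7-column TSV
#'
#' Columns: src_chrom, src_start, src_end, dst_chrom, dst_start, dst_end,
#' strand; 0-based half-open coordinates.
#'
#' @param path file path.
#' @param ... passed to [synteny_map()] (layouts, min fraction).
#' @return `read_synteny`: a `synteny_map`; `write_synteny`: the path,
#'   invisibly.
#' @export
read_synteny <- function(path, ...) {
  df <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  synteny_map(df, ...)
}

#' @rdname read_synteny
#' @param map a `synteny_map`.
#' @export
write_synteny <- function(map, path) {
  data.table::fwrite(as.data.frame(map), path, sep = "\t")
  invisible(path)
}
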