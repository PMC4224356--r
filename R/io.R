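#' Read a BED3/BED6 file
#'
#' Tab-separated, 0-based half-open; `track` and `browser` lines are
#' skipped.  Column 4 is taken as the interval id and column 5 as the score
#' when present.  Malformed lines raise an error naming the line number;
#' with a layout, out-of-bounds intervals are rejected.
#'
#' @param path file path.
#' @param layout optional `Seqinfo` for bounds validation.
#' @return `GRanges` (metadata columns `id` / `score` when present).
#' @export
read_bed <- function(path, layout = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  if (!length(lineno)) {
    return(GenomicRanges::GRanges(seqinfo = layout))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 3)) {
    stop("malformed BED line ", lineno[which(ncol < 3)[1]], ": fewer than 3 columns")
  }
  chrom <- vapply(parts, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  bad <- is.na(start) | is.na(end) | start < 0 | end <= start
  if (any(bad)) {
    stop("malformed BED line ", lineno[which(bad)[1]],
         ": need numeric 0 <= start < end")
  }
  extra <- list()
  if (all(ncol >= 4)) extra$id <- vapply(parts, `[[`, "", 4)
  if (all(ncol >= 5)) {
    extra$score <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5)))
  }
  do.call(bed_granges, c(list(chrom = chrom, start = start, end = end,
                              layout = layout), extra))
}

#' Write a GRanges as BED
#'
#' @param gr `GRanges`; metadata columns `id` and `score` become BED
#'   columns 4 and 5.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- granges_to_bed(gr)
  cols <- c("chrom", "start", "end")
  if ("id" %in% names(df)) {
    cols <- c(cols, "id")
    if ("score" %in% names(df)) cols <- c(cols, "score")
  } else if ("score" %in% names(df)) {
    df$id <- "."
    cols <- c(cols, "id", "score")
  }
  data.table::fwrite(df[cols], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write a chromosome-sizes file (name TAB length)
#' @param path file path.
#' @return a `Seqinfo`.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  genome_layout(df$chrom, df$length)
}

#' @rdname read_chrom_sizes
#' @param layout a `Seqinfo`.
#' @export
write_chrom_sizes <- function(layout, path) {
  utils::write.table(
    data.frame(GenomeInfoDb::seqnames(layout),
               GenomeInfoDb::seqlengths(layout)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a Bismark-style cytosine report
#'
#' TSV with columns chrom, 1-based position, strand, count_methylated,
#' count_unmethylated, context.  Positions are converted to 0-based;
#' non-CpG contexts are dropped (counted in the `dropped_non_cpg`
#' attribute).  With `merge_strands = TRUE`, plus/minus calls of one CpG
#' (minus-strand position = plus position + 1) are merged by summing
#' counts at the plus-strand position.
#'
#' @param path file path.
#' @param layout optional `Seqinfo`.
#' @param merge_strands merge symmetric CpG calls (default `FALSE`).
#' @param min_depth minimum total reads per retained site.
#' @return methylation track `GRanges`; attribute `dropped_non_cpg` gives
#'   the number of skipped non-CpG rows.
#' @export
read_cytosine_report <- function(path, layout = NULL, merge_strands = FALSE,
                                 min_depth = 1L) {
  df <- data.table::fread(
    path, header = FALSE, sep = "\t", data.table = FALSE,
    col.names = c("chrom", "pos1", "strand", "count_meth", "count_unmeth",
                  "context")
  )
  if (any(df$count_meth < 0 | df$count_unmeth < 0)) {
    stop("negative read counts in cytosine report")
  }
  is_cpg <- df$context == "CG"
  dropped <- sum(!is_cpg)
  df <- df[is_cpg, ]
  pos0 <- df$pos1 - 1
  if (merge_strands) {
    pos0[df$strand == "-"] <- pos0[df$strand == "-"] - 1
    dt <- data.table::data.table(chrom = df$chrom, pos0 = pos0,
                                 c = df$count_meth, t = df$count_unmeth)
    dt <- dt[, .(c = sum(c), t = sum(t)), by = .(chrom, pos0)]
    track <- methylation_track(dt$chrom, dt$pos0, dt$c, dt$t, layout = layout,
                               min_depth = min_depth)
  } else {
    track <- methylation_track(df$chrom, pos0, df$count_meth,
                               df$count_unmeth, layout = layout,
                               min_depth = min_depth)
  }
  attr(track, "dropped_non_cpg") <- dropped
  track
}

#' Write a methylation track as a cytosine report
#'
#' All sites are written as plus-strand CpG rows (1-based positions).
#'
#' @param track methylation track `GRanges`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_cytosine_report <- function(track, path) {
  data.table::fwrite(
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(track)),
      pos1 = GenomicRanges::start(track),
      strand = "+",
      count_meth = S4Vectors::mcols(track)$c_reads,
      count_unmeth = S4Vectors::mcols(track)$t_reads,
      context = "CG"
    ),
    path, sep = "\t", col.names = FALSE
  )
  invisible(path)
}

#' Read / write a bedGraph track (piecewise-constant scores)
#'
#' 4 columns: chrom, start, end (0-based half-open), numeric score.
#' Overlapping segments and non-numeric scores are errors.
#'
#' @param path file path.
#' @param layout optional `Seqinfo`.
#' @return `GRanges` with metadata column `score`.
#' @export
read_bedgraph <- function(path, layout = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  if (!sum(keep)) {
    warning("empty bedGraph: ", path)
    return(GenomicRanges::GRanges(seqinfo = layout, score = numeric(0)))
  }
  df <- utils::read.table(
    text = lines[keep], sep = "\t",
    col.names = c("chrom", "start", "end", "score"),
    colClasses = c("character", "numeric", "numeric", "character")
  )
  score <- suppressWarnings(as.numeric(df$score))
  if (any(is.na(score))) {
    stop("non-numeric score at data line ", which(is.na(score))[1])
  }
  gr <- bed_granges(df$chrom, df$start, df$end, layout = layout,
                    score = score)
  if (!GenomicRanges::isDisjoint(gr)) {
    stop("overlapping segments in bedGraph: ", path)
  }
  gr
}

#' @rdname read_bedgraph
#' @param gr `GRanges` with a `score` column.
#' @export
write_bedgraph <- function(gr, path) {
  df <- granges_to_bed(gr)
  data.table::fwrite(df[c("chrom", "start", "end", "score")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a run manifest (key-value text with file digests)
#'
#' Records the package version, seeds/parameters and an md5 digest per
#' output file; re-running the pipeline with identical inputs reproduces
#' identical digests.
#'
#' @param params named list of scalar parameters (seeds, sizes, paths).
#' @param files character vector of output files to digest.
#' @param path manifest path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(params, files, path) {
  lines <- c(
    paste0("epirecomb_version=", as.character(utils::packageVersion("epirecomb"))),
    paste0(names(params), "=", vapply(params, as.character, "")),
    paste0("md5:", basename(files), "=", unname(tools::md5sum(files)))
  )
  writeLines(lines, path)
  invisible(path)
}
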