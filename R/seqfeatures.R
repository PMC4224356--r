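as_dna <- function(seq) {
  if (is.character(seq)) seq <- Biostrings::DNAStringSet(seq)
  if (methods::is(seq, "DNAString")) seq <- Biostrings::DNAStringSet(list(seq))
  seq
}

#' G+C content of nucleotide sequences
#'
#' (#G + #C) / (#A + #C + #G + #T); ambiguous bases (N etc.) are excluded
#' from both numerator and denominator.  `NA` for sequences with no
#' unambiguous base.
#'
#' @param seq character vector, `DNAString` or `DNAStringSet`.
#' @return numeric vector of fractions.
#' @examples
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(seq) {
  seq <- as_dna(seq)
  if (any(Biostrings::width(seq) == 0)) stop("empty sequence")
  f <- Biostrings::letterFrequency(seq, c("A", "C", "G", "T"))
  denom <- rowSums(f)
  out <- (f[, "G"] + f[, "C"]) / denom
  out[denom == 0] <- NA_real_
  unname(out)
}

#' Count CpG dinucleotides
#'
#' Number of positions i with `seq[i] == "C"` and `seq[i+1] == "G"`, counted
#' on the given (plus) strand.
#'
#' @inheritParams gc_content
#' @return integer vector of counts.
#' @export
cpg_count <- function(seq) {
  seq <- as_dna(seq)
  if (any(Biostrings::width(seq) == 0)) stop("empty sequence")
  Biostrings::vcountPattern("CG", seq)
}

#' Normalized CpG (CpG observed/expected ratio)
#'
#' The CpG depletion index (#CpG × L) / (#C × #G), with L the number of
#' unambiguous bases.  `NA` when the sequence has no C or no G.
#'
#' @inheritParams gc_content
#' @return numeric vector.
#' @export
cpg_oe <- function(seq) {
  seq <- as_dna(seq)
  if (any(Biostrings::width(seq) == 0)) stop("empty sequence")
  f <- Biostrings::letterFrequency(seq, c("A", "C", "G", "T"))
  L <- rowSums(f)
  ncpg <- Biostrings::vcountPattern("CG", seq)
  out <- as.numeric(ncpg) * L / (as.numeric(f[, "C"]) * f[, "G"])
  out[f[, "C"] == 0 | f[, "G"] == 0] <- NA_real_
  unname(out)
}

#' Fraction of each region covered by repeat annotation
#'
#' Bases of the region covered by the union of repeat intervals, divided by
#' region length (overlapping repeats are unioned, never double-counted).
#'
#' @param regions `GRanges`.
#' @param repeats `GRanges` of repeat elements (e.g. from a RepeatMasker BED).
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
repeat_fraction <- function(regions, repeats) {
  red <- GenomicRanges::reduce(repeats, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(regions, red, ignore.strand = TRUE)
  ov <- GenomicRanges::pintersect(
    regions[S4Vectors::queryHits(hits)],
    red[S4Vectors::subjectHits(hits)]
  )
  covered <- rowsum_vec(GenomicRanges::width(ov),
                        S4Vectors::queryHits(hits), length(regions))
  covered / GenomicRanges::width(regions)
}
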