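# shorthand: BED-style (0-based half-open) GRanges
gr <- function(chrom, start, end, layout = NULL, ...) {
  bed_granges(chrom, start, end, layout = layout, ...)
}

# brute-force pairwise overlap-count oracle on BED coordinates
brute_overlap_count <- function(query, subject, min_bp = 1) {
  q <- granges_to_bed(query)
  s <- granges_to_bed(subject)
  hit <- vapply(seq_len(nrow(q)), function(i) {
    any(s$chrom == q$chrom[i] &
          pmin(s$end, q$end[i]) - pmax(s$start, q$start[i]) >= min_bp)
  }, logical(1))
  sum(hit)
}

# enumeration oracle for the two-sided Fisher exact p of a 2x2 table:
# hypergeometric probabilities from binomial coefficients, summed over all
# tables (margins fixed) no more probable than the observed one
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# random non-degenerate interval set on a layout
random_intervals <- function(n, layout, max_len = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- GenomeInfoDb::seqnames(layout)
  lens <- GenomeInfoDb::seqlengths(layout)
  ci <- sample(seq_along(chroms), n, replace = TRUE)
  L <- sample(max_len, n, replace = TRUE)
  s <- floor(runif(n) * (lens[ci] - L))
  gr(chroms[ci], s, s + L, layout = layout)
}
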