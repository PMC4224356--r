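#' Cross-species hotspot classification via synteny projection
#'
#' Projects each genome's hotspots into the other genome and calls a hotspot
#' `common` when its projection overlaps (>= 1 bp) a partner hotspot —
#' reciprocally so by default, i.e. the partner hotspot's own projection must
#' also overlap the original.  All remaining mappable hotspots are
#' species-specific; unmappable hotspots are counted and reported separately,
#' never silently dropped.  Also returns, per genome, the syntenic
#' projections of the partner's specific hotspots (the "syntenic region"
#' comparison sets).
#'
#' @param hs_a,hs_b `GRanges` of hotspots in genomes A and B.
#' @param map_ab synteny map A -> B; `map_ba` its inverse (B -> A).
#' @param reciprocal require reciprocal overlap (default `TRUE`).
#' @param min_fraction minimum mapped base fraction for projection.
#' @return object of class `hotspot_classes`: list with per-genome label
#'   factors (`species_specific` / `common` / `unmapped`), a `counts` list
#'   (species_specific_a, species_specific_b, common, unmapped_a,
#'   unmapped_b) and syntenic projection sets `syntenic_a_in_b`,
#'   `syntenic_b_in_a` (projections of the specific hotspots).
#' @export
classify_cross_species <- function(hs_a, hs_b, map_ab, map_ba,
                                   reciprocal = TRUE, min_fraction = NULL) {
  pa <- map_via_synteny(hs_a, map_ab, min_fraction = min_fraction)
  pb <- map_via_synteny(hs_b, map_ba, min_fraction = min_fraction)

  # overlap pairs (a index, b index) via A-projections against B hotspots
  ov_ab <- GenomicRanges::findOverlaps(pa$mapped, hs_b, ignore.strand = TRUE)
  pairs_ab <- cbind(
    a = S4Vectors::mcols(pa$mapped)$orig[S4Vectors::queryHits(ov_ab)],
    b = S4Vectors::subjectHits(ov_ab)
  )
  if (reciprocal) {
    ov_ba <- GenomicRanges::findOverlaps(pb$mapped, hs_a, ignore.strand = TRUE)
    pairs_ba <- cbind(
      a = S4Vectors::subjectHits(ov_ba),
      b = S4Vectors::mcols(pb$mapped)$orig[S4Vectors::queryHits(ov_ba)]
    )
    key <- function(m) paste(m[, "a"], m[, "b"])
    pairs_ab <- pairs_ab[key(pairs_ab) %in% key(pairs_ba), , drop = FALSE]
  }
  common_a <- unique(pairs_ab[, "a"])
  common_b <- unique(pairs_ab[, "b"])

  lab_a <- rep("species_specific", length(hs_a))
  lab_a[common_a] <- "common"
  lab_a[pa$unmapped] <- "unmapped"
  lab_b <- rep("species_specific", length(hs_b))
  lab_b[common_b] <- "common"
  lab_b[pb$unmapped] <- "unmapped"

  spec_a <- which(lab_a == "species_specific")
  spec_b <- which(lab_b == "species_specific")
  syn_a <- pa$mapped[S4Vectors::mcols(pa$mapped)$orig %in% spec_a]
  syn_b <- pb$mapped[S4Vectors::mcols(pb$mapped)$orig %in% spec_b]

  structure(list(
    labels_a = factor(lab_a, c("species_specific", "common", "unmapped")),
    labels_b = factor(lab_b, c("species_specific", "common", "unmapped")),
    counts = list(
      species_specific_a = length(spec_a),
      species_specific_b = length(spec_b),
      common = length(common_a),
      common_b = length(common_b),
      unmapped_a = length(pa$unmapped),
      unmapped_b = length(pb$unmapped)
    ),
    syntenic_a_in_b = syn_a,
    syntenic_b_in_a = syn_b
  ), class = "hotspot_classes")
}

#' Classify mouse hotspots by SNP/DSB set membership
#'
#' Both hotspot sets live on the same genome; a DSB hotspot overlapping
#' (>= 1 bp) any SNP hotspot is an `SNP_DSB` hotspot (counted on the DSB
#' side, matching how shared hotspots are reported), `SNP_only` and
#' `DSB_only` are the non-overlapping remainders of each set.
#'
#' @param snp_hs hotspots from the SNP-based (historical) genetic map.
#' @param dsb_hs hotspots from direct DSB mapping (current).
#' @return object of class `hotspot_classes` with `counts` list
#'   (`snp_only`, `dsb_only`, `snp_dsb`, and `snp_shared` — the number of
#'   SNP hotspots touched by a DSB hotspot, which can be smaller than
#'   `snp_dsb` when one SNP hotspot carries several DSB hotspots).
#' @export
classify_mouse <- function(snp_hs, dsb_hs) {
  check_same_layout(snp_hs, dsb_hs)
  dsb_shared <- GenomicRanges::countOverlaps(dsb_hs, snp_hs) > 0
  snp_shared <- GenomicRanges::countOverlaps(snp_hs, dsb_hs) > 0
  structure(list(
    labels_snp = factor(ifelse(snp_shared, "SNP_DSB", "SNP_only"),
                        c("SNP_only", "SNP_DSB")),
    labels_dsb = factor(ifelse(dsb_shared, "SNP_DSB", "DSB_only"),
                        c("DSB_only", "SNP_DSB")),
    counts = list(
      snp_only = sum(!snp_shared),
      dsb_only = sum(!dsb_shared),
      snp_dsb = sum(dsb_shared),
      snp_shared = sum(snp_shared)
    )
  ), class = "hotspot_classes")
}

#' Overlap enrichment of features in a peak set against resampled controls
#'
#' Observed: number of feature intervals overlapping a peak.  Expected: mean
#' of the same count over `n_controls` control sets, each of the feature
#' set's size and length distribution, placed uniformly in the genome
#' outside `excluded` (by default the features themselves, i.e. hotspot-free
#' sequence).  Fold = observed / expected.  Significance is reported three
#' ways: a Fisher exact p on the 2x2 table built from the rounded expected
#' count (an approximation, since the expected is itself estimated), the
#' Monte-Carlo p (fraction of control sets with >= observed overlaps, +1
#' corrected), and an analytic genome-fraction expected for reference.
#'
#' @param features `GRanges` (e.g. recombination hotspots).
#' @param peaks `GRanges` (e.g. H3K4me3-enriched regions).
#' @param layout a `Seqinfo`.
#' @param excluded `GRanges` controls must avoid (default: `features`).
#' @param n_controls number of control sets (>= 100, default 1000).
#' @param seed integer seed, recorded in the result.
#' @return list with `observed`, `expected`, `fold`, `p_fisher`, `p_mc`,
#'   `expected_genome_fraction`, `n_features`, `n_controls`, `seed`.
#' @export
overlap_enrichment <- function(features, peaks, layout, excluded = features,
                               n_controls = 1000L, seed = 1L) {
  if (n_controls < 100) stop("need n_controls >= 100")
  nf <- length(features)
  observed <- count_overlapping(features, peaks)

  set.seed(seed)
  lengths <- rep(GenomicRanges::width(features), n_controls)
  eligible <- interval_complement(layout, excluded)
  controls <- place_lengths(lengths, eligible, layout)
  hit <- GenomicRanges::countOverlaps(controls, peaks, ignore.strand = TRUE) > 0
  set_id <- rep(seq_len(n_controls), each = nf)
  per_set <- rowsum_vec(as.numeric(hit), set_id, n_controls)
  expected <- mean(per_set)

  fold <- if (expected > 0) observed / expected else NA_real_
  p_fisher <- if (expected > 0 && round(expected) >= 1 && observed >= 1) {
    fisher_exact_2x2(matrix(c(observed, nf - observed,
                              round(expected), nf - round(expected)), 2,
                            byrow = TRUE))
  } else NA_real_
  p_mc <- (1 + sum(per_set >= observed)) / (n_controls + 1)

  # analytic reference: P(random length-matched interval in eligible space
  # overlaps >= 1 peak), computed exactly by interval arithmetic at the mean
  # template length
  Lbar <- max(1, round(mean(GenomicRanges::width(features))))
  p_hit <- overlap_probability(eligible, peaks, Lbar)

  list(observed = observed, expected = expected, fold = fold,
       p_fisher = p_fisher, p_mc = p_mc,
       expected_genome_fraction = nf * p_hit,
       n_features = nf, n_controls = n_controls, seed = seed)
}

# Exact probability that an interval of length L, placed uniformly over all
# start positions at which it fits inside `eligible`, overlaps >= 1 peak.
overlap_probability <- function(eligible, peaks, L) {
  cap <- pmax(GenomicRanges::width(eligible) - L + 1, 0)
  total <- sum(as.numeric(cap))
  if (total == 0) return(NA_real_)
  # valid start positions (1-based left ends within eligible intervals)
  starts_space <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(eligible),
    IRanges::IRanges(GenomicRanges::start(eligible),
                     width = pmax(cap, 0))
  )[cap > 0]
  # an interval starting at s overlaps peak [a, b] iff s in [a - L + 1, b]
  hit_zone <- GenomicRanges::reduce(GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks),
    IRanges::IRanges(pmax(GenomicRanges::start(peaks) - L + 1, 1),
                     GenomicRanges::end(peaks))
  ))
  hitting <- GenomicRanges::intersect(starts_space, hit_zone,
                                      ignore.strand = TRUE)
  sum(as.numeric(GenomicRanges::width(hitting))) / total
}

#' Bootstrap null for interspecies methylation divergence at hotspots
#'
#' Compares the observed mean interspecies methylation difference at
#' hotspots against the distribution of means of size-matched bootstrap
#' samples drawn with replacement from control-region differences.  The
#' empirical two-sided p uses the +1 correction, so it is bounded below by
#' `1 / (B + 1)`.
#'
#' @param diffs_hotspots numeric vector of per-hotspot differences.
#' @param diffs_controls numeric vector of per-control-region differences.
#' @param B number of bootstrap resamples (>= 1000 recommended; smaller B
#'   triggers a warning).
#' @param seed integer seed.
#' @return list with `observed`, `draws`, `empirical_p`, `B`, `seed`.
#' @export
methylation_divergence_null <- function(diffs_hotspots, diffs_controls,
                                        B = 1000L, seed = 1L) {
  diffs_hotspots <- diffs_hotspots[is.finite(diffs_hotspots)]
  diffs_controls <- diffs_controls[is.finite(diffs_controls)]
  if (!length(diffs_hotspots) || !length(diffs_controls)) {
    stop("need non-empty difference vectors")
  }
  if (B < 1000) warning("B < 1000 bootstrap resamples")
  set.seed(seed)
  nh <- length(diffs_hotspots)
  draws <- colMeans(matrix(
    sample(diffs_controls, nh * B, replace = TRUE), nrow = nh
  ))
  observed <- mean(diffs_hotspots)
  p <- (1 + sum(abs(draws) >= abs(observed))) / (B + 1)
  list(observed = observed, draws = draws, empirical_p = p, B = B,
       seed = seed)
}

#' Mean recombination rate as a function of distance to nearest peak
#'
#' Each recombination-map segment is assigned to a distance bin by the
#' distance from its midpoint to the nearest peak (0 for segments whose
#' midpoint lies in a peak); the profile is the bp-weighted mean rate per
#' bin.  Segments on chromosomes without peaks are excluded.
#'
#' @param rec_map `GRanges` with `score` (cM/Mb).
#' @param peaks `GRanges`.
#' @param bin_edges increasing bp distances starting at 0; a final
#'   open-ended bin is added.  Default 0, 5 kb, ..., 100 kb, then open.
#' @return `data.frame` with bin bounds, bp-weighted `mean_rate`, total `bp`
#'   and segment count per bin.
#' @export
recombination_distance_profile <- function(rec_map, peaks,
                                           bin_edges = seq(0, 1e5, by = 5e3)) {
  if (bin_edges[1] != 0 || is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin edges must be increasing and start at 0")
  }
  mid <- (GenomicRanges::start(rec_map) + GenomicRanges::end(rec_map)) %/% 2
  midpoints <- GenomicRanges::GRanges(GenomicRanges::seqnames(rec_map),
                                      IRanges::IRanges(mid, width = 1))
  d <- distance_to_nearest(midpoints, peaks)
  keep <- is.finite(d)
  edges <- c(bin_edges, Inf)
  bin <- findInterval(d[keep], edges, left.open = FALSE)
  w <- GenomicRanges::width(rec_map)[keep]
  r <- S4Vectors::mcols(rec_map)$score[keep]
  nb <- length(edges) - 1
  num <- rowsum_vec(w * r, bin, nb)
  den <- rowsum_vec(w, bin, nb)
  data.frame(
    bin_lo = edges[seq_len(nb)],
    bin_hi = edges[-1],
    mean_rate = ifelse(den > 0, num / den, NA_real_),
    bp = den,
    n_segments = tabulate(bin, nb)
  )
}

#' Grouped feature comparison with t-test or ANOVA
#'
#' Group means with 95% normal-approximation confidence intervals, plus a
#' one-way ANOVA across all groups or pairwise Welch t-tests.
#'
#' @param values_by_group named list of numeric vectors (>= 2 groups).
#' @param test `"anova"` or `"t"` (pairwise Welch).
#' @return list with `summary` (data.frame: group, n, mean, ci_lo, ci_hi)
#'   and `test` (ANOVA result, or data.frame of pairwise t results).
#' @export
group_feature_comparison <- function(values_by_group, test = c("anova", "t")) {
  test <- match.arg(test)
  if (length(values_by_group) < 2) stop("need >= 2 groups")
  if (is.null(names(values_by_group))) {
    names(values_by_group) <- paste0("group", seq_along(values_by_group))
  }
  values_by_group <- lapply(values_by_group, function(v) v[is.finite(v)])
  summ <- do.call(rbind, lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    se <- stats::sd(v) / sqrt(length(v))
    data.frame(group = g, n = length(v), mean = mean(v),
               ci_lo = mean(v) - 1.96 * se, ci_hi = mean(v) + 1.96 * se,
               stringsAsFactors = FALSE)
  }))
  res <- if (test == "anova") {
    one_way_anova(values_by_group)
  } else {
    cmb <- utils::combn(names(values_by_group), 2)
    do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      tt <- two_sample_t(values_by_group[[cmb[1, i]]],
                         values_by_group[[cmb[2, i]]])
      data.frame(group1 = cmb[1, i], group2 = cmb[2, i],
                 t = tt$t, p = tt$p, stringsAsFactors = FALSE)
    }))
  }
  list(summary = summ, test = res)
}
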