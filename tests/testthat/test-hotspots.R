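small_identity_syn <- function(len = 1e5) {
  layout <- genome_layout("chr1", len)
  fwd <- synteny_map(
    data.frame(src_chrom = "chr1", src_start = 0, src_end = len,
               dst_chrom = "chr1", dst_start = 0, dst_end = len,
               strand = "+"),
    src_layout = layout, dst_layout = layout
  )
  list(forward = fwd, reverse = invert_synteny(fwd), layout = layout)
}

test_that("cross-species classification partitions both hotspot sets", {
  syn <- small_identity_syn()
  hs_a <- gr("chr1", c(1000, 5000, 9000), c(2000, 6000, 10000), syn$layout)
  hs_b <- gr("chr1", c(5500, 20000), c(6500, 21000), syn$layout)
  cls <- classify_cross_species(hs_a, hs_b, syn$forward, syn$reverse)
  expect_equal(cls$counts$species_specific_a, 2)
  expect_equal(cls$counts$common, 1)
  expect_equal(cls$counts$species_specific_b, 1)
  # partition: labels cover every hotspot exactly once
  expect_equal(sum(table(cls$labels_a)), 3)
  expect_equal(sum(table(cls$labels_b)), 2)
  # syntenic projections of the partner-specific hotspots are emitted
  expect_length(cls$syntenic_b_in_a, 1)
  expect_length(cls$syntenic_a_in_b, 2)
})

test_that("hotspots with no synteny coverage are reported unmappable, never common", {
  layout <- genome_layout("chr1", 1e5)
  # map covering an unrelated region only
  fwd <- synteny_map(data.frame(
    src_chrom = "chr1", src_start = 90000, src_end = 95000,
    dst_chrom = "chr1", dst_start = 90000, dst_end = 95000, strand = "+"
  ), src_layout = layout, dst_layout = layout)
  hs <- gr("chr1", c(1000, 2000), c(1500, 2500), layout)
  cls <- classify_cross_species(hs, hs, fwd, invert_synteny(fwd))
  expect_equal(cls$counts$unmapped_a, 2)
  expect_equal(cls$counts$common, 0)
})

test_that("reciprocal and one-directional common calls can differ", {
  # A-projection hits b1, but b1 projects elsewhere (non-invertible map)
  layout <- genome_layout("chr1", 1e5)
  fwd <- synteny_map(data.frame(
    src_chrom = "chr1", src_start = 0, src_end = 10000,
    dst_chrom = "chr1", dst_start = 20000, dst_end = 30000, strand = "+"
  ), src_layout = layout, dst_layout = layout)
  bwd <- synteny_map(data.frame(
    src_chrom = "chr1", src_start = 20000, src_end = 30000,
    dst_chrom = "chr1", dst_start = 60000, dst_end = 70000, strand = "+"
  ), src_layout = layout, dst_layout = layout)
  hs_a <- gr("chr1", 1000, 2000, layout)
  hs_b <- gr("chr1", 21000, 22000, layout)
  one_dir <- classify_cross_species(hs_a, hs_b, fwd, bwd, reciprocal = FALSE)
  recip <- classify_cross_species(hs_a, hs_b, fwd, bwd, reciprocal = TRUE)
  expect_equal(one_dir$counts$common, 1)
  expect_equal(recip$counts$common, 0)
})

test_that("mouse SNP/DSB classification counts overlaps on the DSB side", {
  layout <- genome_layout("chr1", 1e5)
  snp <- gr("chr1", c(0, 20), c(10, 30), layout)
  dsb <- gr("chr1", 25, 35, layout)
  cls <- classify_mouse(snp, dsb)
  expect_equal(cls$counts$snp_only, 1)
  expect_equal(cls$counts$dsb_only, 0)
  expect_equal(cls$counts$snp_dsb, 1)
  # identical sets: everything shared
  cls2 <- classify_mouse(snp, snp)
  expect_equal(cls2$counts$snp_only, 0)
  expect_equal(cls2$counts$dsb_only, 0)
  expect_equal(cls2$counts$snp_dsb, 2)
  # one SNP hotspot carrying two DSB hotspots: counts differ by side
  dsb2 <- gr("chr1", c(0, 5), c(3, 9), layout)
  cls3 <- classify_mouse(snp, dsb2)
  expect_equal(cls3$counts$snp_dsb, 2)
  expect_equal(cls3$counts$snp_shared, 1)
  expect_equal(cls3$counts$snp_only, 1)
})

test_that("enrichment of a feature set against itself is maximal and reported with provenance", {
  layout <- genome_layout(c("chr1", "chr2"), c(1e6, 1e6))
  hs <- random_intervals(100, layout, max_len = 2000, seed = 91)
  hs <- GenomicRanges::reduce(hs)
  e <- overlap_enrichment(hs, hs, layout, excluded = GenomicRanges::GRanges(),
                          n_controls = 100, seed = 92)
  expect_equal(e$observed, length(hs))
  expect_gte(e$fold, 1)
  expect_equal(e$n_controls, 100)
  expect_equal(e$seed, 92)
  expect_lt(e$p_mc, 0.05)
  expect_error(overlap_enrichment(hs, hs, layout, n_controls = 10), ">= 100")
})

test_that("bootstrap divergence null hits its bounds on extreme and degenerate input", {
  set.seed(93)
  ctl <- rnorm(1000)
  shifted <- rnorm(50) + 10 * sd(ctl)
  bn <- methylation_divergence_null(shifted, ctl, B = 1000, seed = 94)
  expect_equal(bn$empirical_p, 1 / 1001)
  z <- methylation_divergence_null(rep(0, 10), rep(0, 100), B = 1000, seed = 95)
  expect_equal(z$empirical_p, 1)
  expect_warning(methylation_divergence_null(rnorm(10), ctl, B = 500, seed = 1),
                 "B < 1000")
})

test_that("distance profiles are flat for uniform maps and respond to planted elevation", {
  layout <- genome_layout("chr1", 1e6)
  segs <- tile_windows(layout, 1e4)
  peaks <- gr("chr1", c(1e5, 5e5), c(1.01e5, 5.01e5), layout)
  S4Vectors::mcols(segs)$score <- 2.5
  prof <- recombination_distance_profile(segs, peaks)
  expect_true(all(abs(prof$mean_rate[prof$bp > 0] - 2.5) < 1e-12))

  # doubled rate for segments whose midpoint is inside a peak
  wide_peaks <- gr("chr1", c(1e5, 5e5), c(1.3e5, 5.3e5), layout)
  mid_in <- IRanges::overlapsAny(
    GenomicRanges::resize(segs, 1, fix = "center"), wide_peaks)
  S4Vectors::mcols(segs)$score <- ifelse(mid_in, 5, 2.5)
  # a leading [0, 1) bin isolates the distance-0 (inside-peak) segments
  prof2 <- recombination_distance_profile(
    segs, wide_peaks, bin_edges = c(0, 1, seq(5000, 1e5, by = 5000)))
  expect_equal(prof2$mean_rate[1], 5)
  far <- prof2$mean_rate[prof2$bin_lo >= 5e4 & prof2$bp > 0]
  expect_true(all(abs(far - 2.5) < 1e-12))

  # chromosomes without peaks are excluded, others unaffected
  layout2 <- genome_layout(c("chr1", "chr2"), c(1e6, 1e6))
  segs2 <- tile_windows(layout2, 1e4)
  S4Vectors::mcols(segs2)$score <- 1
  peaks1 <- gr("chr1", 0, 1000, layout2)
  prof3 <- recombination_distance_profile(segs2, peaks1)
  expect_equal(sum(prof3$n_segments), 100)
  expect_error(recombination_distance_profile(segs2, peaks1,
                                              bin_edges = c(5, 10)),
               "start at 0")
})

test_that("group comparisons report means with CIs and recover planted ordering", {
  g <- list(a = rep(1, 50) + 0, b = rep(1, 50) + 0)
  res <- group_feature_comparison(g, test = "anova")
  expect_equal(res$summary$mean, c(1, 1))
  expect_equal(res$test$p, 1)

  set.seed(96)
  g2 <- list(x = rnorm(40), y = rnorm(40, 0.5))
  res2 <- group_feature_comparison(g2, test = "t")
  a2 <- group_feature_comparison(g2, test = "anova")
  expect_equal(a2$test$F, res2$test$t^2, tolerance = 0.2)  # Welch vs pooled

  ordered_ok <- vapply(1:5, function(s) {
    set.seed(200 + s)
    gg <- list(lo = rnorm(500, 0.60, 0.1), mid = rnorm(500, 0.65, 0.1),
               hi = rnorm(500, 0.70, 0.1))
    r <- group_feature_comparison(gg, test = "anova")
    all(diff(r$summary$mean) > 0) && r$test$p < 0.05
  }, logical(1))
  expect_true(all(ordered_ok))
})
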