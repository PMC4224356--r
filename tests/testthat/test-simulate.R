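test_that("genome generation is reproducible with the requested composition", {
  g <- make_genome(2, 1e6, seed = 101)
  expect_equal(GenomeInfoDb::seqnames(g$layout), c("chr1", "chr2"))
  expect_equal(unname(GenomeInfoDb::seqlengths(g$layout)), c(1e6, 1e6))
  g1 <- make_genome(1, 1e5, gc = 0.5, seed = 102, sequence = TRUE)
  g2 <- make_genome(1, 1e5, gc = 0.5, seed = 102, sequence = TRUE)
  expect_identical(as.character(g1$seq), as.character(g2$seq))
  expect_lt(abs(gc_content(g1$seq[[1]]) - 0.5), 0.01)
})

test_that("synteny generation keeps the indel bookkeeping and inverts cleanly", {
  layout <- genome_layout("chr1", 1e6)
  id <- make_synteny_map(layout, indel_rate = 0, seed = 103)
  expect_equal(nrow(id$forward), 1)
  expect_equal(id$forward$src_end, 1e6)
  expect_equal(unname(GenomeInfoDb::seqlengths(id$dst_layout)), 1e6)

  syn <- make_synteny_map(layout, indel_rate = 1e-4, seed = 104)
  map <- syn$forward
  aligned <- sum(map$src_end - map$src_start)
  deleted <- 1e6 - aligned
  inserted <- unname(GenomeInfoDb::seqlengths(syn$dst_layout)) - aligned
  expect_gte(deleted, 0)
  expect_gte(inserted, 0)
  expect_equal(sum(map$dst_end - map$dst_start), aligned)
})

test_that("paired hotspot generation plants exactly the requested sharing", {
  layout <- genome_layout(c("chr1", "chr2"), c(1e6, 1e6))
  syn <- make_synteny_map(layout, indel_rate = 1e-4, seed = 105)
  hs <- make_paired_hotspots(syn, 20, 10, 5, seed = 106)
  expect_length(hs$hs_a, 20)
  expect_length(hs$hs_b, 10)
  cls <- classify_cross_species(hs$hs_a, hs$hs_b, syn$forward, syn$reverse)
  expect_equal(cls$counts$species_specific_a, 15)
  expect_equal(cls$counts$species_specific_b, 5)
  expect_equal(cls$counts$common, 5)
  expect_equal(cls$counts$unmapped_a, 0)

  hs0 <- make_paired_hotspots(syn, 8, 6, 0, seed = 107)
  cls0 <- classify_cross_species(hs0$hs_a, hs0$hs_b, syn$forward, syn$reverse)
  expect_equal(cls0$counts$common, 0)
  expect_error(make_paired_hotspots(syn, 5, 3, 4, seed = 1), "n_shared")
  expect_error(make_paired_hotspots(syn, 1e5, 1e5, 0, seed = 1),
               "generation-failure")
})

test_that("mouse hotspot generation supports doubly-overlapped SNP hotspots", {
  layout <- genome_layout("chr1", 5e6)
  hs <- make_mouse_hotspots(layout, n_snp = 50, n_dsb = 30, n_shared_dsb = 12,
                            n_shared_snp = 10, seed = 108)
  cls <- classify_mouse(hs$snp, hs$dsb)
  expect_equal(cls$counts$snp_only, 40)
  expect_equal(cls$counts$dsb_only, 18)
  expect_equal(cls$counts$snp_dsb, 12)
  expect_equal(cls$counts$snp_shared, 10)
  expect_error(make_mouse_hotspots(layout, 50, 30, 12, 5, seed = 1),
               "n_shared_snp")
})

test_that("correlated field generation hits its marginal and null targets", {
  f <- make_correlated_fields(5000, rho = 0, seed = 109)
  expect_lt(abs(cor(f$m, f$rate)), 2 / sqrt(5000))
  f1 <- make_correlated_fields(100, rho = 0.2, seed = 110)
  f2 <- make_correlated_fields(100, rho = 0.2, seed = 110)
  expect_identical(f1, f2)
  expect_error(make_correlated_fields(100, rho = 0.999), "unattainable")
})

test_that("methylome generation respects the window-level truth", {
  layout <- genome_layout("chr1", 1e6)
  win <- tile_windows(layout, 5e5)
  trk <- make_methylome(layout, win, window_m = c(0.8, 0.8), depth = 200,
                        site_spacing = 1000, seed = 111)
  est <- regional_methylation(trk, win)
  se <- sqrt(0.8 * 0.2 / 200 / 500)
  expect_true(all(abs(est - 0.8) < 4 * se))
})

test_that("recombination map generation multiplies rates inside hotspots", {
  layout <- genome_layout("chr1", 1e6)
  win <- tile_windows(layout, 5e5)
  flat <- make_recombination_map(layout, win, window_rate = c(1, 1))
  expect_equal(unique(S4Vectors::mcols(flat)$score), 1)
  hs <- gr("chr1", c(1e5, 7e5), c(1.02e5, 7.02e5), layout)
  sp <- make_recombination_map(layout, win, c(1, 1), hotspots = hs,
                               hotspot_multiplier = 10)
  expect_equal(region_recombination_rate(sp, hs), c(10, 10))
  expect_equal(region_recombination_rate(sp, gr("chr1", 0, 1e5, layout)), 1)
})

test_that("planted-fold peak generation has exact zero and null extremes", {
  layout <- genome_layout(c("chr1", "chr2"), c(5e6, 5e6))
  hs <- random_intervals(200, layout, max_len = 3000, seed = 112)
  hs <- GenomicRanges::reduce(hs)
  pk0 <- make_peaks(layout, hs, fold = 0, n_peaks = 1000, seed = 113)
  expect_equal(count_overlapping(hs, pk0), 0)
  expect_length(pk0, 1000)
  expect_error(make_peaks(layout, hs, fold = -1), "fold")
})

test_that("published-scale presets reproduce their published set-partition counts", {
  # scaled-down structural check; the full presets run in the acceptance suite
  p <- preset_humanchimp()
  expect_equal(p$n_a - p$n_shared, 9169)
  expect_equal(p$n_b - p$n_shared, 4906)
  m <- preset_mouse()
  expect_equal(m$n_snp - m$n_shared_snp, 44498)
  expect_equal(m$n_dsb - m$n_shared_dsb, 7303)
})
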