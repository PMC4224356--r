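test_that("window tiling emits consecutive windows with flagged partials", {
  w <- tile_windows(genome_layout("chr1", 1.2e6), 5e5)
  expect_equal(granges_to_bed(w)$start, c(0, 5e5, 1e6))
  expect_equal(granges_to_bed(w)$end, c(5e5, 1e6, 1.2e6))
  expect_equal(S4Vectors::mcols(w)$partial, c(FALSE, FALSE, TRUE))

  w2 <- tile_windows(genome_layout("chr1", 5e5), 5e5)
  expect_length(w2, 1)
  expect_false(any(S4Vectors::mcols(w2)$partial))

  w3 <- tile_windows(genome_layout(c("chr1", "chr2"), c(1e6, 1e6)), 2.5e5)
  expect_length(w3, 8)
  expect_false(any(S4Vectors::mcols(w3)$partial))

  expect_error(tile_windows(genome_layout("chr1", 1e6), 0), "invalid-parameter")
})

test_that("overlap counting uses half-open semantics and counts each query once", {
  layout <- genome_layout("chr1", 1e6)
  expect_equal(count_overlapping(gr("chr1", 0, 10, layout),
                                 gr("chr1", 5, 15, layout)), 1)
  expect_equal(count_overlapping(gr("chr1", 0, 10, layout),
                                 gr("chr1", 10, 20, layout)), 0)
  q <- random_intervals(100, layout, seed = 1)
  expect_equal(count_overlapping(q, q), 100)
  # min_bp threshold
  expect_equal(count_overlapping(gr("chr1", 0, 10, layout),
                                 gr("chr1", 5, 15, layout), min_bp = 6), 0)
  expect_error(
    count_overlapping(gr("chr1", 0, 10, layout),
                      gr("chrX", 0, 10, genome_layout("chrX", 2e6))),
    "layout-mismatch"
  )
})

test_that("overlap counting matches a brute-force pairwise scan", {
  layout <- genome_layout(c("chr1", "chr2"), c(2e5, 1e5))
  set.seed(42)
  for (i in 1:5) {
    q <- random_intervals(200, layout, max_len = 500)
    s <- random_intervals(300, layout, max_len = 500)
    expect_equal(count_overlapping(q, s), brute_overlap_count(q, s))
    expect_equal(count_overlapping(q, s, min_bp = 100),
                 brute_overlap_count(q, s, min_bp = 100))
  }
})

test_that("nearest-distance returns gaps, zeros on overlap, NA off-chromosome", {
  layout <- genome_layout(c("chr1", "chr2"), c(1e6, 1e6))
  subj <- gr("chr1", c(200, 415), c(300, 500), layout)
  expect_equal(distance_to_nearest(gr("chr1", 100, 101, layout), subj[1]), 99)
  expect_equal(distance_to_nearest(gr("chr1", 250, 260, layout), subj[1]), 0)
  expect_equal(distance_to_nearest(gr("chr1", 400, 410, layout), subj), 5)
  expect_true(is.na(distance_to_nearest(gr("chr2", 0, 10, layout), subj)))
  expect_warning(
    d <- distance_to_nearest(gr("chr1", 0, 10, layout),
                             GenomicRanges::GRanges()),
    "empty subject"
  )
  expect_true(all(is.na(d)))
})

test_that("complement tiles the genome exactly once together with its set", {
  layout <- genome_layout("chr1", 1e6)
  expect_equal(granges_to_bed(interval_complement(layout, GenomicRanges::GRanges())),
               data.frame(chrom = "chr1", start = 0, end = 1e6))
  expect_length(interval_complement(layout, gr("chr1", 0, 1e6, layout)), 0)
  cmp <- interval_complement(layout, gr("chr1", 100, 200, layout))
  expect_equal(granges_to_bed(cmp)[, c("start", "end")],
               data.frame(start = c(0, 200), end = c(100, 1e6)))

  # base-count property on random sets
  layout2 <- genome_layout(c("chr1", "chr2"), c(5e4, 3e4))
  for (s in 1:5) {
    x <- random_intervals(30, layout2, max_len = 2000, seed = s)
    cmp <- interval_complement(layout2, x)
    both <- c(GenomicRanges::reduce(x), cmp)
    expect_equal(sum(GenomicRanges::width(both)), 8e4)
    expect_true(GenomicRanges::isDisjoint(both))
  }
})

test_that("control regions preserve the template length multiset and avoid excluded space", {
  layout <- genome_layout("chr1", 1e6)
  template <- gr("chr1", c(0, 5000), c(1000, 7000), layout)
  ctrl <- sample_control_regions(template, layout, template, n = 2, seed = 3)
  expect_setequal(GenomicRanges::width(ctrl), c(1000, 2000))

  # only one 10 kb gap of eligible space
  excluded <- gr("chr1", c(0, 510000), c(500000, 1e6), layout)
  tpl <- gr("chr1", 0, 1000, layout)[rep(1, 5)]
  ctrl2 <- sample_control_regions(tpl, layout, excluded, n = 5, seed = 4)
  expect_true(all(GenomicRanges::start(ctrl2) - 1 >= 500000 &
                    GenomicRanges::end(ctrl2) <= 510000))

  # zero intersection with excluded, any template
  hs <- random_intervals(50, layout, max_len = 3000, seed = 5)
  ctrl3 <- sample_control_regions(hs, layout, hs, n = 500, seed = 6)
  expect_equal(sum(GenomicRanges::width(
    GenomicRanges::intersect(ctrl3, GenomicRanges::reduce(hs)))), 0)

  # reproducible under a fixed seed
  expect_identical(
    sample_control_regions(hs, layout, hs, n = 100, seed = 9),
    sample_control_regions(hs, layout, hs, n = 100, seed = 9)
  )

  # impossible placement names the offending length
  expect_error(
    sample_control_regions(gr("chr1", 0, 20000, layout), layout,
                           excluded, n = 1, seed = 1),
    "placement-failure.*20000"
  )
})
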