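#' Generate a synthetic genome layout (and optionally random sequence)
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param gc G+C fraction of the random sequence.
#' @param seed integer seed.
#' @param sequence also generate random i.i.d. sequence (default `FALSE`;
#'   only needed when sequence features are being computed).
#' @return list with `layout` (`Seqinfo`) and `seq` (named `DNAStringSet`
#'   or `NULL`).
#' @export
make_genome <- function(n_chrom = 2L, chrom_length = 1e6, gc = 0.41,
                        seed = 1L, sequence = FALSE) {
  set.seed(seed)
  layout <- genome_layout(paste0("chr", seq_len(n_chrom)),
                          rep(chrom_length, n_chrom))
  seqs <- NULL
  if (sequence) {
    prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    seqs <- Biostrings::DNAStringSet(vapply(seq_len(n_chrom), function(i) {
      paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE,
                   prob = prob), collapse = "")
    }, character(1)))
    names(seqs) <- GenomeInfoDb::seqnames(layout)
  }
  list(layout = layout, seq = seqs)
}

#' Generate a synteny map with random indels
#'
#' Walks each chromosome emitting aligned blocks (exponential lengths, mean
#' `1 / indel_rate`) separated by short insertions or deletions.  With
#' `indel_rate = 0` the map is the identity.  Forward and reverse maps are
#' mutually inverse on all aligned bases, so any interval fully inside a
#' block round-trips to itself.
#'
#' @param layout source-genome `Seqinfo`.
#' @param indel_rate per-bp indel rate (mean aligned block length is its
#'   reciprocal).
#' @param indel_size min and max indel length in bp.
#' @param seed integer seed.
#' @return list with `forward` / `reverse` (`synteny_map`s) and
#'   `dst_layout` (`Seqinfo` of the destination genome).
#' @export
make_synteny_map <- function(layout, indel_rate = 1e-5,
                             indel_size = c(10L, 50L), seed = 1L) {
  set.seed(seed)
  chroms <- GenomeInfoDb::seqnames(layout)
  lens <- GenomeInfoDb::seqlengths(layout)
  rows <- list()
  dst_len <- numeric(length(chroms))
  names(dst_len) <- chroms
  for (ci in seq_along(chroms)) {
    L <- lens[ci]
    src <- 0; dst <- 0
    while (src < L) {
      blen <- if (indel_rate == 0) L else
        max(1, min(round(stats::rexp(1, indel_rate)), L - src))
      rows[[length(rows) + 1L]] <- data.frame(
        src_chrom = chroms[ci], src_start = src, src_end = src + blen,
        dst_chrom = chroms[ci], dst_start = dst, dst_end = dst + blen,
        strand = "+", stringsAsFactors = FALSE
      )
      src <- src + blen
      dst <- dst + blen
      if (src < L) {
        isz <- sample(indel_size[1]:indel_size[2], 1)
        if (stats::runif(1) < 0.5) {
          src <- min(src + isz, L)   # deletion: source bases unaligned
        } else {
          dst <- dst + isz           # insertion in destination
        }
      }
    }
    dst_len[ci] <- dst
  }
  dst_layout <- genome_layout(chroms, dst_len)
  fwd <- synteny_map(do.call(rbind, rows), src_layout = layout,
                     dst_layout = dst_layout)
  list(forward = fwd, reverse = invert_synteny(fwd), dst_layout = dst_layout)
}

# candidate hotspot start positions: interior of aligned source blocks, with
# enough margin that a hotspot of max_len never touches a block edge, spaced
# so hotspots at distinct slots (and their projections) can never overlap
synteny_slots <- function(map, spacing, max_len) {
  margin <- max_len
  per_block <- lapply(seq_len(nrow(map)), function(i) {
    lo <- map$src_start[i] + margin
    hi <- map$src_end[i] - margin - max_len
    if (hi < lo) numeric(0) else seq(lo, hi, by = spacing)
  })
  data.frame(
    chrom = rep(map$src_chrom, lengths(per_block)),
    start = unlist(per_block, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Generate paired hotspot sets for two genomes with controlled sharing
#'
#' Places `n_a` hotspots in genome A and `n_b` in genome B such that exactly
#' `n_shared` A-hotspots have synteny projections overlapping a B-hotspot
#' (reciprocally), and no other projection overlaps.  Hotspots sit fully
#' inside aligned synteny blocks at well-separated slots, so every hotspot
#' maps with complete coverage and classification recovers the counts
#' exactly, for identity as well as indel-bearing maps.
#'
#' @param synteny output of [make_synteny_map()] (forward/reverse pair).
#' @param n_a,n_b,n_shared hotspot counts (`n_shared <= min(n_a, n_b)`).
#' @param length_dist min and max hotspot length in bp (uniform draw).
#' @param spacing distance between candidate slots (must exceed twice the
#'   maximum hotspot length).
#' @param seed integer seed.
#' @return list with `hs_a`, `hs_b` (`GRanges`).
#' @export
make_paired_hotspots <- function(synteny, n_a, n_b, n_shared,
                                 length_dist = c(1000L, 3000L),
                                 spacing = 8000L, seed = 1L) {
  if (n_shared > min(n_a, n_b)) stop("n_shared must be <= min(n_a, n_b)")
  if (spacing <= 2 * length_dist[2]) {
    stop("spacing must exceed twice the maximum hotspot length")
  }
  set.seed(seed)
  map <- synteny$forward
  slots <- synteny_slots(map, spacing, length_dist[2])
  need <- n_a + n_b - n_shared
  if (nrow(slots) < need) {
    stop("generation-failure: ", nrow(slots), " slots available, ", need,
         " needed; enlarge the genome or reduce counts")
  }
  slots <- slots[sample(nrow(slots), need), ]
  layout_a <- attr(map, "src_layout")

  len_a <- sample(length_dist[1]:length_dist[2], n_a, replace = TRUE)
  hs_a <- bed_granges(slots$chrom[seq_len(n_a)], slots$start[seq_len(n_a)],
                      slots$start[seq_len(n_a)] + len_a, layout = layout_a)

  # genome-B hotspots: projections of the shared A-hotspots, plus
  # projections of fresh intervals at the remaining (unused-by-A) slots
  shared_src <- bed_granges(slots$chrom[seq_len(n_shared)],
                            slots$start[seq_len(n_shared)],
                            slots$start[seq_len(n_shared)] + len_a[seq_len(n_shared)],
                            layout = layout_a)
  b_idx <- seq(n_a + 1, length.out = n_b - n_shared)
  len_b <- sample(length_dist[1]:length_dist[2], n_b - n_shared, replace = TRUE)
  bonly_src <- bed_granges(slots$chrom[b_idx], slots$start[b_idx],
                           slots$start[b_idx] + len_b, layout = layout_a)
  src_b <- c(shared_src, bonly_src)
  proj <- map_via_synteny(src_b, map, min_fraction = 1)
  if (length(proj$unmapped)) {
    stop("generation-failure: slot placement produced unmappable hotspots")
  }
  hs_b <- proj$mapped
  S4Vectors::mcols(hs_b) <- NULL
  list(hs_a = sort(hs_a), hs_b = sort(hs_b))
}

#' Generate mouse SNP and DSB hotspot sets with controlled overlap
#'
#' Places `n_snp` SNP (historical) hotspots and `n_dsb` DSB (current)
#' hotspots on one genome such that exactly `n_shared_dsb` DSB hotspots
#' overlap a SNP hotspot, spread over `n_shared_snp` distinct SNP hotspots
#' (when `n_shared_dsb > n_shared_snp`, some SNP hotspots carry two DSB
#' hotspots, as observed in real hotspot catalogues).
#'
#' @param layout a `Seqinfo`.
#' @param n_snp,n_dsb set sizes.
#' @param n_shared_dsb DSB hotspots overlapping a SNP hotspot.
#' @param n_shared_snp SNP hotspots overlapped by a DSB hotspot (default
#'   `n_shared_dsb`; must satisfy `n_shared_snp <= n_shared_dsb <=
#'   2 * n_shared_snp`).
#' @param length_dist,spacing,seed as [make_paired_hotspots()].
#' @return list with `snp`, `dsb` (`GRanges`).
#' @export
make_mouse_hotspots <- function(layout, n_snp, n_dsb, n_shared_dsb,
                                n_shared_snp = n_shared_dsb,
                                length_dist = c(1000L, 3000L),
                                spacing = 8000L, seed = 1L) {
  if (n_shared_snp > n_shared_dsb || n_shared_dsb > 2 * n_shared_snp) {
    stop("need n_shared_snp <= n_shared_dsb <= 2 * n_shared_snp")
  }
  if (n_shared_dsb > n_dsb || n_shared_snp > n_snp) {
    stop("shared counts exceed set sizes")
  }
  if (spacing <= 2 * length_dist[2]) {
    stop("spacing must exceed twice the maximum hotspot length")
  }
  set.seed(seed)
  chroms <- GenomeInfoDb::seqnames(layout)
  lens <- GenomeInfoDb::seqlengths(layout)
  max_len <- length_dist[2]
  slot_list <- lapply(seq_along(chroms), function(ci) {
    s <- seq(max_len, lens[ci] - 2 * max_len, by = spacing)
    data.frame(chrom = chroms[ci], start = s, stringsAsFactors = FALSE)
  })
  slots <- do.call(rbind, slot_list)
  need <- n_snp + (n_dsb - n_shared_dsb)
  if (nrow(slots) < need) {
    stop("generation-failure: ", nrow(slots), " slots available, ", need,
         " needed")
  }
  slots <- slots[sample(nrow(slots), need), ]

  n_double <- n_shared_dsb - n_shared_snp   # SNP hotspots carrying 2 DSBs
  len_snp <- sample(length_dist[1]:length_dist[2], n_snp, replace = TRUE)
  # doubled SNP hotspots (the first n_double) need room for two disjoint
  # DSB hotspots inside them
  if (n_double > 0) len_snp[seq_len(n_double)] <- max_len
  snp <- bed_granges(slots$chrom[seq_len(n_snp)], slots$start[seq_len(n_snp)],
                     slots$start[seq_len(n_snp)] + len_snp, layout = layout)

  dsb_chrom <- character(0); dsb_s <- numeric(0); dsb_e <- numeric(0)
  if (n_double > 0) {
    i <- seq_len(n_double)
    third <- max_len %/% 3
    dsb_chrom <- c(dsb_chrom, rep(slots$chrom[i], 2))
    dsb_s <- c(dsb_s, slots$start[i], slots$start[i] + 2 * third)
    dsb_e <- c(dsb_e, slots$start[i] + third, slots$start[i] + max_len)
  }
  if (n_shared_snp > n_double) {
    i <- seq(n_double + 1, n_shared_snp)
    L <- sample(length_dist[1]:length_dist[2], length(i), replace = TRUE)
    dsb_chrom <- c(dsb_chrom, slots$chrom[i])
    dsb_s <- c(dsb_s, slots$start[i])
    dsb_e <- c(dsb_e, slots$start[i] + L)
  }
  if (n_dsb > n_shared_dsb) {
    i <- seq(n_snp + 1, need)
    L <- sample(length_dist[1]:length_dist[2], length(i), replace = TRUE)
    dsb_chrom <- c(dsb_chrom, slots$chrom[i])
    dsb_s <- c(dsb_s, slots$start[i])
    dsb_e <- c(dsb_e, slots$start[i] + L)
  }
  dsb <- bed_granges(dsb_chrom, dsb_s, dsb_e, layout = layout)
  list(snp = sort(snp), dsb = sort(dsb))
}

#' Published-scale synthetic presets
#'
#' Named parameter bundles reproducing the published hotspot-catalogue
#' sizes: `preset_humanchimp()` plants 9,300 human and 5,037 chimpanzee
#' hotspots of which 131 are shared; `preset_mouse()` plants 47,068 SNP and
#' 9,874 DSB hotspots with 2,571 DSB hotspots overlapping 2,570 SNP
#' hotspots (one SNP hotspot carries two DSB hotspots, which is what makes
#' the published SNP-only/DSB-only/shared counts mutually consistent).
#'
#' @return list of generator parameters.
#' @export
preset_humanchimp <- function() {
  list(kind = "humanchimp",
       n_a = 9300L, n_b = 5037L, n_shared = 131L,
       n_chrom = 10L, chrom_length = 16e6,
       indel_rate = 1e-5, indel_size = c(10L, 50L),
       length_dist = c(1000L, 3000L), spacing = 8000L)
}

#' @rdname preset_humanchimp
#' @export
preset_mouse <- function() {
  list(kind = "mouse",
       n_snp = 47068L, n_dsb = 9874L,
       n_shared_dsb = 2571L, n_shared_snp = 2570L,
       n_chrom = 10L, chrom_length = 48e6,
       length_dist = c(1000L, 3000L), spacing = 8000L)
}

#' Generate the hotspot sets (and maps) of a published-scale preset
#'
#' @param preset output of [preset_humanchimp()] or [preset_mouse()].
#' @param seed integer seed.
#' @return for a human/chimp preset: list with `hs_a`, `hs_b`, `map_ab`,
#'   `map_ba`, `layout_a`, `layout_b`; for a mouse preset: list with `snp`,
#'   `dsb`, `layout`.
#' @export
generate_preset_hotspots <- function(preset, seed = 1L) {
  layout <- genome_layout(paste0("chr", seq_len(preset$n_chrom)),
                          rep(preset$chrom_length, preset$n_chrom))
  if (preset$kind == "humanchimp") {
    syn <- make_synteny_map(layout, indel_rate = preset$indel_rate,
                            indel_size = preset$indel_size, seed = seed)
    hs <- make_paired_hotspots(syn, preset$n_a, preset$n_b, preset$n_shared,
                               length_dist = preset$length_dist,
                               spacing = preset$spacing, seed = seed + 1L)
    list(hs_a = hs$hs_a, hs_b = hs$hs_b,
         map_ab = syn$forward, map_ba = syn$reverse,
         layout_a = layout, layout_b = syn$dst_layout)
  } else {
    hs <- make_mouse_hotspots(layout, preset$n_snp, preset$n_dsb,
                              preset$n_shared_dsb, preset$n_shared_snp,
                              length_dist = preset$length_dist,
                              spacing = preset$spacing, seed = seed)
    list(snp = hs$snp, dsb = hs$dsb, layout = layout)
  }
}

# E[1/depth] for depth = max(1, Poisson(lambda)) — used in the attenuation
# correction of the planted window correlation
mean_inv_depth <- function(lambda) {
  k <- 1:max(200, ceiling(lambda + 10 * sqrt(lambda)))
  stats::dpois(0, lambda) + sum(stats::dpois(k, lambda) / k)
}

#' Generate correlated per-window methylation and recombination-rate fields
#'
#' Latent bivariate-Gaussian construction: window methylation is a linear
#' (clipped) function of one latent normal; the window rate multiplier is a
#' lognormal function of a second latent normal correlated with the first.
#' Because read noise attenuates the observed methylation and the lognormal
#' link attenuates the rate-side correlation, the latent correlation is
#' inflated by the two analytic attenuation factors so the *observed*
#' window-scale Pearson correlation targets `rho`:
#' `a_m = sd_m / sqrt(sd_m^2 + v_noise)` with
#' `v_noise = m(1-m) E[1/depth] / sites_per_window`, and
#' `a_r = sigma / sqrt(exp(sigma^2) - 1)`.
#'
#' @param n_windows number of windows.
#' @param rho target observed correlation (|rho| < 1).
#' @param mean_meth,sd_meth mean and SD of true window methylation.
#' @param base_rate background recombination rate (cM/Mb).
#' @param sigma_rate lognormal SD of the window rate multiplier.
#' @param depth mean read depth per cytosine.
#' @param sites_per_window expected covered cytosines per window.
#' @param seed integer seed.
#' @return list with `m` (true window methylation), `rate` (window rate,
#'   cM/Mb) and the latent correlation used.
#' @export
make_correlated_fields <- function(n_windows, rho, mean_meth = 0.75,
                                   sd_meth = 0.08, base_rate = 1,
                                   sigma_rate = 0.5, depth = 30,
                                   sites_per_window = 250, seed = 1L) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  v_noise <- mean_meth * (1 - mean_meth) * mean_inv_depth(depth) /
    sites_per_window
  a_m <- sd_meth / sqrt(sd_meth^2 + v_noise)
  a_r <- sigma_rate / sqrt(exp(sigma_rate^2) - 1)
  rho_lat <- rho / (a_m * a_r)
  if (abs(rho_lat) >= 0.99) {
    stop("target correlation unattainable after attenuation correction")
  }
  set.seed(seed)
  z1 <- stats::rnorm(n_windows)
  z2 <- rho_lat * z1 + sqrt(1 - rho_lat^2) * stats::rnorm(n_windows)
  m <- pmin(pmax(mean_meth + sd_meth * z1, 0.02), 0.98)
  rate <- base_rate * exp(sigma_rate * z2 - sigma_rate^2 / 2)
  list(m = m, rate = rate, rho_latent = rho_lat)
}

#' Generate a per-cytosine methylome with window-level true methylation
#'
#' CpG sites are placed on a regular grid (`site_spacing` bp apart); each
#' site's read depth is Poisson around `depth` (minimum 1) and its C-read
#' count is Binomial(depth, m) with m the true methylation of the window
#' containing the site.
#'
#' @param layout a `Seqinfo`.
#' @param windows `GRanges` of windows (from [tile_windows()]).
#' @param window_m true methylation per window.
#' @param depth mean read depth.
#' @param site_spacing bp between consecutive sites.
#' @param seed integer seed.
#' @return a methylation track (`GRanges` with `c_reads` / `t_reads`).
#' @export
make_methylome <- function(layout, windows, window_m, depth = 30,
                           site_spacing = 2000L, seed = 1L) {
  set.seed(seed)
  chroms <- GenomeInfoDb::seqnames(layout)
  lens <- GenomeInfoDb::seqlengths(layout)
  pos <- lapply(seq_along(chroms), function(ci) {
    seq(site_spacing %/% 2, lens[ci] - 1, by = site_spacing)
  })
  chrom <- rep(chroms, lengths(pos))
  pos <- unlist(pos, use.names = FALSE)
  sites <- bed_granges(chrom, pos, pos + 1, layout = layout)
  hit <- GenomicRanges::findOverlaps(sites, windows, select = "first")
  m <- window_m[hit]
  d <- pmax(1L, stats::rpois(length(sites), depth))
  c_reads <- stats::rbinom(length(sites), d, m)
  S4Vectors::mcols(sites)$c_reads <- c_reads
  S4Vectors::mcols(sites)$t_reads <- d - c_reads
  sites
}

#' Generate a piecewise-constant recombination map
#'
#' Window-level rates from a smooth field, multiplied by
#' `hotspot_multiplier` inside hotspot intervals; segments are split at
#' window and hotspot boundaries.
#'
#' @param layout a `Seqinfo`.
#' @param windows `GRanges` tiling the genome.
#' @param window_rate rate per window (cM/Mb).
#' @param hotspots `GRanges` (may be empty / `NULL`).
#' @param hotspot_multiplier rate multiplier inside hotspots.
#' @return `GRanges` of non-overlapping segments with `score`.
#' @export
make_recombination_map <- function(layout, windows, window_rate,
                                   hotspots = NULL, hotspot_multiplier = 10) {
  pieces <- GenomicRanges::granges(windows)
  if (!is.null(hotspots) && length(hotspots)) {
    pieces <- GenomicRanges::disjoin(c(pieces, GenomicRanges::granges(hotspots)))
  }
  wi <- GenomicRanges::findOverlaps(pieces, windows, select = "first")
  score <- window_rate[wi]
  if (!is.null(hotspots) && length(hotspots)) {
    in_hs <- IRanges::overlapsAny(pieces, hotspots)
    score[in_hs] <- score[in_hs] * hotspot_multiplier
  }
  S4Vectors::mcols(pieces)$score <- score
  sort(pieces)
}

#' Generate a methylome + recombination map with a planted window correlation
#'
#' Convenience wrapper tying [make_correlated_fields()],
#' [make_methylome()] and [make_recombination_map()] to one layout and
#' window size.
#'
#' @inheritParams make_correlated_fields
#' @param layout a `Seqinfo`.
#' @param window_size window size in bp.
#' @param site_spacing bp between cytosine sites.
#' @param hotspots,hotspot_multiplier optional hotspot spikes on the map.
#' @param seed integer seed.
#' @return list with `windows`, `meth_track`, `rec_map` and `truth`
#'   (the generated fields).
#' @export
make_correlated_bundle <- function(layout, window_size = 5e5, rho = 0.2,
                                   depth = 30, site_spacing = 2000L,
                                   hotspots = NULL, hotspot_multiplier = 10,
                                   mean_meth = 0.75, sd_meth = 0.08,
                                   base_rate = 1, sigma_rate = 0.5,
                                   seed = 1L) {
  windows <- tile_windows(layout, window_size)
  fields <- make_correlated_fields(
    length(windows), rho, mean_meth = mean_meth, sd_meth = sd_meth,
    base_rate = base_rate, sigma_rate = sigma_rate, depth = depth,
    sites_per_window = window_size / site_spacing, seed = seed
  )
  meth <- make_methylome(layout, windows, fields$m, depth = depth,
                         site_spacing = site_spacing, seed = seed + 1L)
  rec_map <- make_recombination_map(layout, windows, fields$rate,
                                    hotspots = hotspots,
                                    hotspot_multiplier = hotspot_multiplier)
  list(windows = windows, meth_track = meth, rec_map = rec_map,
       truth = fields)
}

#' Generate a peak set with planted fold enrichment over hotspots
#'
#' Background peaks are placed uniformly over hotspot-free sequence; the
#' number of hotspots that should appear peak-overlapped at the requested
#' fold is computed from the empirically estimated null hit probability
#' (the same null that [overlap_enrichment()] resamples), and that many
#' peaks are planted fully inside distinct hotspots.  With `fold = 1` no
#' excess is planted beyond the null expectation; with `fold = 0` no
#' hotspot overlaps any peak.
#'
#' @param layout a `Seqinfo`.
#' @param hotspots `GRanges`.
#' @param fold target fold enrichment (>= 0).
#' @param peak_length peak length in bp.
#' @param n_peaks total number of peaks.
#' @param n_mc control draws used to estimate the null hit probability.
#' @param seed integer seed.
#' @return `GRanges` of peaks.
#' @export
make_peaks <- function(layout, hotspots, fold, peak_length = 1000L,
                       n_peaks = 20000L, n_mc = 20000L, seed = 1L) {
  if (fold < 0) stop("fold must be >= 0")
  set.seed(seed)
  free <- interval_complement(layout, hotspots)
  if (fold == 0) {
    return(sort(place_lengths(rep(peak_length, n_peaks), free, layout)))
  }
  base <- place_lengths(rep(peak_length, n_peaks), free, layout)
  # null hit probability of a length-matched control against these peaks
  hw <- GenomicRanges::width(hotspots)
  ctrl <- place_lengths(hw[sample.int(length(hw), n_mc, replace = TRUE)],
                        free, layout)
  p_hit <- mean(GenomicRanges::countOverlaps(ctrl, base) > 0)
  k <- round(fold * length(hotspots) * p_hit)
  eligible_hs <- which(GenomicRanges::width(hotspots) >= peak_length)
  if (k > length(eligible_hs)) {
    stop("generation-failure: requested fold unattainable; maximum ",
         "attainable is ", round(length(eligible_hs) /
                                   (length(hotspots) * p_hit), 2))
  }
  planted <- GenomicRanges::GRanges()
  if (k > 0) {
    target <- hotspots[eligible_hs[sample.int(length(eligible_hs), k)]]
    off <- floor(stats::runif(k) *
                   (GenomicRanges::width(target) - peak_length + 1))
    planted <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(target),
      IRanges::IRanges(GenomicRanges::start(target) + off,
                       width = peak_length),
      seqinfo = GenomeInfoDb::seqinfo(hotspots)
    )
  }
  sort(c(GenomicRanges::granges(base), planted))
}
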