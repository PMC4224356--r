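#' Default configuration for the full synthetic analysis
#'
#' Scales are chosen so the whole run finishes in well under a minute while
#' every stage has enough data to be statistically meaningful: a 20 Mb
#' genome in 250 kb windows for the window-scale stage, a few hundred
#' hotspots per species for the hotspot stage.
#'
#' @param seed master integer seed; every stochastic stage derives its seed
#'   from it.
#' @param out_dir output directory for the TSV tables and manifest.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("epirecomb_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    input = "synthetic",
    paths = list(),
    genome = list(n_chrom = 4L, chrom_length = 5e6, gc = 0.41),
    window_size = 250e3,
    site_spacing = 1000L,
    depth = 30,
    rho = 0.2,
    hotspots = list(n_a = 300L, n_b = 200L, n_shared = 30L,
                    length_dist = c(1000L, 3000L), spacing = 8000L,
                    indel_rate = 1e-5, hotspot_multiplier = 10),
    mouse = list(n_snp = 400L, n_dsb = 150L, n_shared_dsb = 40L,
                 n_shared_snp = 40L),
    peaks = list(fold = 3, peak_length = 1000L, n_peaks = 2000L),
    n_repeats = 400L,
    enrichment = list(n_controls = 200L),
    divergence = list(B = 1000L, n_controls = 1000L),
    profile_bins = seq(0, 1e5, by = 5e3)
  )
}

write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  data.table::fwrite(df, path, sep = "\t")
  path
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, in order: input generation (or loading), the window-scale
#' stage (feature table, correlations across raw and Box-Cox-transformed
#' values, standardized multiple regression with VIFs and backward stepwise
#' selection), and the hotspot-scale stage (cross-species and SNP/DSB-style
#' classification, histone-peak overlap enrichment with resampled controls,
#' the bootstrap methylation-divergence null, the recombination-versus-
#' distance profile, and grouped methylation comparisons).  Writes one TSV
#' per analysis plus a manifest with seeds and file digests; a fixed seed
#' makes the run byte-reproducible.
#'
#' @param config list from [default_config()].
#' @return invisible list with the result tables and `files` (paths of
#'   everything written).
#' @export
run_full_analysis <- function(config = default_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- config$seed
  files <- character(0)

  ## ---- inputs stage -------------------------------------------------
  if (identical(config$input, "synthetic")) {
    genome <- make_genome(config$genome$n_chrom, config$genome$chrom_length,
                          gc = config$genome$gc, seed = s, sequence = TRUE)
    layout <- genome$layout
    syn <- make_synteny_map(layout, indel_rate = config$hotspots$indel_rate,
                            seed = s + 1L)
    hs <- make_paired_hotspots(syn, config$hotspots$n_a, config$hotspots$n_b,
                               config$hotspots$n_shared,
                               length_dist = config$hotspots$length_dist,
                               spacing = config$hotspots$spacing,
                               seed = s + 2L)
    bundle <- make_correlated_bundle(
      layout, window_size = config$window_size, rho = config$rho,
      depth = config$depth, site_spacing = config$site_spacing,
      hotspots = hs$hs_a,
      hotspot_multiplier = config$hotspots$hotspot_multiplier, seed = s + 3L
    )
    peaks <- make_peaks(layout, hs$hs_a, fold = config$peaks$fold,
                        peak_length = config$peaks$peak_length,
                        n_peaks = config$peaks$n_peaks, seed = s + 4L)
    set.seed(s + 5L)
    rep_len <- sample(200:2000, config$n_repeats, replace = TRUE)
    repeats <- place_lengths(rep_len, layout_granges(layout), layout)
    # independent partner-genome methylome (same marginal distribution)
    windows_b <- tile_windows(syn$dst_layout, config$window_size)
    fields_b <- make_correlated_fields(length(windows_b), 0,
                                       depth = config$depth,
                                       sites_per_window = config$window_size /
                                         config$site_spacing, seed = s + 6L)
    meth_b <- make_methylome(syn$dst_layout, windows_b, fields_b$m,
                             depth = config$depth,
                             site_spacing = config$site_spacing,
                             seed = s + 7L)
    mouse <- make_mouse_hotspots(layout, config$mouse$n_snp,
                                 config$mouse$n_dsb,
                                 config$mouse$n_shared_dsb,
                                 config$mouse$n_shared_snp,
                                 seed = s + 8L)
  } else {
    need <- c("hotspots_a", "hotspots_b", "synteny_ab", "synteny_ba",
              "methylome", "rec_map", "peaks", "chrom_sizes")
    missing <- setdiff(need, names(config$paths))
    if (length(missing)) {
      stop("inputs stage: missing path for '", missing[1], "'")
    }
    layout <- read_chrom_sizes(config$paths$chrom_sizes)
    hs <- list(hs_a = read_bed(config$paths$hotspots_a, layout),
               hs_b = read_bed(config$paths$hotspots_b))
    syn <- list(forward = read_synteny(config$paths$synteny_ab,
                                       src_layout = layout),
                reverse = read_synteny(config$paths$synteny_ba,
                                       dst_layout = layout))
    bundle <- list(
      meth_track = read_cytosine_report(config$paths$methylome, layout),
      rec_map = read_bedgraph(config$paths$rec_map, layout)
    )
    peaks <- read_bed(config$paths$peaks, layout)
    genome <- list(layout = layout, seq = NULL)
    repeats <- if (!is.null(config$paths$repeats)) {
      read_bed(config$paths$repeats, layout)
    } else NULL
    meth_b <- NULL
    mouse <- NULL
  }

  ## ---- window-scale stage -------------------------------------------
  wt <- build_window_table(layout, config$window_size, bundle$rec_map,
                           bundle$meth_track, seq_source = genome$seq,
                           repeats = repeats)
  files <- c(files, write_tsv(wt, config$out_dir, "window_table.tsv"))

  cc <- wt[is.finite(wt$methylation) & is.finite(wt$recombination_rate), ]
  raw <- pearson_cor(cc$methylation, cc$recombination_rate)
  bc <- boxcox_transform(cc$recombination_rate)
  trans <- pearson_cor(cc$methylation, bc$y)
  cor_tab <- data.frame(
    comparison = c("methylation_vs_rate", "methylation_vs_boxcox_rate"),
    r = c(raw$r, trans$r), p = c(raw$p, trans$p), n = c(raw$n, trans$n),
    boxcox_lambda = c(NA, bc$lambda)
  )
  files <- c(files, write_tsv(cor_tab, config$out_dir, "correlations.tsv"))

  pred_cols <- intersect(c("gc", "repeat_fraction", "methylation",
                           "cpg_count"), names(wt))
  reg_tab <- NULL
  if (length(pred_cols) >= 2) {
    X <- as.matrix(cc[, pred_cols])
    fit <- ols_standardized(bc$y, X)
    st <- backward_stepwise(bc$y, X)
    reg_tab <- data.frame(
      predictor = names(fit$beta),
      beta = unname(fit$beta),
      p = unname(fit$pvalues),
      vif = unname(fit$vif),
      retained_by_stepwise = names(fit$beta) %in% st$retained,
      adjusted_r2 = fit$adjusted_r2
    )
    files <- c(files, write_tsv(reg_tab, config$out_dir, "regression.tsv"))
  }

  ## ---- hotspot stage ------------------------------------------------
  cls <- classify_cross_species(hs$hs_a, hs$hs_b, syn$forward, syn$reverse)
  cls_tab <- data.frame(class = names(cls$counts),
                        count = unlist(cls$counts, use.names = FALSE))
  files <- c(files, write_tsv(cls_tab, config$out_dir,
                              "classification_counts.tsv"))

  if (!is.null(mouse)) {
    mcls <- classify_mouse(mouse$snp, mouse$dsb)
    mtab <- data.frame(class = names(mcls$counts),
                       count = unlist(mcls$counts, use.names = FALSE))
    files <- c(files, write_tsv(mtab, config$out_dir,
                                "mouse_classification_counts.tsv"))
  }

  enr <- overlap_enrichment(hs$hs_a, peaks, layout,
                            n_controls = config$enrichment$n_controls,
                            seed = s + 20L)
  enr_tab <- data.frame(
    observed = enr$observed, expected = enr$expected, fold = enr$fold,
    p_fisher = enr$p_fisher, p_mc = enr$p_mc,
    expected_genome_fraction = enr$expected_genome_fraction,
    n_features = enr$n_features, n_controls = enr$n_controls,
    seed = enr$seed
  )
  files <- c(files, write_tsv(enr_tab, config$out_dir, "enrichment.tsv"))

  div_tab <- NULL
  if (!is.null(meth_b)) {
    proj_hs <- map_via_synteny(hs$hs_a, syn$forward)
    hs_pairs_a <- hs$hs_a[S4Vectors::mcols(proj_hs$mapped)$orig]
    d_hs <- methylation_difference(bundle$meth_track, meth_b,
                                   hs_pairs_a, proj_hs$mapped)
    ctrl <- sample_control_regions(hs$hs_a, layout, hs$hs_a,
                                   n = config$divergence$n_controls,
                                   seed = s + 21L)
    proj_ctrl <- map_via_synteny(ctrl, syn$forward)
    ctrl_a <- ctrl[S4Vectors::mcols(proj_ctrl$mapped)$orig]
    d_ctrl <- methylation_difference(bundle$meth_track, meth_b,
                                     ctrl_a, proj_ctrl$mapped)
    dn <- methylation_divergence_null(d_hs, d_ctrl,
                                      B = config$divergence$B,
                                      seed = s + 22L)
    div_tab <- data.frame(observed = dn$observed,
                          empirical_p = dn$empirical_p, B = dn$B,
                          n_hotspot_diffs = sum(is.finite(d_hs)),
                          n_control_diffs = sum(is.finite(d_ctrl)),
                          seed = dn$seed)
    files <- c(files, write_tsv(div_tab, config$out_dir,
                                "divergence_null.tsv"))
  }

  prof <- recombination_distance_profile(bundle$rec_map, peaks,
                                         bin_edges = config$profile_bins)
  files <- c(files, write_tsv(prof, config$out_dir, "distance_profile.tsv"))

  groups <- list(
    species_specific = regional_methylation(
      bundle$meth_track, hs$hs_a[cls$labels_a == "species_specific"]),
    common = regional_methylation(
      bundle$meth_track, hs$hs_a[cls$labels_a == "common"]),
    syntenic_partner = regional_methylation(
      bundle$meth_track, cls$syntenic_b_in_a)
  )
  gc_res <- group_feature_comparison(groups, test = "anova")
  gtab <- gc_res$summary
  gtab$anova_F <- gc_res$test$F
  gtab$anova_p <- gc_res$test$p
  files <- c(files, write_tsv(gtab, config$out_dir, "group_comparison.tsv"))

  manifest <- write_manifest(
    list(seed = s, window_size = config$window_size,
         n_chrom = config$genome$n_chrom,
         chrom_length = config$genome$chrom_length),
    files, file.path(config$out_dir, "manifest.txt")
  )

  invisible(list(
    window_table = wt, correlations = cor_tab, regression = reg_tab,
    classification = cls, mouse_classification = if (!is.null(mouse)) mcls,
    enrichment = enr_tab, divergence = div_tab, profile = prof,
    groups = gtab, files = c(files, manifest)
  ))
}
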