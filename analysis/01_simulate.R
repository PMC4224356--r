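#!/usr/bin/env Rscript
# Generate the synthetic input bundle every downstream analysis script
# reads: a 20 Mb two-species genome pair joined by an indel-bearing synteny
# map, paired recombination-hotspot catalogues, a sperm-like methylome with
# a planted window-scale methylation-rate correlation of 0.2, a
# recombination map with hotspot spikes, and a histone-peak set planted at
# 3-fold enrichment over hotspots.

suppressPackageStartupMessages(library(epirecomb))

seed <- 20140
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- make_genome(n_chrom = 4, chrom_length = 5e6, seed = seed)
layout <- genome$layout
syn <- make_synteny_map(layout, indel_rate = 1e-5, seed = seed + 1)
hs <- make_paired_hotspots(syn, n_a = 300, n_b = 200, n_shared = 30,
                           seed = seed + 2)
bundle <- make_correlated_bundle(layout, window_size = 2.5e5, rho = 0.2,
                                 depth = 30, site_spacing = 1000,
                                 hotspots = hs$hs_a, hotspot_multiplier = 10,
                                 seed = seed + 3)
peaks <- make_peaks(layout, hs$hs_a, fold = 3, peak_length = 1000,
                    n_peaks = 2000, seed = seed + 4)
# repeat annotation placed independently of everything else, so it should
# carry no signal for recombination rate
set.seed(seed + 5)
rep_len <- sample(200:2000, 3000, replace = TRUE)
rep_chrom <- sample(GenomeInfoDb::seqnames(layout), 3000, replace = TRUE)
rep_start <- floor(runif(3000) * (5e6 - rep_len))
repeats <- bed_granges(rep_chrom, rep_start, rep_start + rep_len, layout)

write_chrom_sizes(layout, file.path(out, "genome_a.chrom.sizes"))
write_chrom_sizes(syn$dst_layout, file.path(out, "genome_b.chrom.sizes"))
write_bed(hs$hs_a, file.path(out, "hotspots_a.bed"))
write_bed(hs$hs_b, file.path(out, "hotspots_b.bed"))
write_synteny(syn$forward, file.path(out, "synteny_ab.tsv"))
write_synteny(syn$reverse, file.path(out, "synteny_ba.tsv"))
write_cytosine_report(bundle$meth_track, file.path(out, "methylome_a.cov.tsv"))
write_bedgraph(bundle$rec_map, file.path(out, "recombination_a.bedgraph"))
write_bed(peaks, file.path(out, "h3k4me3_peaks_a.bed"))
write_bed(repeats, file.path(out, "repeats_a.bed"))

files <- list.files(out, full.names = TRUE)
files <- files[basename(files) != "manifest.txt"]
write_manifest(list(seed = seed, rho = 0.2, peak_fold = 3,
                    hotspot_multiplier = 10),
               files, file.path(out, "manifest.txt"))

cat("Simulated input bundle written to", out, "\n")
cat(" ", length(hs$hs_a), "genome-A hotspots,", length(hs$hs_b),
    "genome-B hotspots (30 shared by construction)\n")
cat(" ", length(bundle$meth_track), "CpG sites,",
    length(bundle$rec_map), "recombination-map segments,",
    length(peaks), "peaks\n")
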