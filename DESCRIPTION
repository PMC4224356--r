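Package: epirecomb
Title: Epigenetic Covariates of Mammalian Recombination Rates and Hotspots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to analyse how DNA methylation and histone modifications
    (H3K4me3, H3K27me3) covary with mammalian recombination rates, both in
    long genomic windows and at recombination hotspots. Provides interval
    algebra on genome layouts (window tiling, overlap counting,
    nearest-distance, complement, length-matched control-region resampling,
    and a simplified synteny/liftOver projection between genomes),
    per-cytosine fractional methylation tracks with regional summaries,
    sequence features (G+C, CpG count, CpG O/E, repeat fraction), the
    statistical machinery used at window scale (Pearson correlation, Box-Cox
    transformation, standardized multiple regression with variance inflation
    factors and backward stepwise selection) and at hotspot scale
    (cross-species and SNP/DSB hotspot classification, overlap enrichment
    against resampled length-matched controls, bootstrap
    methylation-divergence nulls, recombination-versus-distance profiles,
    grouped comparisons). A synthetic-data generator with paper-scale presets
    produces inputs with known planted structure so every stage runs and is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    MASS,
    car,
    withr
Config/testthat/edition: 3
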