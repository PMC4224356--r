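#!/usr/bin/env Rscript
# Window-scale analysis: does methylation covary with recombination rate in
# long genomic windows?  Builds per-window feature tables at three window
# sizes, reports Pearson correlations on raw and Box-Cox-transformed rates,
# and fits the standardized multiple regression with VIF diagnostics and
# backward stepwise selection at 250 kb.

suppressPackageStartupMessages(library(epirecomb))

sim <- "results/sim"
stopifnot(dir.exists(sim))
layout <- read_chrom_sizes(file.path(sim, "genome_a.chrom.sizes"))
meth <- read_cytosine_report(file.path(sim, "methylome_a.cov.tsv"), layout)
rec <- read_bedgraph(file.path(sim, "recombination_a.bedgraph"), layout)

cors <- do.call(rbind, lapply(c(1e5, 2.5e5, 5e5), function(ws) {
  wt <- build_window_table(layout, ws, rec, meth)
  cc <- wt[is.finite(wt$methylation), ]
  raw <- pearson_cor(cc$methylation, cc$recombination_rate)
  bc <- boxcox_transform(cc$recombination_rate)
  tr <- pearson_cor(cc$methylation, bc$y)
  data.frame(window_kb = ws / 1e3, n_windows = raw$n,
             r_raw = raw$r, p_raw = raw$p,
             r_boxcox = tr$r, p_boxcox = tr$p, lambda = bc$lambda)
}))
dir.create("results", showWarnings = FALSE)
data.table::fwrite(cors, "results/window_correlations.tsv", sep = "\t")
cat("Correlation between methylation and recombination rate by window size:\n")
print(cors, digits = 3)

# regression at the finest window size; the repeat annotation is placed
# independently of the rate field, so stepwise selection should drop it
repeats <- read_bed(file.path(sim, "repeats_a.bed"), layout)
wt <- build_window_table(layout, 1e5, rec, meth, repeats = repeats)
cc <- wt[is.finite(wt$methylation), ]
bc <- boxcox_transform(cc$recombination_rate)
X <- cbind(methylation = cc$methylation,
           repeat_fraction = cc$repeat_fraction)
fit <- ols_standardized(bc$y, X)
st <- backward_stepwise(bc$y, X)
reg <- data.frame(predictor = names(fit$beta), beta = unname(fit$beta),
                  p = unname(fit$pvalues), vif = unname(fit$vif),
                  retained = names(fit$beta) %in% st$retained)
data.table::fwrite(reg, "results/window_regression.tsv", sep = "\t")
cat(sprintf("\nStandardized regression at 100 kb (adjusted R^2 = %.3f):\n",
            fit$adjusted_r2))
print(reg, digits = 3)
cat("\nThe generator plants a smooth-field correlation of 0.2 between\n")
cat("methylation and rate; uncorrelated hotspot rate spikes attenuate the\n")
cat("raw window correlation, and the Box-Cox transform recovers part of\n")
cat("it.  The independently placed repeats should not be retained.\n")
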