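---
title: "Models, calibrations and design choices in epirecomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, calibrations and design choices in epirecomb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`epirecomb` analyses how DNA methylation and histone modifications covary
with mammalian recombination, at two scales: long genomic windows, where
methylation and recombination rate correlate, and recombination hotspots,
whose rapid evolutionary turnover is the interesting signal. This vignette
documents the models and conventions behind each operation, the synthetic
generator that stands in for real methylomes, genetic maps and ChIP peak
sets, and the design decisions taken where more than one reasonable choice
existed. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Coordinates and interval conventions

All interchange formats (BED, bedGraph, synteny TSV) use 0-based half-open
coordinates; in memory everything is a `GRanges` (1-based closed), with
`bed_granges()` / `granges_to_bed()` converting at the boundary. Overlap
means at least one shared base (`min_bp = 1`); abutting half-open intervals
do not overlap. No statement of a reciprocal-fraction rule exists for the
overlap analyses this package supports, so none is imposed. Strand is
ignored for all interval operations. Window tilings emit a final partial
window flagged `partial`; window-scale statistics exclude partial windows
by default because a short terminal window has a noisier feature estimate
and would bias length-sensitive columns (CpG count in particular).

## Fractional methylation

A cytosine's methylation is C/(C+T) over its bisulfite reads; a region's
methylation is the **unweighted** mean over covered cytosines — "the mean
over all mapped cytosines" reading, in which each site counts once
regardless of depth. Depth-weighting is available behind
`weight_by_depth = TRUE` for sensitivity analyses, since coverage-weighted
averaging is a common alternative dialect. Defaults: minimum site depth 1
at track construction, minimum 5 covered CpGs per window (windows below it
get `NA` methylation and are dropped listwise from model fits). These
thresholds are configurable; they are deliberately mild because the
binomial site noise is already absorbed into the generator calibration
below.

## Synteny projection

Full UCSC chain/net parsing is out of scope; the synteny model is a
simplified chain: ordered gap-free blocks whose source and destination
spans have equal length, non-overlapping on the source genome. An interval
projects if at least `min_fraction = 0.95` of its bases (mirroring
liftOver's default `-minMatch`) fall in blocks agreeing on destination
chromosome and strand; the projected interval spans the min–max of the
projected base coordinates, so small internal indels widen rather than
split it. Negative-strand blocks reverse coordinates within the block.
Cross-species "common" hotspot calls use **reciprocal** overlap by default
(the A-hotspot's projection must overlap a B-hotspot whose own projection
overlaps the A-hotspot); whether a one-directional projection suffices is
not determinable from the analyses this mirrors, so the one-directional
mode is exposed via `reciprocal = FALSE`. Unmappable hotspots are counted
and reported, never silently dropped.

## Control regions and enrichment

"Expected" overlap counts are defined by resampling: control sets of the
same size and length multiset as the feature set, placed uniformly over all
start positions at which the interval fits entirely outside the excluded
space (by default the features themselves — hotspot-free sequence).
Placement is by direct capacity-weighted sampling — an eligible gap of
width w offers max(w − L + 1, 0) start positions for length L — which
cannot reject, so no retry loop is needed; a length with zero capacity
raises `placement-failure` naming it. With n equal to the template size the
exact length multiset is used. The headline-scale default is n = 10⁶
controls.

How an "expected" count should be computed is ambiguous (genome-fraction
argument vs resampling); `overlap_enrichment()` reports both: the
resampled expected (used for the fold), and an exact analytic
genome-fraction expectation computed by interval arithmetic at the mean
template length. Significance is reported two ways: a Fisher exact p on
the 2×2 table built from the rounded expected count — documented as an
approximation, since the expected is itself an estimate — and the
Monte-Carlo p, the (+1-corrected) fraction of control sets with at least
the observed overlap count. Bivalent chromatin is handled by intersecting
the H3K4me3 and H3K27me3 peak sets (≥1 bp) and feeding the result to the
same enrichment operation.

## Statistical conventions

- **Pearson correlation**: two-sided p from the t distribution with n−2 df.
- **Box–Cox**: (x^λ − 1)/λ, log at λ=0; automatic λ maximizes the profile
  log-likelihood over the grid [−3, 3] in steps of 0.01. Zeros (windows
  with rate 0 exist in real maps) are shifted by half the smallest positive
  value before transforming; the shift is returned with the transform.
- **Standardized regression**: OLS on z-scored response and predictors;
  reported per predictor are standardized β, p, and VIF = 1/(1−R²ⱼ);
  exactly collinear predictors give `Inf` VIF with a warning. Backward
  stepwise removes the largest-p predictor while it exceeds α = 0.05 —
  the named method fixes neither the criterion nor the threshold, so the
  conventional α is used and AIC-based removal is available behind
  `criterion = "aic"`.
- **Fisher's exact test**: authored as the probability-mass two-sided rule
  (sum of hypergeometric probabilities of all tables, margins fixed, no
  more probable than the observed), the dominant convention; a relative
  tolerance of 10⁻⁷ guards probability ties against floating-point loss.
- **t-test**: Welch (unequal variance) by default.
- **Bootstrap divergence null**: B bootstrap means of hotspot-set-sized
  samples drawn with replacement from control differences; two-sided
  empirical p = (1 + #{|draw| ≥ |observed|})/(B+1), bounded below by
  1/(B+1).
- p-values are reported raw throughout; the pipeline applies no
  multiple-testing correction because its analyses are single planned
  comparisons (peak callers' internal FDR machinery is out of scope).
- Whether the window analyses should transform only the response or the
  predictors too is left open in the sources this mirrors; the drivers
  transform the response and the operation accepts any columns, so either
  protocol is expressible.

## The synthetic generator

The generator produces inputs with the statistical structure the analysis
assumes; its defaults are the package's study conditions and are not tuned
per run.

**Hotspot catalogues.** Hotspot lengths are uniform on [1, 3] kb (real
catalogues report kb-scale hotspots; no length distribution is published
for them, so a simple bounded distribution is used). Hotspots are placed at
slots spaced 8 kb apart (more than twice the maximum length, so distinct
slots can never collide) strictly inside aligned synteny blocks with a
margin of one maximum length, which guarantees complete projection
coverage. Shared hotspots are planted by projecting the genome-A interval
into genome B; specific hotspots occupy distinct slots, so their
projections cannot overlap anything. Classification therefore recovers the
planted counts exactly, for identity maps and indel-bearing maps alike —
this is what makes the published-scale presets exact rather than approximate.

The mouse preset plants 47,068 SNP hotspots and 9,874 DSB hotspots with
2,571 shared DSB hotspots spread over 2,570 SNP hotspots: the published
SNP-only count (44,498) exceeds 47,068 − 2,571 by one, which is only
consistent if one SNP hotspot carries two DSB hotspots; the generator
plants exactly that configuration, and `classify_mouse()` counts shared
hotspots on the DSB side and SNP-only on the SNP side, reporting both.

**Synteny maps.** Aligned blocks of exponential length (mean 1/indel_rate,
default 10⁵ bp) alternate with indels of 10–50 bp, insertions and
deletions equiprobable. Forward and reverse maps are mutually inverse on
aligned bases.

**Methylome and recombination map.** Window-level truth comes from a
latent bivariate Gaussian (Z₁, Z₂) with correlation ρ_latent: methylation
m = clip(0.75 + 0.08·Z₁, 0.02, 0.98) (sperm-like hypermethylation with
realistic window spread), and rate = base·exp(σZ₂ − σ²/2) with σ = 0.5
(lognormal, mean `base` = 1 cM/Mb, CV ≈ 53%, matching the right-skew of
real window rates that motivates the Box–Cox step). CpG sites sit on a
regular grid (default one per 2 kb), depth is max(1, Poisson(30)), C-reads
are Binomial(depth, m).

Because read noise attenuates the observed window methylation and the
lognormal link attenuates the rate-side correlation, the latent correlation
is inflated analytically so the **observed** window Pearson r targets ρ:

- methylation attenuation a_m = sd_m / √(sd_m² + v), with noise variance
  v = m̄(1−m̄)·E[1/depth]/S over S sites per window (E[1/depth] computed
  numerically for the truncated Poisson);
- rate attenuation a_r = σ/√(exp(σ²)−1), the exact correlation factor for
  a lognormal transform of a bivariate-normal component;
- ρ_latent = ρ / (a_m·a_r), with an error if attenuation pushes it past
  0.99.

Under the defaults both factors are near 1 (a_m ≈ 0.999 at 250 sites per
window, a_r ≈ 0.94), and the recovered window correlation is unbiased to
well within sampling error — the acceptance suite checks recovery of
ρ = 0.2 within its Fisher-z interval over repeated seeds. Hotspot rate
spikes (a configurable multiplier, default 10×, inside hotspot intervals)
add rate variance uncorrelated with methylation, so runs that overlay
spikes measure a correspondingly attenuated raw correlation; the analysis
drivers note this where it applies.

**Peak sets.** Background peaks are placed uniformly over hotspot-free
sequence. The number of hotspots that should appear peak-overlapped at
fold F is F·n_hotspots·p̂, where p̂ is the null hit probability estimated
by Monte Carlo (20,000 length-matched controls) — the same null that
`overlap_enrichment()` resamples — and that many peaks are planted fully
inside distinct hotspots (so controls, which avoid hotspots, can never
touch them and the expected count is undisturbed). F = 1 reduces to the
independent-placement null; F = 0 places everything clear of hotspots. A
fold demanding more planted hotspots than exist raises
`generation-failure` with the attainable maximum.

**What the generator does not emulate.** Real sequence evolution, PRDM9
motif placement, read-level bisulfite chemistry and conversion errors,
CpG-density covariation with methylation, and spatial autocorrelation of
recombination beyond the window-level field. Passing tests therefore
demonstrate that the pipeline recovers planted structure of the assumed
form — not that real data satisfy those assumptions.

## Problem sizes and determinism

The default full-analysis configuration uses a 20 Mb genome in 250 kb
windows with a few hundred hotspots — large enough for every stage to be
statistically meaningful, small enough to re-run freely; the calibration
checks in the acceptance suite use 5,000 windows / 5,000 hotspots with
1,000 control sets, the scale at which the stated tolerances (Fisher-z
interval for ρ, 15% relative error on fold) are comfortably within reach.
Every stochastic operation takes an explicit seed which is recorded in its
output; `run_full_analysis()` derives all stage seeds from one master seed
and writes a manifest with md5 digests, and two runs with the same seed are
byte-identical.

## Known limitations

- The simplified chain model cannot express inversions or translocations
  within a block, and multi-genome (>2) synteny is out of scope.
- The Fisher table built from a rounded expected count treats an estimate
  as data; the Monte-Carlo p is the principled alternative and is always
  reported alongside.
- Regional methylation assumes CpG context only (CHG/CHH are dropped at
  ingestion, counted).
- The window regression corrects for neither spatial autocorrelation among
  neighbouring windows nor phylogenetic non-independence; its p-values
  carry the usual OLS caveats.
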