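---
title: "Statistical genotyping of STR loci from high-resolution melt curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical genotyping of STR loci from high-resolution melt curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltSTR)
```

## The problem

Forensic STR genotyping normally happens at the very end of the DNA
workflow, after amplification and capillary electrophoresis. A qPCR
instrument with high-resolution melt (HRM) capability records, much earlier,
the fluorescence of a dye-saturated amplicon while it is heated through its
dissociation range. Because STR alleles differ in amplicon length — one
repeat unit of a tetranucleotide locus is 4 bp — the melt curve of a sample
carries weak but real genotype information: the position of the tallest
peak in the negative derivative $-dF/dT$, and the number and height of the
shoulders flanking it. `meltSTR` implements the full statistical pipeline
for extracting and classifying that signal at two loci, D5S818 (panel of 7
closely related genotypes) and D18S51 (panel of 6), together with a
simulator that generates melt curves with the same statistical structure.

The central difficulty is that closely related genotypes (one repeat apart)
produce Tm differences of a tenth of a degree or so, well inside a single
peak width, so most heterozygotes appear as one primary peak with partially
merged shoulders rather than as resolved doublets. Classification accuracy
well above the 1-in-7 chance rate, but far below 100%, is the expected
regime.

## Feature extraction

For each sample the raw finite difference $-\Delta F / \Delta T$ is placed
at interval midpoints of the acquisition grid and smoothed with a
Savitzky–Golay local polynomial filter (default window 11 points, degree 3;
`window = 1` disables smoothing). On the canonical 60–95 °C ramp in 0.1 °C
steps, the midpoint grid contains 64.95 °C natively — which is why that
otherwise odd-looking temperature can serve as an exact padding point
without interpolation. Negative derivative values are not clipped; they are
ordinary noise and clipping would bias the smoother.

Peak detection is deliberately simple and fully deterministic:

1. *Resolved peaks* are local maxima of the smoothed $-dF/dT$ inside the
   melt window (default 70–90 °C) with topographic prominence at least
   `prominence_frac` (default 0.05) of the tallest in-window value. The
   tallest candidate is the **primary**; ties go to the lower temperature.
2. *Unresolved shoulders* are terraces on the primary's flanks: with $g$
   the first difference of the smoothed curve, an interior local minimum of
   $g$ on the ascending flank with $0 < g \le \tau \max g$ (default
   $\tau = 0.15$), or symmetrically an interior local maximum with $g < 0$,
   $|g| \le \tau \max |g|$, on the descending flank.

A numerical caveat worth stating: a terrace in this sense only exists for a
fairly narrow range of component separations. Brute-force evaluation of
two-component logistic mixtures shows that a weight-0.3 species less than
about 2.5 slope-widths from the primary leaves the flank slope strictly
monotone — no terrace exists to find, at any resolution — while beyond
about 4 slope-widths the species resolves into its own local maximum. The
terrace threshold $\tau$ trades sensitivity in that intermediate band
against false terraces on noisy tails, and is exposed in the configuration
for exactly that reason.

Each sample is then summarized as a fixed-length vector of $k$
(temperature, height) pairs — $k = 3$ for D5S818, $k = 4$ for D18S51,
matching the observation counts supported by those panels' morphologies —
primary first, shoulders by ascending temperature. Samples with more than
$k$ observations keep the primary and the $k-1$ tallest shoulders; samples
with fewer are padded with (64.95 °C, $-dF/dT$ at 64.95 °C) pairs.
Padding a full pair rather than a lone height keeps every vector the same
length with a constant, non-discriminative temperature coordinate.

## Classifiers

**LDA.** Fitted from its defining statistics: class means $\mu_c$, pooled
within-class covariance $\Sigma_W = \sum_c \sum_{i \in c} (x_i - \mu_c)
(x_i - \mu_c)^\top / (n - C)$, and the linear discriminant
$\delta_c(x) = x^\top \Sigma_\lambda^{-1}\mu_c - \tfrac12 \mu_c^\top
\Sigma_\lambda^{-1}\mu_c + \ln \pi_c$ with softmax posteriors. Priors
default to uniform — the natural benchmark here is the 1-in-$C$ chance
rate, not the sampling frequencies of the training panel — with empirical
priors available. The ridge is relative,
$\Sigma_\lambda = \Sigma_W + \lambda\,\mathrm{diag}(\Sigma_W)$ with
$\lambda = 10^{-6}$, because an all-pad feature column (constant 64.95)
makes $\Sigma_W$ exactly singular; a zero diagonal entry receives
$\lambda$ times the mean positive diagonal instead, since scaling zero
would add nothing. Ties in the discriminant break by class-label order, so
prediction is fully deterministic.

**PCA cluster typing.** A fully specified, open replacement for the
proprietary PCA clustering shipped with the instrument software (whose
components and preprocessing are undocumented; no byte-level compatibility
is attempted). Smoothed derivative curves are restricted to the melt
window and min–max scaled to $[0,1]$ — differentiation already removes
additive baselines, scaling removes amplitude, leaving shape. Standards
are centered and projected onto the top $m$ (default 2) principal
components, computed by SVD with each component's sign fixed so its
largest-magnitude entry is positive. Each class's scores get a Gaussian
with pooled covariance — 7–10 standards per class cannot support stable
per-class covariances in 2 dimensions (a per-class option exists).
Unknowns take the class with the highest posterior, unless the Mahalanobis
distance to even the best class exceeds the $\chi^2_m$ quantile 0.999, in
which case they are `UNCLASSIFIED`. Unlike the instrument software, the
fitted model serializes to JSON and can type later runs without re-running
the standards alongside them.

## Evaluation

The unit of evaluation is the known × predicted confusion matrix, labels
sorted lexicographically by allele pair. Because published
homozygous/heterozygous splits mix two aggregations — some rates are
pooled-count (micro), others mean-of-recalls (macro) — `subset_accuracy()`
makes the mode explicit, and the packaged reproduction states the mode for
every statistic it checks. A misclassification is a *near miss* when the
predicted genotype shares one allele with the truth and errs by exactly one
repeat on the other, with the shared allele chosen over both pairings.

Geno-group schemes merge genotypes into coarser classes; the eleven
published grouping options for the two loci ship as fixtures. Two
evaluation protocols exist because the published comparison method is not
defined precisely: *collapse* (classify genotypes, then sum the confusion
matrix into group cells — conserves the grand total and can only raise
accuracy) and *retrain* (re-label the standards with group labels and
refit — changes the fitted class structure, so accuracy can move either
way). Both are computed side by side.

The four published confusion matrices are packaged as TSV fixtures. Every
statistic derivable from their printed cells is recomputed by
`reproduce_reported_statistics()` and reproduces at printed precision, with
one exception: the printed overall rate of the D5S818 PCA matrix (23.77%)
differs marginally from the trace/total of its own printed cells
(49/206 = 23.79%), so for that matrix only the homozygous/heterozygous
macro rates — which reconcile exactly — are scored. The published
*retrained* geno-group accuracies (81.0%, 46.6%, 65.4%, 63.5%) require the
study's raw melt curves, which were never released, and are out of scope;
the post-hoc collapse of the published D5S818 LDA matrix by its best
grouping gives 147/185 = 79.46%, a different (weaker) protocol reported as
such.

## The simulator

Each amplicon species melts as a two-state logistic transition:

$$F(T) = b_0 + b_1 (T - 60) + A \sum_i w_i\,
  \sigma\!\left(\frac{Tm_i + J - T}{s}\right) + \varepsilon(T)$$

with heterozygotes contributing two species of weight 1, homozygotes one
species of weight 2, an optional heteroduplex species (off by default —
real heterozygote HRM shows it, and enabling it stresses the classifiers),
a per-sample Tm jitter $J \sim N(0, \sigma_{Tm}^2)$ drawn once per sample
(run-to-run shifts move the whole curve), and iid per-reading noise. Tm
follows the empirical GC/length law $Tm = c_0 + c_1\,\mathrm{gc} - c_2 /
\mathrm{length}$, with length = flank + 4 × repeats.

Default parameter choices, fixed once:

* `tm_coeffs = (67, 41, 675)` and the locus fixtures (flank 119 bp / GC
  0.38 for D5S818, flank 131 bp / GC 0.365 for D18S51 — calibrated
  placeholders, since true amplicon flank composition for the published
  primers is not stated anywhere usable) put primaries near 78–80 °C and
  one repeat unit at ≈ 0.10 °C of Tm — deliberately small, reproducing the
  overlapping-curve difficulty that caps real-world accuracy.
* `transition_slope = 0.3` °C gives realistic peak widths (~1 °C FWHM of
  the derivative lobe); `amplitude = 1000`, `baseline = (100, −0.2)`,
  `noise_sd = 2` (0.2% of amplitude), `tm_jitter_sd = 0.05` °C.
* Per-sample RNG substreams are derived from (seed, sample index), so a
  dataset is reproducible independently of generation order.

What the simulator emulates: transition positions tracking amplicon length,
primary-peak/shoulder morphology whose height ratios track species weights,
baseline drift, instrument noise, run-to-run Tm shifts. What it does not:
nearest-neighbor thermodynamics, salt/dye effects, amplification-phase
artifacts, sequence variation within alleles of equal length. Passing
recovery tests on simulated data therefore demonstrates the pipeline's
statistical correctness, not field performance on any instrument.

The parameter-recovery checks use a slightly wider spacing regime
(`tm_coeffs = (73, 41, 1700)`, ≈ 0.26 °C per repeat, with jitter 0.05 °C
and noise 0.2% of amplitude): held-out LDA accuracy over 700 unknowns is
then ≥ 0.90, collapses to the 1/7 chance rate when training labels are
shuffled (reported as the mean over several permutations — a single
permutation retains a noisy number of fixed points), and falls below 0.5
when both noise scales are multiplied by 20. Under the narrower default
spacing, the same pipeline lands near 59% on the 7-genotype panel —
without any tuning, the same operating regime the published study reports.

## Numerical choices and limitations

* Derivatives at interval midpoints (not nodes): makes the pad temperature
  a native grid point and keeps the differencing exact for linear trends.
* Problem sizes in the test-suite: simulated datasets use 8 standards and
  up to 100 unknowns per genotype (700 held-out samples), enough for the
  binomial error on an accuracy near 0.9 to sit around one percentage
  point.
* Degenerate inputs fail loudly and specifically: flat curves ("no melt
  signal"), no in-window peak ("no-peak", the sample is unusable), classes
  with fewer than two standards, singular covariances at zero ridge.
* Non-canonical temperature grids are accepted with a warning — only
  strict monotonicity is required — but padding needs 64.95 °C inside the
  curve's range.
* The peak/shoulder identification in the original study was visual; any
  automated rule, including this one, is a proxy. The terrace band
  limitation above is the main known blind spot.
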