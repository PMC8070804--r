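---
title: "Methods: optical metabolic imaging analysis in flimetry"
author: "flimetry authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optical metabolic imaging analysis in flimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimetry)
```

This vignette documents the models, numerical choices and design decisions
behind `flimetry` — the assumptions a user should know before trusting the
numbers, and the reasoning behind the places where the design was genuinely
open.

## The decay model and its fitting

Time-correlated single-photon counting (TCSPC) accumulates, per pixel, a
histogram of photon arrival times after each laser pulse. Autofluorescence
of the metabolic co-enzymes NAD(P)H and FAD decays bi-exponentially because
each co-enzyme exists in two conformations (free and protein-bound) with
distinct lifetimes:

$$I(t) = A\,\bigl[\alpha_1 e^{-t/\tau_1} + \alpha_2 e^{-t/\tau_2}\bigr]
\circledast \mathrm{IRF} + C,\qquad \alpha_1 + \alpha_2 = 1,\;
\tau_1 < \tau_2 .$$

The measured curve is the model convolved with the instrument response
function (IRF), the system's temporal blur. `modelDecay()` implements this
forward model — the bi-exponential is sampled at bin centers, convolved
discretely with the unit-sum IRF kernel, scaled by the amplitude $A$, and
the background $C$ (uncorrelated room/detector light, which is flat in
time) is added *after* the convolution. Fitting is by **iterative
reconvolution**: the optimizer adjusts $(A, \alpha_1, \tau_1, \tau_2, C)$
so the convolved model matches the data. We never attempt to deconvolve the
data itself; direct deconvolution of Poisson counts is numerically unstable
and no TCSPC practitioner does it that way.

Assumptions: uniform time bins, an IRF measured on the same grid, photon
counts low enough per pulse that pile-up is negligible (the count-rate
regime of a standard two-photon system), and decays complete enough within
the observation window that truncation is minor (< 1% of the signal is
lost on the default window; this is asserted in the test suite).

### Time grid

The default grid is **1024 bins x 12.2 ps = 12.5 ns**, the pulse period of
an 80 MHz Ti:sapphire laser. Both numbers matter: 12.2 ps resolves a
~220 ps IRF, and the 12.5 ns window lets a 2.5 ns protein-bound NAD(P)H
component decay by five time constants. On a much shorter window the long
lifetime and the background offset become nearly unidentifiable and
$\tau_m$ recovery degrades severalfold — this is why the window, not the
bin count, is the load-bearing choice. Both are configurable everywhere
(`defaultIrf(binWidthNs, nBins)`); the image-pipeline tests use a coarser
256 x 48.8 ps grid over the same window, which loses almost no accuracy
and fits four times faster.

### Weighting

The default objective is **Poisson maximum likelihood**, implemented as
least squares on signed deviance residuals
$r_i = \mathrm{sign}(y_i - m_i)\sqrt{2\,(m_i - y_i + y_i \ln(y_i/m_i))}$,
so that `minpack.lm`'s Levenberg–Marquardt minimizes the Poisson deviance
exactly. The classical Neyman chi-square (weights $1/\max(y_i, 1)$) is
available via `weighting = "neyman"`, but it is *not* the default for a
measured reason: with many near-empty tail bins on the long grid, clipping
counts at 1 over-weights downward fluctuations and biases $\tau_m$ low by
several percent at $10^4$ photons, while the deviance fit is unbiased
(median $|\tau_m|$ error ~1.8% at $10^4$ photons, shrinking monotonically
with photon count — both properties are asserted in the suite).

Other fitting choices: initials $\alpha_1 = 0.7$, $\tau_1 = 0.4$,
$\tau_2 = 2.5$ ns for NAD(P)H and $0.7 / 0.3 / 2.0$ ns for FAD (published
free/bound ranges); bounds $\tau_1 \in [0.05, 1.5]$,
$\tau_2 \in [0.8, 8]$ ns, $\alpha_1 \in [0, 1]$, $A, C \ge 0$; if the
optimizer exits with $\tau_1 \ge \tau_2$ the component pairs are swapped so
the short component is always first. Fits are deterministic given
identical inputs — the optimizer has no stochastic element. Decays with
fewer than 500 photons (after 3x3 pixel binning, radius configurable) are
refused: below that, bi-exponential parameters are not meaningfully
constrained.

## Segmentation

The pipeline reproduces the classic CellProfiler recipe on NAD(P)H
intensity images, where nuclei are darker than cytoplasm but brighter than
background:

1. **Nuclei**: a three-class Otsu threshold (exhaustive two-threshold
   search over a 128-bin histogram, maximizing between-class variance); the
   middle band is the nuclear candidate mask. This is the only
   parameter-free reading of "a threshold between background and cytoplasm
   intensity". Touching nuclei are split by a distance-transform watershed.
   Objects are kept if their area lies in [15, 500] px, eccentricity
   $\le 0.9$ and solidity $\ge 0.8$ — the concrete form of a "round
   objects" filter. Eccentricity comes from second-order pixel moments;
   solidity is pixel count over a lattice-corrected convex-hull area
   (shoelace area + boundary/2 + 1), which is stable for objects as small
   as a 3-pixel-radius nucleus.
2. **Cells**: seeded propagation from each nucleus (`EBImage::propagate`,
   the same Voronoi-on-intensity-manifold algorithm CellProfiler uses for
   secondary objects), restricted to the foreground of a global two-class
   Otsu threshold so growth cannot leak into background.
3. **Cytoplasm** = cell minus nucleus. The `LabelMasks` container
   revalidates the set algebra (cytoplasm label = cell label everywhere,
   nuclei inside their cells, nuclei and cytoplasm disjoint) on every
   construction.

Only 2-D sections are segmented, matching single-optical-section
acquisitions.

## Per-cell variables and the OMI index

Per-cell values are **means over valid cytoplasm pixels** (valid in both
channels); cells with fewer than 10 valid pixels are dropped. The optical
redox ratio is the per-pixel NAD(P)H/FAD intensity ratio. The composite
index is

$$\mathrm{OMI} = \widehat{RR} + \widehat{\tau_m^{NADH}} -
\widehat{\tau_m^{FAD}},$$

where each hat denotes division by the mean of that variable over the same
patient's **control** cells. Normalizing all three variables — not only the
redox ratio — is a deliberate resolution of an ambiguity: coefficients
(1, 1, −1) are only meaningful if the three terms are unitless and on a
common scale, and nanosecond-valued lifetimes would otherwise dominate or
vanish depending on units. A consequence worth knowing: the control group's
mean OMI index is 1 by construction, and a *decrease* under treatment is
the response signature (glycolysis and co-enzyme protein-binding drop,
FAD τ_m rises). Z-score tables are likewise control-referenced per patient:
$Z = (\bar{x}_{treated} - \bar{x}_{control}) / s_{control}$.

## Response calling

Per patient and condition, two gates on the single-cell OMI index:

* **one-way ANOVA** of control vs treatment, $p < 0.05$. For two groups
  this is identical to the unpaired equal-variance t-test ($F = t^2$); both
  statistics are reported and the shared p-value is used, which dissolves
  the apparent methods/figure discrepancy between "ANOVA" and "t-test".
* **Glass's Δ** $= (\bar{x}_{control} - \bar{x}_{treated})/s_{control}$
  with the $n-1$ sample SD and cutoff **0.75**. Glass's Δ (control-SD
  denominator) is the right effect size here because single-cell samples
  are so large that p-values alone are nearly always significant, and
  treatment can change the variance. The sign convention makes a decrease
  positive; an OMI **increase** is reported as `na_increase` — effect size
  "not applicable", non-response — rather than as a negative Δ.

A `responder` requires both gates; each gate can be switched off
(`pGate`, `deltaGate`) to reproduce either analysis alone. No
multiple-testing correction is applied across patients, matching screening
practice for per-patient calls.

## Subpopulation analysis

Per-cell OMI-index distributions within one (patient, condition) group are
modeled as univariate Gaussian mixtures, K = 1–3, fitted by EM (tolerance
$10^{-6}$ on the log-likelihood, at most 500 iterations, component SDs
floored at $10^{-4}$ of the data SD; means initialized from random data
points, SDs at the data SD, uniform weights). Only groups with **more than
100 cells** are analyzed — a strict gate; 100 exactly is excluded.

**Model selection.** The fit-and-select process is repeated 100 times:
each repeat runs one randomly initialized EM per K and picks the
minimum-AIC K (with $\mathrm{AIC} = 2(3K-1) - 2\ln L$); the K chosen by
the majority of repeats wins, ties resolving to the smaller K, and the
best-likelihood fit at that K is returned. Two guards reflect what a
"subpopulation" means: restart solutions in which a component owns fewer
than 5 cells, or in which an SD collapses to the floor, are discarded as
degenerate.

This consensus design is deliberate. The obvious alternative — take the
best log-likelihood over all restarts per K, then compare AICs once — is
*less* reliable, and measurably so: an exhaustive restart search hands AIC
the globally best overfit optima (spikes on a few points, splits of one
mode), and on 4-SD-separated two-component data (n = 300) it recovers
K = 2 only ~70% of the time, versus ~85% for the consensus, with the
unimodal case improving from ~62% to ~90%. Even the consensus is not
infallible at exactly 4 SD separation — AIC is a liberal criterion and
occasionally prefers K = 3 on genuinely bimodal samples; the suite
therefore asserts majority-correct selection over replicate datasets
rather than near-certainty. Selection at n = 50 is genuinely marginal and
is likewise asserted only at majority level.

**Heterogeneity.** The weighted heterogeneity index of a fitted mixture is

$$wH = \sum_i \bigl(1 - p_i \ln(p_i + 1)\bigr)\,(\sigma_i + d_i),$$

with natural logarithm, component proportions $p_i$ and SDs $\sigma_i$,
and $d_i$ the distance from component $i$'s median to the median of the
entire distribution. Two readings were fixed here: a Gaussian component's
median equals its mean (the only way $d_i$ is computable from the model),
and the overall median is taken from the **raw cell values**, not the
fitted mixture (an `overall_median` the user can recompute either way).
Useful closed forms: one component with $d = 0$ gives
$(1-\ln 2)\,\sigma \approx 0.3069\,\sigma$; two balanced components at
$\pm 1$ with $\sigma = 0.2$ give $2(1 - 0.5\ln 1.5)(1.2) \approx 1.9134$.
Density curves for display are the mixture pdf, which has unit area by
construction, so groups of different sizes are directly comparable.

## The synthetic-data generators

The generators produce every input the pipeline consumes, with known
ground truth. They emulate the study conditions, not the microscope:

* **Decays** are Poisson draws around the reconvolved model curve — true
  shot-noise statistics (dispersion index ~1 per bin, asserted), but no
  detector afterpulsing, pile-up or photobleaching.
* **The IRF** is Gaussian with $\sigma = 93.4$ ps (FWHM 220 ps, matching a
  second-harmonic-generation measurement on urea crystals), centered at
  10% of the window. **Microsphere standards** are mono-exponential 2.1 ns
  decays at $2\times10^5$ photons, seven replicates — the daily lifetime
  standard of a FLIM lab.
* **Scenes** place non-overlapping circular cells (disk nuclei inside
  round cell bodies; a ring layout for hollow-organoid cross-sections) and
  simulate per-pixel two-channel histograms from each cell's ground-truth
  parameters, with the background < nucleus < cytoplasm NAD(P)H intensity
  ordering the segmentation relies on. No optical point-spread blurring,
  no 3-D rendering, no irregular cell shapes — so segmentation scores here
  are an upper bound on real-data performance, and passing tests validate
  the algorithmic chain, not robustness to imaging artifacts.
* **The cohort** is a 7-patient x 4-condition table of per-cell variables.
  Control cells vary ~8% (relative SD) per variable; responder groups get
  a ground-truth OMI-index decrease of 1.2 control SDs, realized as equal
  parts lower redox ratio, lower NAD(P)H $\tau_m$ and higher FAD $\tau_m$
  so the shift survives fitting and normalization; non-responders get a
  0.2 SD increase. The response pattern is: patients 1, 3, 7 respond to
  both single agents and the combination, patient 4 to the single agents
  only, patients 2 and 5 to the combination only, patient 6 to nothing —
  4 everolimus, 4 ABT263, 5 combination responders. Patient 6 is a 50/50
  two-subtype mixture separated by 4 SD in every condition; patient 1's
  everolimus group has twice the control SD; patient 7 has 0.6x SD
  throughout. Patients 1, 6, 7 have 300 cells per group; the others have
  **exactly 100**, the largest size the strict >100 gate excludes (the
  stated design constraints — a three-patient gate and larger
  non-eligible groups — cannot hold simultaneously, and the gate is the
  anchoring fact). Effect sizes are the artifact's own calibration: 1.2 SD
  clears the 0.75 cutoff with ~3 standard errors of margin at n = 100,
  and a 0.2 SD increase lands in `na_increase` for all but ~1 in 10
  groups, where sampling noise may yield a small non-significant decrease
  (`non_responder`) — either way, not a responder. One cell-level draw
  detail matters for the mixture analysis: the per-cell redox ratio is
  drawn directly as a Gaussian and NAD(P)H intensity derived from it,
  because a ratio of two independent Gaussians is right-skewed and that
  skew masquerades as a spurious third mixture component.
* **Growth tables**: slow-growing neuroendocrine organoid lines change
  diameter by Normal(0, 5)% over 48 h — centered at zero, the reason
  diameter is a useless response readout for them — against a
  Normal(40, 15)% colorectal comparator.

Every generator is a pure function of (preset, seed): integer photon
counts are bit-identical across runs at a fixed seed.

## Problem sizes in the test suite

The suite is sized to validate the science quickly: decay-fit recovery uses
200 replicate fits at $10^4$ photons (plus 100 each at $10^3$ and $10^5$
for the monotonicity check); image-pipeline tests run a 32 px, 3-cell scene
on the 256-bin grid; segmentation scoring uses 64–96 px scenes with 6–12
cells; mixture-selection replicate checks use 12 datasets x 50 repeats;
the cohort runs at full size (2,800 cells). The whole suite completes in
about three minutes on one CPU.

## Known limitations

* Per-pixel fitting is plain R over `minpack.lm`; a 256 x 256 two-channel
  image at full grid resolution is minutes of compute, not seconds. Batch
  users should bin aggressively or coarsen the time grid (accuracy loss is
  negligible down to ~50 ps bins for these lifetimes).
* The fitter is per-pixel only: no global fitting of shared lifetimes
  across pixels, no phasor analysis, no three-component models.
* Segmentation assumes the NAD(P)H contrast ordering and roughly convex
  cells; it has no learned component and will not handle densely packed
  irregular morphologies as well as a trained model.
* AIC-based mixture selection is liberal near its resolution limit (see
  above); wH-index comparisons between groups are more robust than the
  selected K itself.
* The synthetic cohort draws per-cell variables independently across
  variables within a cell; real OMI variables are correlated cell-to-cell,
  so multivariate structure (beyond the scalar OMI index modeled here) is
  not emulated.
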