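---
title: "Methods: parametric OCT mapping, blockwise SVM segmentation and the contextual override filter"
author: "gliomaOCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parametric OCT mapping, blockwise SVM segmentation and the contextual override filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomaOCT)
```

# The problem

Intraoperative optical coherence tomography (OCT) of the resection cavity can
distinguish glioma from white matter because tumor tissue attenuates the
probing beam faster and scatters it more heterogeneously. This package
implements the full inference stack around that observation:

1. **Parametric maps** — a depth-resolved optical attenuation coefficient
   (OAC) and a refined speckle contrast (RSC) computed per pixel from a
   B-scan, with signal-to-noise masking;
2. **Blockwise features** — each scan partitioned into blocks of 20 adjacent
   A-scans summarised by (mean OAC, mean RSC) inside a fixed depth region of
   interest;
3. **Segmentation** — a standardized linear one-vs-rest SVM labelling each
   block normal white matter (green), damaged white matter (yellow) or tumor
   (red), evaluated by grouped leave-one-out cross-validation and
   one-vs-rest ROC/AUC;
4. **Contextual filter** — a deterministic rule engine modelling the
   human-in-the-loop review of a segmentation map, which converts block
   labels into a scan-level tumor probability and can override implausible
   scattered positives;
5. **Reader-study evaluation** — pooled confusion counts, sensitivity /
   specificity / accuracy, inter-rater consistency, and scan-level
   percentile bootstrap confidence intervals for multi-reader forced-choice
   panels;
6. **Synthetic data** — a seed-deterministic B-scan and reader-panel
   generator with known ground truth, so the whole pipeline is testable
   without any patient data.

# Attenuation coefficient

For each A-scan (raster column) in linear intensity $I(j)$, the
depth-resolved attenuation estimate is

$$\mu_s(j) \;=\; \frac{I(j)}{2\,\Delta \sum_{i=j}^{N-1} I(i)},$$

with $\Delta$ the axial inter-pixel distance (default 0.0075 mm) and $N$ the
scan depth. The tail sum is truncated at the bottom pixel; the estimator
assumes the signal has essentially decayed by then. Two systematic effects
follow directly from the formula and are *characterised in the tests rather
than corrected*:

* On an infinitely deep noiseless exponential medium with true coefficient
  $\mu$, the estimator converges to
  $(1-e^{-2\mu\Delta})/(2\Delta) = \mu - \mu^2\Delta + O(\mu^3\Delta^2)$ —
  a discretisation gap below $2\mu^2\Delta$ (about $-2.6\%$ at
  $\mu = 3.5\ \mathrm{mm^{-1}}$).
* On a finite scan the truncated tail inflates $\mu_s(j)$ by the relative
  factor $1/(1-e^{-2\mu\Delta(N-j)})$, which the unit tests verify exactly
  via the finite geometric series. For a 256-pixel scan this bias is
  negligible for strongly attenuating tissue but substantial at depth for
  weakly attenuating tissue; the feature region of interest sits at depth
  pixels 20–40 where it is small for all three classes.

Because intensity appears in numerator and denominator, the OAC raster is
exactly invariant under global intensity scaling — calibration of the
scanner's intensity units is irrelevant.

# Speckle contrast

RSC is the local dispersion-over-mean of the *OAC field* in a centered
10 px (depth) × 20 px (width) sliding window. Computing contrast on OAC
rather than raw intensity removes the depth-decay trend, so the statistic
reflects microstructural heterogeneity. The default statistic is the
standard speckle-contrast form $\mathrm{sd}/\mathrm{mean}$ (population
standard deviation); a variance-over-mean variant is available via
`computeRSC(type = "variance")` because the two readings cannot be
distinguished from the field's notation. Windows lacking full support at
the raster border, and windows containing any masked cell, are masked —
no partial-window statistics are invented.

# SNR masking

Pixels are valid where $10\log_{10}(I/I_{\mathrm{noise}})$ meets the noise
floor (default 15 dB). The noise reference is taken from the scan's
metadata when available and otherwise estimated as the median intensity of
the bottom 5 % of rows. Two evaluation modes exist:

* `snrMask()` default: the criterion per raw pixel — the literal contract,
  used by its unit tests and oracle.
* `computeParametricMaps()`: the criterion on a 10 × 20 box-averaged
  (speckle-reduced) intensity, with each column's mask forced to a depth
  prefix. Fully developed speckle sends roughly 1–2 % of pixels below any
  threshold regardless of mean SNR; a per-pixel mask is therefore
  salt-and-pepper, and the strict window-masking rule would annihilate the
  RSC map. The smoothed prefix mask implements what the cutoff is
  physically for — removing the signal-starved deep region.

# Features and classifier

Scans are partitioned left-to-right into non-overlapping blocks of 20
A-scans (trailing remainder columns dropped; the canonical 400-wide scans
divide evenly). Per block, mean OAC and mean RSC are taken over valid cells
in the half-open depth interval [20, 40) — 20 rows; the interval bounds are
configurable since an inclusive reading (21 rows) is equally defensible. A
block with under 50 % valid ROI cells is flagged invalid and excluded,
never imputed.

The classifier standardizes both features to zero mean and unit variance
(population SD, the StandardScaler convention) and fits one linear-kernel
SVM per class against the rest — a true one-vs-rest scheme; the underlying
library's native multiclass mode is one-vs-one and is deliberately not
used. The regularization constant defaults to $C = 1$ and is exposed.
Prediction is the argmax of the three decision values with exact ties
broken by the fixed class order Normal < DamagedMatter < Tumor. The binary
tumor-vs-rest score is the Tumor class's decision value; no probability
calibration is applied.

Cross-validation is grouped per scan by default, so that scaler and SVMs
are refit from scratch inside every fold and blocks of one scan never
appear on both sides; `grouping = "per_block"` mirrors the literal
one-block-per-fold reading. A fold whose training remainder loses a class
is refused rather than silently degenerating. ROC curves use a threshold
sweep over unique scores with trapezoidal integration, which the tests
prove equivalent to exhaustive concordant-pair counting with half credit
for ties.

# The contextual filter

The filter is a model of the contextual reasoning a trained reader applies
to a segmentation map — not a claim about surgeon cognition. Its rules, in
order:

1. Red runs shorter than `minRun` (default 2) flanked on both sides by
   green (map boundary counts as green) are suppressed as scattered noise.
2. The surviving red fraction maps through density thresholds (defaults
   0.10 / 0.30) to a base probability: 0.1 at or below the low threshold,
   0.9 at or above the high one, linear between.
3. If surviving red blocks adjoin yellow — the damaged-matter margin
   pattern of a real infiltration front — the probability is multiplied by
   `neighborWeight` (default 1.5).
4. If the deepest valid-signal extent among surviving red blocks falls
   short of `depthFraction` (default 0.5) of the scan depth, the
   probability is attenuated proportionally.

The product is clipped to [0, 1]; the call is Tumor only when it strictly
exceeds the 0.5 threshold, so a probability of exactly one half is a
white-matter call. The source heuristics are qualitative ("rare",
"dense", "deeper"); every quantification here is an engineering default,
chosen once so that the four scan-level outcome archetypes (confirmed true
positive, overridden scattered false positive, confirmed clustered false
positive, false negative without visual warning) behave correctly, and all
are exposed in `filterConfig()`. Using the *maximum* depth extent over
surviving red blocks (rather than the mean) keeps the score monotone:
adding red evidence can never lower the probability. One documented edge:
recolouring the only yellow neighbour of a red run to red removes the
margin bonus and can lower the score — monotonicity is guaranteed for
green-to-red changes.

`batchVerdicts()` compares every call with the naive machine rule "any red
block ⇒ tumor" and ledgers the scans where the filter overrides it,
splitting algorithmic false positives into overridden and confirmed when
truth is known.

# Reader-study statistics

Confusion counts pool all (scan, reader) assessments against scan truth.
Metrics are the standard ratios, reported at full precision and as
whole-percent values rounded half-up (the convention of clinical
performance tables; note base R's `round()` rounds half to even and is not
used for display). Zero-denominator metrics are flagged undefined, never
zero.

Inter-rater consistency defaults to mean pairwise percent agreement — the
simplest reading of "degree of agreement" — with Fleiss' kappa as the
chance-corrected alternative; neither is claimed to reproduce any
particular published consistency value, since per-scan rater data are not
available.

Bootstrap confidence intervals resample *scans* with replacement (each
resampled scan keeps its full reader-call vector and truth; the original
scan count is maintained), recompute the statistic per iteration, and take
the empirical 2.5th / 97.5th percentiles of 10,000 replicates, all
deterministically under a seed. An assessment-pair resampling mode exists
for the alternative reading of the design. Iterations with an undefined
statistic are dropped; more than 50 % undefined is an error. Modality
comparison reports point estimates, intervals and a CI-overlap flag per
metric pair — no additional hypothesis tests are invented, mirroring how
such comparisons are reported in this study design.

# The synthetic-data generator

`simulateBScan()` draws, per pixel,
$$I = I_0\, T(r, c)\, e^{-2\mu_s\Delta r} \cdot E + n_0 E',$$
where $T$ is a 2-D lognormal texture field with correlation length ~3 px
in both axes modulating local reflectivity, $E, E'$ are unit-mean
exponential deviates (fully developed speckle: intensity coefficient of
variation 1), and $n_0$ is the additive noise-floor level. The texture
field must vary axially, not only laterally: any per-column multiplier
cancels exactly in the OAC ratio, and speckle contrast would then carry no
tissue signal at all.

Defaults (simulator constants, not measured tissue values): $\mu_s$ =
1.0 / 2.0 / 3.5 mm⁻¹ and $\sigma_{\mathrm{tex}}$ = 0.10 / 0.30 / 0.55 for
normal white matter / damaged white matter / tumor; $I_0 = 1$;
$n_0 = 10^{-4} I_0$, giving a ~40 dB display dynamic range typical of
intensity OCT. Geometry defaults to 256 depth pixels at 7.5 µm pitch with
configurable width (400 A-scans for training-style scans). Layout
families: homogeneous scans, contiguous tumor infiltration with
damaged-matter margins, and scattered single-block tumor singletons (the
tissue pattern behind scattered false-positive-like maps, counted as
white matter at scan level). Reader panels draw each reader's call from
scan-level sensitivity/specificity; a "unanimous" mode gives all readers
one shared call vector per scan, the regime in which scan-level bootstrap
variance follows the single-observer binomial closed form.

What the generator does **not** model: axial point-spread convolution,
confocal/sensitivity roll-off, speckle spatial correlation beyond one
pixel, polarization channels, and real histology-adjacent heterogeneity.
Passing tests therefore demonstrate the pipeline's statistical and
algorithmic correctness on data with the assumed structure — not clinical
performance on patient scans.

# Numerical choices and problem sizes

* All computation in double precision; masked/undefined cells carry `NaN`
  and propagate, never silent zeros.
* Half-open 0-based depth and lateral intervals throughout; the RSC window
  is centered with output masked within half a window of the border.
* Training/LOOCV exercises use 23 simulated homogeneous scans of 400
  A-scans (460 blocks, 23 folds); bias and separability Monte-Carlo suites
  use 60–200 seed replicates at width 100, and the bootstrap suite uses
  10,000 iterations on 86-scan panels — sizes chosen to make the
  Monte-Carlo error a small fraction of each tested margin.
* Float rasters are stored as 32-bit-float TIFF normalised to [0, 1] with
  the scale factor recorded in the JSON sidecar; 16-bit rasters
  round-trip bit-exactly.

# Known limitations

* The depth-dependent truncation bias of the attenuation estimator is
  characterised but not corrected; absolute OAC values at depth on weakly
  attenuating tissue are systematically high.
* The contextual filter's quantitative thresholds are engineering
  defaults; only their qualitative behaviour is anchored in the source
  heuristics.
* Inter-rater consistency values depend on the agreement formula chosen;
  both offered formulas are deterministic but not interchangeable.
* The simulator's class parameters produce a strongly separable regime;
  real transitional-zone tissue is harder than anything the tests see.
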