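---
title: "Methods: capacitive skin imaging and TEWL analysis with skincap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: capacitive skin imaging and TEWL analysis with skincap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skincap)
```

## The measurement problem

The outermost skin layer, the stratum corneum, is characterised by two
complementary quantities: its water content, and the water flux escaping
through it (trans-epidermal water loss, TEWL, in g·m⁻²·h⁻¹). An occlusive
film — for example a sunscreen — raises the first and suppresses the second,
but both changes are small relative to instrument noise and site-to-site
variability. `skincap` implements an analysis chain designed to make such
subtle changes visible:

1. capacitive images of the skin surface (a fingerprint-sensor die reporting
   one 8-bit grey level per pixel, brighter = higher permittivity = wetter)
   are compared *within* a site across time, using template matching to
   re-find the same region of interest (ROI) in every capture;
2. repeated TEWL readings are summarised by mean, sample SD and coefficient
   of variation (CV), and changes are always expressed against each site's
   own pre-application baseline;
3. a PCA-based image distance ranks whole frames by similarity, providing a
   global, feature-free view of which sites changed and by how much.

A synthetic study generator produces ground-truthed data with the same
statistical structure, so every stage of the chain can be validated against
known truth.

## Template matching

For a template $T$ (the ROI crop, $h \times w$) and target image $I$, every
valid placement $(x, y)$ receives a score computed from the overlapping
pixels. Six scoring functions are provided:

| method | score (standard form) | best match |
|---|---|---|
| SqDiff | $\sum (T - I)^2$ | minimum |
| SqDiff\_Normed | $\sum (T - I)^2 \big/ \sqrt{\sum T^2 \sum I^2}$ | minimum |
| CCorr | $\sum T \cdot I$ | maximum |
| CCorr\_Normed | $\sum T \cdot I \big/ \sqrt{\sum T^2 \sum I^2}$ | maximum |
| CCoeff | $\sum T' \cdot I'$ | maximum |
| CCoeff\_Normed | $\sum T' \cdot I' \big/ \sqrt{\sum T'^2 \sum I'^2}$ | maximum |

where $T'$ and $I'$ are the template and window after subtracting their own
means (the window mean is recomputed at every placement). All sums run over
the template footprint; surfaces contain valid placements only, so no
padding convention ever enters the scores. Coordinates are 0-based with `x`
the column, `y` the row, origin top-left; rectangles are half-open.

Two formula conventions circulate for the correlation families: the
classical (un-squared product, square-rooted denominator) forms above, and a
variant in which each product term is squared and the denominator is used
without the root. The classical forms are the default because they carry
the properties the method names promise (`CCoeff_Normed` is then a Pearson
correlation in $[-1, 1]$, invariant to adding a constant to both images —
exactly what ROI relocation under hydration-induced brightness change
needs). The squared-product variant is available via `literal = TRUE` so
results computed with either convention can be reproduced; both paths are
verified elementwise against an independent nested-loop oracle.

Numerical choices: pixels are cast to doubles; sliding-window sums are
computed by a direct C++ kernel (exact summation, no FFT, so the scores are
bit-for-bit the naive sums); a window with zero energy (or zero variance
under `CCoeff_Normed`) would give 0/0, and is deterministically assigned
the *worst* score (0 for maximised methods, $+\infty$ for minimised ones,
0 for an exact 0/0 difference score) so featureless regions can never win.
Ties in `best_match()` are broken by smallest `y`, then smallest `x`.
Sub-pixel peak interpolation and rotation/scale invariance are out of
scope: captures of a marked skin site differ by small translations only.

The default relocation method is `CCorr_Normed`; on synthetic captures with
realistic noise (SD 5 grey levels) and a 32 × 32 template it recovers the
exact planted offset in ≥ 95 % of trials, and all six methods recover
noiseless offsets exactly.

## Hydration statistics

Grey levels are mapped to a permittivity scale by an affine calibration.
The device's internal calibration is not public, so the default anchors are
physically motivated endpoints: grey 0 → relative permittivity 1 (air) and
grey 255 → 81 (liquid water at ~20 °C), linear in between. This is a
stand-in, flagged as such; all conclusions the package draws are
*within-site differences*, which an affine recalibration rescales but never
reorders. `roi_stats()` reports mean, sample SD and an equal-width
histogram over the calibration range (last bin closed, counts always sum to
the ROI pixel count). `hydration_change()` subtracts each group's baseline
timepoint, and `hydration_tewl_ratio()` forms mean permittivity divided by
mean TEWL — a scale-free index that moves in the *same* direction for both
effects of an occlusive film and therefore amplifies the contrast between
products.

## TEWL statistics

Replicate series (default five readings) are summarised by the arithmetic
mean and the sample ($n-1$) SD — appropriate at $n = 5$ — and by the CV,
$100 \cdot \mathrm{SD}/\mathrm{mean}$, the standard instrument-repeatability
index. Changes are reported absolutely and as a percentage of the baseline
mean. No hypothesis tests are attached: the pipeline is descriptive, and
per-replicate values are always available for external testing.

## PCA image distance

All study frames are flattened row-major, centred by the collection mean,
and the top $N$ eigendirections of the sample covariance are extracted via
the SVD of the centred data matrix — exact, deterministic, with a fixed
sign convention (largest-magnitude coordinate of each component positive).
$N$ defaults to $\min(8, \mathrm{rank})$; with 12 study frames the rank is
at most 11 and 8 components retain nearly all variance.

An image's *component representation* is the set of per-component
contribution vectors $pc(i, \cdot) = s_i \, c_i$, where $s_i$ is the score
along unit component $c_i$. This interpretation (rather than raw scores or
a per-image PCA) makes the distance basis-stable and, at full rank, equal
to the plain image-space distance between centred images; it is isolated
behind `project()` so alternatives are a one-function swap. The distance
between two images is

$$ d = \frac{1}{N} \sum_{i=1}^{N} \sum_{j} \bigl(pc_1(i,j) - pc_2(i,j)\bigr)^2, $$

a mean-squared quantity that is nevertheless conventionally referred to as
a Euclidean distance; `rooted = TRUE` applies the square root to the double
sum before the $1/N$ factor, giving a grey-level-scale quantity. The two
versions rank pairs identically, so the choice never affects orderings.
Because the $c_i$ are orthonormal, the double sum collapses to
$\sum_i (s_{1i} - s_{2i})^2$, which is how projections are compared without
materialising the $N \times p$ matrices; the equivalence is tested against
a brute-force double-sum oracle.

## The synthetic study generator

`study_design()` + `generate_study()` emulate a four-site volar-forearm
study: three sites treated with sunscreens labelled SPF 20, 30 and 50+, one
untreated control; timepoints `before`, `1h`, `2h`; TEWL measured by two
instruments of very different repeatability; skin imaged at every
timepoint.

What is emulated, and how:

* **Micro-relief texture** — two families of gently wandering anti-aliased
  dark lines (default orientations 30° and 120°, spacing 12 px, depth 60
  grey levels) over a plateau (default grey 90), reproducing the
  criss-cross glyphic pattern of real capacitive skin frames without any
  skin physics.
* **Hydration** — a purely additive mean-brightness shift per product and
  timepoint, clipped to the 8-bit range. Defaults: +60/+45/+30 grey levels
  at 1 h for SPF 20/30/50+ (0 for control), slightly attenuated at 2 h.
  The moisturising vehicle dominates this signal, so the *lowest* SPF shows
  the *largest* brightness rise.
* **TEWL** — replicate readings drawn from a normal law (the minimal model
  for data reported as mean ± SD) with mean `baseline_tewl × effect` and SD
  = mean × CV/100, truncated to positive values. Defaults: baseline
  12 g·m⁻²·h⁻¹ (a typical volar-forearm value), multiplicative effects
  0.90/0.80/0.70 at 1 h and 0.85/0.72/0.60 at 2 h for SPF 20/30/50+
  (1.0 for control): occlusion deepens with SPF and with time.
* **Instruments** — CVs of 3 % (condenser-chamber class) versus 15 %
  (unventilated-chamber class), so instrument repeatability itself is a
  study variable.
* **Capture geometry** — each post-baseline frame is a re-capture of the
  site's own texture, translated by a uniform random jitter of up to
  ±10 px per axis, border refilled with fresh (unbrightened) texture, plus
  independent Gaussian capture noise (SD 5 grey levels).

No published effect magnitudes exist for these quantities (they appear
only graphically in the literature this design mirrors), so the defaults
above were fixed once as field-plausible values and are ordinary arguments
of `study_design()`, not claims about any specific product.

All randomness derives from the single design seed through one RNG stream
consumed in a fixed order, so studies are exactly reproducible; the
`run_pipeline()` config exposes that seed at top level.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: non-linear sensor response and spatially
correlated sensor noise, skin deformation, rotation or pressure-dependent
contact differences between captures, occlusion kinetics during the
measurement itself, drift of the baseline over hours, and any real
formulation chemistry. Results on synthetic data validate the *algorithms*
(relocation accuracy, statistical recovery, ranking behaviour), not the
biological claims.

## Problem sizes and degenerate inputs

Validation uses full-size 256 × 300 frames for study-level checks (20
independent study seeds for the ordering properties; 100 seeded trials for
noisy relocation; 200 simulated sessions for CV discrimination) and small
random instances (images ≤ 8×8, templates ≤ 3×3, 100 trials) for exact
oracle equivalence, where the brute-force reference is cheap.

Degenerate inputs are handled deterministically and loudly: all-zero or
constant templates under normalised methods are errors, not silent zeros;
ragged CSV grids, out-of-range pixels, missing schema columns and missing
baselines all raise typed conditions; a missing per-site baseline in
`site_report()` degrades to `NA` deltas with a warning rather than
failing the whole report.

## Known limitations

* The grey → permittivity calibration is a linear stand-in; absolute
  permittivity values (and therefore absolute hydration/TEWL ratios) should
  not be compared across devices.
* Relocation is translation-only and pixel-resolution; real repositioning
  errors include small rotations the matcher will absorb as reduced peak
  scores.
* The PCA distance is computed on a model fitted to the pooled study
  frames; rankings are therefore relative to that collection and change if
  frames are added or removed.
* With translation jitter, *whole-frame* mean brightness underestimates the
  hydration effect (borders are refilled with unbrightened texture); the
  pipeline always measures over the relocated ROI, which does not suffer
  this dilution.
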