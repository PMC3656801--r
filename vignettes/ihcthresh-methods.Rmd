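---
title: "Adaptive threshold segmentation of DAB&H-stained nuclei: models and methods"
author: "ihcthresh package"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Adaptive threshold segmentation of DAB&H-stained nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcthresh)
```

# The problem

Immunohistochemistry (IHC) with a DAB chromogen and a haematoxylin
counterstain produces brightfield images in which immunopositive nuclei are
brown and immunonegative nuclei blue, on an off-white background. Counting
the brown nuclei (here: FOXP3-positive regulatory T-cells in follicular
lymphoma tissue) is a routine quantification task, and locally adaptive
thresholding — recomputing the binarisation cut-off per pixel from the
statistics of a sliding window — is the standard family of methods for it,
because contrast and brightness drift both across a slide and between
acquisitions.

This package implements the full apparatus needed to *compare* such
methods objectively: three colour separations, six classic threshold
algorithms plus two contrast-gated hybrids, a synthetic image generator
with exact ground truth, and pixel-, object- and shape-level agreement
statistics. Because the boundary of a real nucleus is not observable, the
comparison runs on synthetic images whose templates are known by
construction.

# Colour separation

Three monochrome representations of brown stain content are supported, all
under the same polarity contract (objects dark, background bright):

* **Blue channel** — the raw B plane; DAB absorbs strongly in blue.
* **Brown axis** — `B - 0.3 (R + G)`. On an 8-bit image the raw axis is
  bounded by roughly `0.4 B` for neutral backgrounds, i.e. it never
  approaches 255. A fixed contrast gate of 150 (see below) could then
  never open, so by default the axis is min–max rescaled to `[0, 255]`.
  This choice also makes the operation idempotent when re-applied to its
  own output. The unscaled, clipped variant is available with
  `brownAxis(rgb, rescale = FALSE)`.
* **Colour deconvolution** — per-pixel optical densities
  `OD = -log10((I + 1) / 256)` are unmixed against unit absorption vectors
  of haematoxylin and DAB (Ruifrok–Johnston values
  H = (0.650, 0.704, 0.286), DAB = (0.269, 0.568, 0.778); residual =
  normalised cross product). The `+1` offset keeps the transform bijective
  on 8-bit data. Negative concentrations are clipped at zero, and each
  stain map is re-rendered as a pseudo-brightfield intensity
  `255 * 10^(-c)` so that every threshold method sees the same dark-object
  polarity. Stain vectors are overridable ([stainBasis()],
  [readStainBasis()]).

# The threshold methods

All methods scan a `w x w` window (default 51 px, matched to nucleus size)
and share the convention `B = 0` object, `B = 1` background, with strict
inequalities so ties fall to the object branch. Window statistics (mean,
population sd, min, max, contrast) are computed once per image with
mirror-padded borders — reflection avoids the artificial contrast step
that zero- or edge-padding would create — using incremental algorithms
(running sums, van Herk–Gil–Werman extrema), so the cost is independent of
`w`.

| method | rule (background where true) | parameters |
|---|---|---|
| Niblack | `I > m + k sigma` | `k = -0.2` |
| Sauvola | `I > m (1 + k (sigma/R - 1))` | `sauvolaK = +0.2`, `R = 128` |
| White | `m < I * bias` | `bias = 2` |
| Bernsen | `I > (max + min)/2` where contrast `>= Tc`, else background | `Tc = 150` |
| Yasuda | four-step pipeline, below | `T1..T4 = 50, 100, 128, 15` |
| Palumbo | object where `I < T1` or `0.85 m(corners) > m(centre)` | `T1 = 20, T2 = 0.85` |

The *hybrids* apply the Niblack or Sauvola rule only inside the Bernsen
contrast gate (`C >= Tc`) and classify everything else background; in the
benchmark tables "Niblack" and "Sauvola" always mean these hybrids. After
segmentation, a size filter removes every 8-connected component below
900 px (strictly: an 899-px object is removed, a 900-px object kept),
which is smaller than any whole nucleus at this magnification.

Design choices in ambiguous corners, all switchable via
`thresholdParams()`:

* **Sauvola's `k` sign.** The benchmark parameter table prints
  `k = -0.2` for both Niblack and Sauvola. For Niblack (additive rule)
  that is the standard dark-object setting. For the multiplicative Sauvola
  rule, however, a negative `k` raises the threshold *above* the local
  mean wherever the window is flat, so every window that barely clips a
  nucleus floods its background with detections and each object acquires a
  false-positive ring of window-radius size; counts roughly double and
  object precision collapses to about one half. The published per-method
  results (object precision 0.9722, specificity around 0.998, counts equal
  to the template) are only consistent with the original
  Sauvola–Pietikäinen sign, so the package separates the two parameters
  and defaults `sauvolaK = +0.2`; `sauvolaK = -0.2` reproduces the printed
  table literally. One consequence of this resolution is that our Sauvola
  sensitivity sits marginally below Bernsen's, whereas the source tables
  have it marginally above.
* **Bernsen's low-contrast branch.** Read literally, the piecewise rule
  sets the threshold to 0 in low-contrast windows, which would classify
  only pure-black pixels as objects there; the accompanying description
  says low-contrast windows *are background*. Default follows the
  description (`bernsenLowContrast = "background"`), the literal branch is
  available as `"equation"`.
* **Yasuda's scales and final step.** Step 1 rescales the image to
  `[0, 255]` (the printed normalisation lands in `[0, 1]`, but `T3 = 128`
  and `T4 = 15` are clearly 8-bit quantities, so every intermediate image
  here lives on the 8-bit scale, with step-3 "flagged background" pixels
  carrying 255). The final classification uses 3x3 statistics by default
  (`yasudaStep4Window = "local"`), and the printed equation orientation —
  the condition marks an *object* — is the default
  (`yasudaStep4 = "equation"`); the prose-inverted variant is available.
  The equation orientation over-detects around busy texture, which is
  exactly the behaviour reported for this method.
* **Palumbo's geometry.** The 51-px window splits into a 3x3 grid of
  17x17 tiles; the far neighbourhood is the union of the four corner
  tiles. Tiles are equal-sized, so the union mean equals the mean of the
  four tile means.

# The synthetic scene model

A scene ([sceneConfig()], presets A–E via [scenePreset()]) is sampled,
rasterised and rendered as follows.

**Geometry.** Brown nucleus areas are drawn from a normal distribution
truncated at ±2.5 sd (and at zero); the pre-truncation sd is inflated by
the analytic retention factor (≈ 1/0.955) so the *realised* moments match
the configured ones. Shapes are ellipses with aspect ratio matched to the
configured max/min radius statistics, uniformly random orientation, and a
low-order harmonic boundary perturbation (amplitude ≤ 5% of radius);
each shape is rescaled so its analytic polar-integral area equals its
sampled area exactly, which keeps the rasterised template areas unbiased.
Brown nuclei are placed fully inside the frame by rejection sampling with
a 2-px clearance: clusters may be nearly touching, but never merge into
one 8-connected template component, so the template object count always
equals the configured count. (Truly touching nuclei would be
indistinguishable in the template, and the benchmark's object counts are
defined by it.) Blue nuclei have a broader area distribution, may overlap
anything and may be clipped by the frame. The configured preset statistics
mix area and radius figures that are not mutually consistent for any
ellipse (`pi * rmax * rmin` differs from the stated area by up to 12%);
area takes priority, the radii only set the aspect-ratio distribution.

**Rendering.** Background is off-white with a low-frequency illumination
gradient; blue nuclei are filled by mapping a fine Perlin gradient-noise
field through a light-to-dark blue ramp (the "curly" chromatin texture);
brown nuclei are drawn on top, almost homogeneous: a per-nucleus colour
jitter plus a weak, smooth Perlin modulation. Stain density fades linearly
over the outermost 2 px of every nucleus (≈ 10% of the radius). This rim
emulates the gradual, partly blurred nuclear border seen in stained
tissue, and it is what makes mid-range thresholds cut slightly *inside*
the true boundary — without it every method cuts exactly at the geometric
edge (symmetric optical blur does not move the 50% point) and the
characteristic homogeneous under-segmentation of boundary pixels cannot
occur. Templates are purely geometric and unaffected by rendering.

**Degradation** (order fixed, applied to the RGB rendering only):
Gaussian blur (σ = 1 px, the diffraction-limited point spread of a
40x/NA 0.63 objective at typical camera sampling), radial vignette
`1 - v (d/dmax)^2` with v = 0.1 (centre brighter than the periphery),
chromatic aberration as per-channel radial magnification (R x 1.001,
B x 0.999, producing faint colour rims), additive Gaussian noise
(σ = 3 grey levels), then clipping and 8-bit quantisation. Everything is
deterministic given the scene seed.

**Palette.** The defaults — brown (120, 72, 45), blue ramp
(165, 170, 205) to (70, 80, 150), background (235, 232, 228) — are chosen,
not measured. The brown was picked dark enough to be DAB-saturated: under
colour deconvolution it maps to a DAB pseudo-intensity of ≈ 32. A notably
lighter brown (e.g. DAB intensity ≈ 50) would sit exactly on the White
rule's cut-off `m/2` at a nucleus centre, making that method's output
degenerate, which contradicts the reported behaviour of all six methods.
All palette entries are overridable per scene.

**What the generator does not emulate.** Stain hue variation inside
nuclei (orange to dark brown), truly touching nuclei, overlapping brown
nuclei, out-of-focus layers, stromal deposits and slide-level artefacts.
Consequences: the brown-axis channel is *cleaner* here than in real
material, because an achromatic intra-nucleus texture largely cancels in
`B - 0.3(R + G)`; segmentation sensitivities measured on that channel
are therefore optimistic relative to acquired images. Passing tests show
that the methods behave correctly on images with these statistics, not
that any method is adequate for a specific clinical sample.

# Evaluation

Pixel-level agreement uses the confusion counts (0 = object on both
sides) and the standard coefficients: sensitivity, specificity, Dice,
Jaccard, Sokal–Sneath, Rogers–Tanimoto, plus overall pixel accuracy and
precision. Ratios with zero denominators are reported missing. The
benchmark tables also carry the mean ± sd across the six coefficient
columns; this averages heterogeneous quantities and is reproduced only
because the original tables print it.

Object-level agreement requires a correspondence, which the source
material does not specify: here a detected object matches a template
object when their intersection exceeds 50% of the template object's area,
one-to-one, greedily by descending intersection (ties to the lower
label). This keeps homogeneously eroded detections matched while disjoint
blobs become false-positive objects. Object accuracy is matched/template,
object precision matched/detected, and the count error is
detected − template. For object-level statistics, components touching the
image border are excluded (border-clipped objects segment with cavities
and would distort shape features); the per-image tables use all objects.

Shape features per object: pixel area; perimeter by Moore 8-neighbour
contour tracing (diagonal steps count √2; a single pixel has perimeter 1
by convention — roundness depends on this estimator, which is why it is
documented); roundness `4·pi·area/perimeter²`; solidity against the convex
hull of pixel corners (hence ≤ 1); eccentricity and axis ratio from the
same-second-moments ellipse with the single-pixel (1/12) moment term, so
a 1-px object has eccentricity 0. Agreement per feature is summarised as
Bland–Altman tables (difference vs mean, bias, 1.96-sd limits — the limit
multiplier is our choice, the source draws plots without stating limits).

The quasi-Bland–Altman statistic pairs, for every matched object, the
centroid displacement with the relative erroneous area
`(FP + FN) / template area`. A large ratio at near-zero displacement means
the error is distributed homogeneously around the boundary; displacement
growing with the ratio indicates a directional bias.

# Numerical choices and degenerate inputs

* Window statistics are exact: integer images make all running sums
  exact in doubles, and the brute-force oracle agrees to 1e-9 on random
  images (an explicit test).
* `sigma` is the population standard deviation (divide by `w²`); the
  variance is exposed as its square.
* A constant image makes Yasuda's step-1 normalisation undefined; the
  result is defined as all-background.
* Yasuda's step-3 division is guarded: the else-branch only runs where
  the window contrast is at least `T2` (= 100), so the denominator is
  never near zero.
* Component labelling is 8-connected with labels assigned in raster
  order of each component's first pixel; ties cannot occur.
* Masks serialise as 8-bit PNG, object = black.

# Problem sizes

The shipped configuration reproduces the full study at its native scale:
five 1000 × 1000 px images per seed, six methods on three channels, five
master seeds for the aggregate statistics (450 segmentations), and 100
generator seeds for the parameter-recovery checks. These sizes are the
package's defaults; everything scales down through `sceneConfig()` for
experimentation, and the test suite uses 320 × 320 px scenes where a full
image adds nothing.

# Known limitations

* The five benchmark images themselves are not distributed; all
  quantitative reproduction is therefore stochastic, over re-synthesised
  scenes with the published object statistics.
* The brown-axis channel lacks a published absolute scaling; our
  full-range rescale is one defensible choice and threshold parameters on
  that channel should be read accordingly.
* The generator's blue-nucleus count, palette and degradation magnitudes
  are plausibility choices, stated above, not measurements; the published
  per-cell table values cannot be matched cell-by-cell, only in
  aggregate behaviour.
* Whole-slide tiling and stitching are out of scope; the border-exclusion
  flag is the only interface-level concession to tiled processing.
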