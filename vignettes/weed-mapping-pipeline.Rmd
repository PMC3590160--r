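---
title: "From flight plan to weed-map statistics: the uavweeds pipeline"
author: "uavweeds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From flight plan to weed-map statistics: the uavweeds pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uavweeds)
```

## The problem

Early-season site-specific weed management needs weed maps a few weeks after
crop emergence, when weeds sit in small patches, often look spectrally like
the crop, and are only a few centimetres across. UAV imaging can deliver the
centimetre ground sampling distance (GSD) this requires, but three coupled
questions must be answered before any classification is attempted:

1. **Mission geometry** — what altitude, overlap and waypoint grid produce a
   given pixel size over a given field, and at what cost in image count and
   flight time?
2. **Band-to-band registration** — a multi-lens multispectral camera stores
   each channel through its own lens; the channels must be registered onto a
   common grid before any band ratio is meaningful.
3. **Spectral separability** — do the vegetation indices computed from the
   registered imagery actually separate bare soil, crop and weeds, and by
   how much?

`uavweeds` implements all three, plus a synthetic crop-field generator that
makes the full pipeline testable without flying anything.

## Mission geometry

All mission arithmetic follows the nadir pinhole relations. With focal
length $f$, sensor width $s_w$, pixel count $n_x$ and altitude $h$:

$$\mathrm{GSD} = \frac{h\, s_w / n_x}{f}, \qquad
  \mathrm{footprint\ width} = \frac{h\, s_w}{f},$$

and analogously for the short axis. GSD uses the *horizontal* pixel pitch;
the vertical pitch differs by under 0.2% for the supported cameras, and a
constructor validity check refuses cameras whose pitches disagree by more
than 10%.

```{r}
cam <- miniMCA6()
groundSamplingDistance(cam, c(30, 100))   # 1.63 and 5.42 cm/px
imageFootprint(cam, 100)                  # ~69 x 55 m, 0.38 ha
altitudeForGsd(cam, c(1, 4))              # 19 and 74 m
```

Waypoint grids assign forward-lap to the long footprint dimension (along
the flight line) and side-lap to the short one, and round **both** counts
up:

$$n_\mathrm{lines} = \left\lceil \frac{L}{(1-o_\mathrm{side})\,
  \mathrm{fp}_h} \right\rceil, \qquad
  n_\mathrm{per\ line} = \left\lceil \frac{W}{(1-o_\mathrm{fwd})\,
  \mathrm{fp}_w} \right\rceil.$$

This is the convention mission planners use in practice — each image is
credited only its non-overlapping advance, so the grid still covers the
field if the last line is clipped by the boundary — and it reproduces the
117 and 12 images/ha of the worked example below. A greedy oracle that
stops as soon as the far edge of the last footprint passes the field edge
would occasionally plan one line fewer; the tests pin the step-accumulation
convention deliberately.

```{r}
plan <- planGrid(cam, FlightParams(30))    # 60% forward-lap, 30% side-lap
plan
imagesPerHectare(plan, FlightParams(30))
```

Display rounding: GSD to two decimals (cm), footprints to the nearest
metre, `altitudeForGsd()` **up** to whole metres (a pilot cannot fly a
fractional target altitude, and rounding up keeps the GSD at or below the
requested value). Footprint area is exact width times height; note that at
30 m the exact 20.8 x 16.6 m footprint is 0.035 ha while its rounded
21 x 17 m display suggests 0.036 ha.

The flight-time model is deliberately transparent — climb and descent at
the climb rate, serpentine cruise along the waypoint path, plus dwell per
waypoint:

$$T = \frac{2h}{v_\mathrm{climb}} + \frac{\ell_\mathrm{path}}{v_\mathrm{cruise}}
  + n_\mathrm{img}\, t_\mathrm{dwell}.$$

Vendor planners embed unpublished acceleration/turn models, so durations
from `estimateFlightTime()` are the package's own estimate and are only
comparable to such tools in order of magnitude. The waypoint frame is
local: origin at a field corner, x along the direction angle, serpentine
starting at the origin (the starting corner is an arbitrary choice; nothing
downstream depends on it).

## Band-to-band registration

A six-lens camera yields six single-band frames per waypoint. The model
per slave band is a centre-anchored similarity transform plus a
distance-dependent parallax term:

$$q = s\,R(\theta)\,(p - c) + c + \begin{pmatrix} d_x + \delta(D) \\ d_y
  \end{pmatrix}, \qquad
  \delta(D) = \frac{b\, f}{\mathrm{pitch}\cdot D},$$

with $b$ the lateral lens baseline, $D$ the subject distance and $c$ the
image centre. A calibration taken at long range is wrong at close range by
exactly $\delta(D)$ — about 1.8 px for a 30 mm baseline at 30 m — which is
why the parallax term exists. The parallax offset is applied along x;
supplying per-band `dx`/`dy` absorbs any rig orientation. Default
baselines place the lenses on a 2 x 3 grid with 33 mm spacing, a plausible
layout for a compact six-lens rig; the true geometry, when known, should be
configured instead.

Numerical choices:

* **Resampling** is bilinear; samples falling outside the slave frame
  become `NA` rather than zero. Zero-filled borders would leak black pixels
  into every downstream index statistic; `NA`s are excluded instead.
* **Estimation** (`estimateAlignment()`): translation first, by full-frame
  cross-correlation with a 3-point parabolic sub-pixel refinement of the
  peak; then rotation and scale by direct Nelder-Mead minimisation of the
  mean squared intensity difference, initialised at the translation
  estimate. For the sub-degree rotations and sub-percent scale changes of
  rig calibration, this local refinement is more robust at small frame
  sizes than a log-polar/Fourier-Mellin stage and needs no resampling
  machinery of its own. It is a local optimiser: it assumes the
  translation initialisation is within the correlation peak's basin, which
  holds for rig-type misalignments but not for arbitrary large rotations.
* **Quality control** mirrors field practice: spectral values are sampled
  along a short line (45 samples by default) crossing a contrast edge —
  such as the rim of the reflectance panel — and each band's edge is
  localised at its steepest gradient with a 3-point parabolic refinement.
  `misalignmentScore()` is the worst per-band edge offset relative to the
  master band. A band with a flat profile has no localisable edge and
  reports offset 0; probe segments should cross exactly one edge, since
  with two similar edges in view the steepest-gradient rule may lock onto
  different edges in different bands.

```{r}
base <- matrix(40, 96, 96); base[, 49:96] <- 160      # one step edge
stk <- MultibandStack(array(rep(base, 3), c(96, 96, 3)),
                      c(530, 670, 780))
model <- BandAlignmentModel(dx = c(3, 0, 0), dy = c(-2, 0, 0),
                            baseline = rep(0, 3), masterIndex = 3L)
mis <- misalignStack(stk, model)
misalignmentScore(spatialProfile(mis, c(26, 48, 70, 48)))      # ~3 px
misalignmentScore(spatialProfile(applyAlignment(mis, model),
                                 c(26, 48, 70, 48)))           # ~0
```

`misalignStack()` applies the inverse transform, so aligning with the same
model restores the stack up to interpolation error — the round-trip the
test suite checks, along with recovery of random per-band perturbations
(translations to 5 px, rotations to 1 degree, scale to 1%) to under half a
pixel of residual edge offset in at least 95% of seeded trials.

## Spectral separability

Radiometric calibration is a one-point empirical line through the origin
per band, anchored on a reference panel of known reflectance $\rho_p$
(default 0.99): gain $= \rho_p / \overline{\mathrm{DN}}_\mathrm{panel}$.
The three indices are

$$\mathrm{NDVI} = \frac{\mathrm{NIR} - R}{\mathrm{NIR} + R}, \quad
  \mathrm{NGRDI} = \frac{G - R}{G + R}, \quad
  \mathrm{ExG} = 2g - r - b = \frac{2G - R - B}{R + G + B},$$

with lower-case letters the chromatic coordinates. All three are ratios,
so they are invariant to a global positive rescaling of the bands —
computing them on raw digital numbers or on calibrated reflectance gives
the same values whenever calibration is a single gain per band with equal
gains across bands; with band-dependent gains the two differ, and the
package supports both, defaulting to whatever stack it is given. With two
red channels (670 and 700 nm) the 670 nm band is the red input: it is the
canonical red-absorption band, clear of the red-edge transition that the
700 nm channel samples. Band roles resolve by nearest centre wavelength
within 40 nm; pixels with zero denominators are flagged invalid and
excluded from every statistic, never imputed.

Separability is quantified two ways:

* **ANOVA + LSD** (`anovaLsd()`): one-way ANOVA, then pairwise least
  significant differences on the pooled within-group mean square at
  $\alpha = 0.01$, with a compact letter display. No multiplicity
  correction is applied beyond the protected-LSD convention. The test
  suite verifies the empirical type-I rate over 2000 null simulations
  stays within [0.002, 0.025].
* **M-statistic** (`mStatistic()`):
  $M = (\mu_1 - \mu_2) / (\sigma_1 + \sigma_2)$, the histogram-separation
  measure; $|M| > 1$ indicates moderate separability, larger is better.
  The same mean difference separates narrow histograms better than wide
  ones.

ROI sampling treats a pixel as inside a polygon when its **centre** is
(0-based, top-left origin, half-open convention), and the vegetation class
is the pool of crop and weed pixels. `separabilityTable()` assembles, per
camera x altitude x index, the vegetation-vs-soil and crop-vs-weed rows
(class max/min/mean/SD, LSD outcome, M); NDVI rows are emitted only for
stacks with a NIR band, and a missing class yields an absent row rather
than an error.

A note on summary statistics: M computed from per-pixel data does not
equal M recomputed from *rounded* summary tables. The package's tests pin
the definition (e.g. means 0.58/-0.16 with SDs 0.07/0.01 give exactly
9.25) and validate published orderings qualitatively rather than chasing
values derived from unpublished unrounded data.

## The synthetic field generator

`generateScene()` renders the study conditions: a 100 x 100 m sunflower
field, rows 0.7 m apart at direction angle 65 degrees, weed patches
between the rows, 49 white 1 x 1 m sampling frames on a regular grid, and
a 1 x 1 m reflectance panel at the field centre, rasterised at 1.63 cm GSD
(the 30 m multispectral case) by default.

Design choices where the field layout leaves freedom:

* Crop plants are filled discs (default diameter 0.18 m, the size of 4-6
  leaf sunflower) at 0.25 m intra-row spacing with small positional
  jitter — the simplest shape that produces usable row structure. Crop
  pixels stay within 30% of the half row spacing of their centreline, and
  weeds are clipped away from that belt, so row-geometry ground truth is
  exact by construction.
* Weed patches (default 150 per hectare, radius 0.3 m) are clusters of
  smaller discs (0.10 m; weeds at this stage are similar to or smaller
  than the crop, and the configuration refuses weed diameters above the
  crop diameter) centred on inter-row midlines.
* Per-class per-band digital numbers are independent Gaussians clipped to
  the bit depth. Real canopies have correlated bands, texture, shadows and
  BRDF effects; none of that is modelled, so passing tests demonstrate the
  *statistical pipeline* is correct, not that any particular field will
  separate. The default class statistics are back-solved so the index
  summaries land on realistic values (vegetation NDVI about 0.58, bare
  soil about -0.16, crop 0.61 vs weed 0.55); several band-level
  configurations are consistent with the same index summaries and the
  defaults are one of them.
* Mask precedence where geometry overlaps is panel > frame > crop > weed >
  soil, keeping the class masks mutually exclusive and jointly exhaustive
  — an invariant the tests check pixel by pixel.
* Frames are cropped from the scene raster by nearest-neighbour windowing
  (`renderFrames()`); the analysis is nadir over flat terrain, so no
  perspective model is applied.

```{r}
cfg <- SceneConfig(fieldWidth = 10, fieldLength = 10, nFrames = 4L,
                   weedPatchDensity = 400, seed = 7L)
scene <- generateScene(cfg)
scene
```

Problem sizes: the test suite and examples use 10 x 10 m sub-scenes
(613 x 613 px at the default GSD) with a denser weed infestation (400
patches/ha) so that every cover class is well represented at sub-scene
size; registration tests use 96 x 96 px three-band stacks and 100
recovery trials. These sizes give stable statistics while keeping the full
suite in the low minutes.

On parameter recovery: each class x band sample mean is an exact Gaussian
draw, so its standardised deviation from the generator target is a
standard normal. The recovery acceptance therefore checks the *ensemble* —
at least 16 of the 18 class x band means within 2 standard errors (the
binomial expectation of a 95.4% per-check rate) and none beyond 4 —
rather than demanding all 18 simultaneously clear a 2-sigma band, a
criterion that fair sampling noise alone would fail more often than not.

## Known limitations

* Terrain is flat and imaging nadir: no DEM following, no perspective or
  lens distortion, no vignetting.
* The flight-time model ignores acceleration, turns, wind and battery
  limits.
* The alignment estimator is local; it will not recover arbitrary large
  rotations, and profile-based scoring needs a single clean edge in view.
* The scene generator draws bands independently per pixel; it cannot
  emulate spectral correlation, texture or illumination structure, and
  weed/crop spectra at patch level are exactly Gaussian.
* Separability statistics assume pixels are independent samples;
  spatial autocorrelation in real imagery inflates effective sample sizes
  and makes real p-values optimistic. The M-statistic, being
  variance-based, is less sensitive to this but still ignores within-field
  structure.
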