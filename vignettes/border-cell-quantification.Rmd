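---
title: "Quantifying collective border-cell migration: regions, morphometrics and actin flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collective border-cell migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bordercell)
```

## The measurement problem

A migrating border-cell group balances two actin machineries: protrusive
F-actin in the fingers extended by leader cells, and contractile F-actin
in the supracellular cable that runs along the outer rim of the whole
cluster and spans cell boundaries. A third compartment, the inner
cell–cell contacts, stays comparatively constant. `bordercell` turns a
calibrated fluorescence time-lapse of such a group (pixel size in µm,
frame interval in s, one or two channels) plus a small set of clicked
landmarks into:

1. a pixel-level decomposition into protrusions, cable (with broken
   sections) and contacts;
2. scalar morphometrics — protrusion area fraction, cable discontinuity,
   protrusion count, total area, migration speed — and a
   tight/loose/balanced category;
3. a dense actin-velocity field with divergence, retrograde/anterograde
   labels and region-wise flow summaries.

This vignette explains the models and the numerical choices; the README
shows a worked end-to-end example.

## Region decomposition

**Group mask.** The background-subtracted frame is Otsu-thresholded,
holes are filled and the largest connected component is kept
(`segment_group()`). Pixel classification by a trained classifier would
serve the same purpose on real data; thresholding is fully determined by
the image and ships without training data.

**Protrusions versus main body.** The group mask is opened with a disc of
radius 2 µm (configurable); the largest component of the opening is the
main body, and connected components of the remainder with area of at
least 5 µm² become labelled protrusions (`decompose_protrusions()`).
Smaller residues are merged back into the body so that body and
protrusions always partition the mask exactly. A curvature-based edge
filtration could separate the same two compartments; the morphological
opening has the same observable contract — fingers versus body — with a
single interpretable length parameter. The 5 µm² floor operationalises a
"large" protrusion and is configurable; protrusion counts are reported
but never used by the classifier.

**Cable tracing.** The user clicks each cell-to-cell boundary point
along the rim in clockwise order, starting beside the leader protrusion.
The clicked points are snapped to the traced body boundary (tolerance
3 px; a farther landmark is an error naming the landmark), and the
boundary polyline is split at them into per-cell arcs. The peripheral
bundle runs just inside the cell edge, so each boundary vertex is pulled
4 px inward along the local normal and the intensity is sampled at
offsets 3–5 px across the band (sampling across rather than along the
rim keeps intact/broken transitions sharp). A vertex is "cable" when its
band intensity reaches 0.5× the group-mean intensity; maximal runs form
intact cable segments, the rest broken sections, and runs shorter than
3 px are absorbed into their neighbours as speckle denoising. The
threshold fraction is a configuration choice: the criterion is published
only as "according to the F-actin intensity", and half the group mean
separates bundle-level from cytoplasm-level signal over a wide intensity
range because both scale with expression level and bleaching.

**Contacts.** For each clicked endpoint pair the brightest path through
the body (minimum-cost path with pixel cost `1/(1 + I)`, 8-connected,
edge costs weighted by step length) is dilated to a ribbon of half-width
2 px. A tiny cost term proportional to the distance from the straight
chord breaks exact ties, so a featureless image yields the straight
line.

## Morphometrics and classification

Cable discontinuity is the broken length over the total rim length;
protrusion area fraction is protrusion area over total (body +
protrusion) area; areas use the pixel calibration squared. Migration
speed follows the first-and-third-time-point rule: the centroid
displacement between frames 1 and 3 divided by twice the frame interval,
in µm/min; a sliding variant applies the same two-interval rule at every
start frame for time-lapse plots.

The classifier applies the printed band edges with their printed
inclusivities: tight requires fraction < 0.10 *and* discontinuity ≤ 0.08;
loose requires fraction > 0.25 *and* discontinuity ≥ 0.25; balanced
requires 0.10 ≤ fraction ≤ 0.25 *and* 0.08 < discontinuity < 0.25. The
prose leaves combinations such as a low fraction with a badly broken
cable undefined; these are reported as `"unclassified"` — silently
forcing a category would bias downstream statistics.

Relative region intensities are class means divided by the group-mean
intensity of the same frame. The normaliser is a configuration choice
(the denominator is not published); the group mean makes values
comparable across frames once bleaching is corrected. Photobleaching is
modelled as a single exponential on frame means, fitted by least squares
on the log means; each frame is divided by its fitted relative decay, and
a non-decaying fit returns the input unchanged with the decay flagged
absent. Front/middle/rear cell positions are terciles of the centroid
projections on the motion axis (the assignment rule is not published;
terciles are symmetric and scale-free).

## Actin flows

`piv_config()` holds the operating point: source and search windows of
1.4 and 2.4 µm², converted to the nearest odd pixel sides (5 and 7 px at
0.2 µm/px); a correlation cut-off c₀ = 0.5; spatial interpolation with a
6 µm Gaussian (σ 1.2 µm); temporal smoothing with a 20 s kernel (σ 10 s).
"Cross-correlation coefficient" is implemented as the zero-normalised
(Pearson) correlation of the two patches — the only definition bounded in
[−1, 1] for which a 0.5 threshold is meaningful. The argmax is over
integer shifts; ties are broken by the smallest displacement magnitude
and then lexicographically by (dy, dx) for determinism. An optional
3-point parabolic sub-pixel refinement exists behind `subpixel = TRUE`
and is off by default so the estimator is exactly the brute-force
definition the tests check against. The grid stride defaults to the
source-window side (one estimate per non-overlapping source window);
velocities convert as px/frame × pixel size × 60 / frame interval.

Interpolation is a Gaussian-weighted average of the kept estimates at
every in-mask pixel with the kernel truncated at its stated size; the
weights are renormalised over the available estimates, and pixels beyond
the kernel radius of every estimate are invalid rather than zero.
Divergence uses central differences and is defined only where all four
axis neighbours are valid; with µm/min velocities it is in min⁻¹.
Retrograde versus anterograde is the sign of the cosine between the flow
vector and the instantaneous motion direction; zero vectors and exactly
perpendicular flow are unclassified. Flow-angle rose histograms are
plotted in a frame where the protrusion axis maps to 90° (anterograde)
and its opposite to 270°. The "strong flow" occurrence threshold is not
published; the default is half the 95th percentile of the movie's valid
flow speeds, recorded in the output. The sink–myosin association uses a
Spearman rank correlation between the per-frame mean negative divergence
and the mean second-channel intensity over cable pixels; constant series
are flagged undefined instead of silently returning zero.

## The synthetic generator

No imaging data are deposited with the study this pipeline re-implements
(raw data are held on the authors' storage), so the package ships a
generator whose outputs carry exact ground truth. A cluster is a disk of
radius 7 µm (about 35 px) holding 6 cells as angular sectors; junction
angles define both the contact lines (radial polylines to the centre) and
the landmark set a user would click. The cable is a band 2–7 px inside
the disk edge — a ~1 µm bundle with a thin cortex margin outside it —
interrupted by dim gap arcs totalling the requested rim fraction, placed
deterministically away from protrusion bases and junctions. Finger
protrusions (rounded rectangles) attach at specified angles; fixture
protrusion lengths are solved so the rasterised area fraction lands on
the requested value. Ground-truth segment lengths are angular shares of
the continuous circle (the polyline is its rasterisation; summing jagged
pixel steps would over-count unevenly).

Rendering freezes a per-pixel multiplicative log-normal speckle (σ_log
0.18, clipped to [0.7, 1.5]) at frame 1 and advects it by the prescribed
flow with backward bilinear warping; out-of-domain samples take the
region base intensity. Prescribed flows are uniform translation,
retrograde flow anti-parallel to each protrusion axis, centripetal unit
flow on the cable band, or a linear sink v(r) = −k·r with analytic
divergence −2k. Whole-group drift, exponential bleaching
(frame × e^(−Δt/τ)) and clamped Gaussian noise complete the model. All
randomness flows through the spec's single seed; equal specs give
bit-identical movies.

Default intensity levels (background 0, body 110, cable 200, protrusion
150, contact 130, gap 30 counts) emulate a background-subtracted confocal
section and keep the scene Otsu-separable: with a zero background, Otsu's
threshold settles near half the foreground mean (~65 counts), safely
below the dimmest foreground class (body × 0.7 ≈ 77). Broken cable
sections are dimmer than that threshold by design, but they lie inside
the rim margin, so they are enclosed holes that hole-filling restores —
which is why noise-free masks are recovered *exactly*. What the generator
does **not** emulate: the point-spread function and z-blur of a real
confocal stack, intensity inhomogeneity across cells, cell-shape
irregularity, polar-cell signal, or texture decorrelation over time.
Passing tests therefore validate the algorithms' contracts, not
robustness to every property of real microscopy data.

## Problem sizes and tolerances

The shipped fixtures are 160 × 160 px at 0.2 µm/px with 2–10 frames —
small enough that the whole suite (unit, property and end-to-end tests)
runs in well under a minute, while every geometric feature (5 px cable
band, 10–16 px wide protrusions, 3 px PIV shifts) stays several pixels
wide. Morphometric recovery is tested to ±0.02 against generator truth;
the bleach fit to 5 % on τ and 1 % on flattened means; PIV translation
recovery is exact and checked against a literal ZNCC oracle to 1e-9; the
end-to-end sink divergence is accepted within 25 % of −2k, the slack
covering integer-pixel quantisation of a linear field plus interpolation
smoothing. The speed fixture drifts at 0.5 µm/min with a 24 s frame
interval so the drift is a whole pixel per frame; sub-pixel drift would
add centroid pixelisation error of order 0.01 µm/min, which is why the
recovery tolerance is 0.02.

## Known limitations

* Cell identities along the rim come entirely from the clicked
  junctions; cells are not tracked between frames beyond re-using the
  landmarks.
* The cable tracer assumes the bundle runs within a few pixels of the
  body boundary (offset configurable); a cable detached from the rim
  would be labelled broken.
* Plain spatial cross-correlation is O(window² × shifts) per estimate —
  fine at fixture scale and for typical border-cell crops, but large
  mosaics would want an FFT implementation.
* The monoexponential bleach model is per-channel and spatially uniform;
  strongly heterogeneous bleaching would need a per-pixel model.
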