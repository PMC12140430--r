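---
title: "Methods and design of the omnicyte microcolony pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the omnicyte microcolony pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omnicyte)
```

This vignette records how each stage of the pipeline works, which
parameters matter and why their defaults are what they are, and which
design decisions were genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The colony simulator

The simulator is the package's source of ground truth, not a rendering
toy: every downstream module is validated against its masks, lineage and
focus tables.

Cells are spherocylinders (a rectangle with semicircular caps) described
by center, orientation, pole-to-pole length L and width w. Dynamics per
frame interval dt:

* **Growth.** L ← L·exp(g·dt). Exponential single-cell elongation is the
  standard model for steadily growing rod-shaped bacteria, and it makes
  the closed-form population curve 2^(t/t_d), t_d = ln 2/g, available as
  an independent oracle for tests.
* **Division.** A cell divides on reaching its target division length,
  drawn once per cell as N(μ_div, (cv·μ_div)²). The septum sits at
  fraction 0.5 + ε of the length, ε ~ N(0, s_asym); both daughters inherit
  the mother's orientation and tile her footprint exactly. Asymmetric
  septation is small but nonzero in real cells; it also guarantees the
  two daughters are distinguishable in tests.
* **Mechanical relaxation.** After growth and division, overlapping rods
  are separated by iterating pairwise displacements along the line of
  closest approach between their axis segments, with a small angular
  torque from the contact lever arm, capped at 400 iterations per frame
  and stopped when the deepest interpenetration falls below 2% of the
  cell width. This is deliberately minimal mechanics: the goal is a
  monolayer of touching, non-overlapping rods, not a calibrated granular
  simulation.
* **Rasterization.** A pixel belongs to a rod when its center lies within
  w/2 of the rod's axis segment (with a 1e-9 epsilon so exact-boundary
  ties are inclusive); a pixel claimed by two rods goes to the nearer
  axis. Labels are the (globally unique) cell ids.

Defaults describe a typical agarose-pad experiment: 0.1 µm pixels, one
frame every 3 minutes, width 1 µm, initial length 2 µm, division at
4 µm ± 5%, septum asymmetry SD 0.02, and g = ln 2/25 min⁻¹ (a 25-minute
doubling time), which takes a single progenitor past 100 cells within the
default 60 frames on a 512×512 field. A colony that would leave the field
stops the simulation at the last fitting frame with a warning and a
`truncated` flag.

All randomness flows from one root seed. The geometry stream is drawn
inside the simulation; rendering noise, foci and drift each derive a named
substream via `substream_seed()`, so any stage can be re-run independently
and byte-identically.

## Modality renders

`render_modality()` produces idealized contrast, not photometric realism:
each modality is a set of intensity levels for background, cell interior,
cell edge, cell–cell junction and (for phase) a halo ring, followed by
Gaussian blur and then additive white Gaussian noise. The levels encode
the qualitative structure that distinguishes the modalities: phase has
dark cells on a bright background with a bright halo; under- and
over-focused brightfield have weak interiors with opposite-sign edge
relief; in-focus brightfield has almost no interior contrast; cytoplasmic
fluorescence has bright interiors with a dimmer junction line between
touching cells (there is simply less cytoplasm above the contact plane);
membrane fluorescence has a bright shell over a dim, uniform interior.
Noise is added after blur so it stays white, and rendered values are not
clipped, so noise statistics remain exact for tests.

What the renders do **not** emulate: the phase-contrast shade-off artifact
that dims colony centers, realistic point-spread functions, photobleaching,
or uneven illumination. Tests passing on these renders therefore
demonstrate algorithmic correctness on idealized contrast, not performance
on difficult real data — that is exactly the division of labour intended
between the baseline segmenter and imported learned masks.

Foci are additive 2D Gaussians at sub-pixel positions drawn uniformly
along the central 70% of the cell axis with a small lateral offset; the
ground-truth table (position, amplitude, long-axis fraction) is the oracle
for focus-detection tests.

## Registration

Frame-to-frame shifts are estimated by cross-correlation: both images are
mean-subtracted and apodized, correlated via FFT, and the integer peak is
refined on a ±1.5 px neighbourhood sampled at 1/upsample px with a
matrix-multiply DFT, so only the peak region is ever upsampled. Two
choices matter:

* **The window is a Tukey (flat-top) taper, not a Hann window.** A window
  that varies over the interior biases the sub-pixel peak towards zero
  because the windowed moving image is no longer a pure translation of
  the windowed reference; a flat interior with tapered edges keeps the
  translation exact for interior content while still suppressing
  wrap-around.
* **A second pass refines each frame against frame 1.** Sequential
  step estimates accumulate error like a random walk; after applying the
  accumulated shifts, each aligned frame is re-registered directly to the
  first frame and the residual folded in.

Confidence is the normalized correlation peak in [0, 1]; the default
reliability threshold of 0.1 sits far above what independent-noise image
pairs produce (tested empirically) and far below genuine consecutive
frames. Steps larger than `max_step` or unreliable steps are replaced by
the previous accepted step and flagged. Shifts are applied by Fourier
interpolation with wrapped-in margins overwritten by the frame's
background median; masks, if ever resampled, use nearest-integer shifts.

## Baseline segmentation

The baseline segmenter exists so the pipeline runs end-to-end on clean or
synthetic data; learned segmenters enter through `import_masks()` with
identical label semantics. It is a three-step classical scheme: (i)
foreground by Otsu thresholding with modality-dependent polarity (dark
cells for phase, bright for fluorescence, absolute deviation from the
median for low-contrast brightfield), with hole filling; (ii) one seed
per cell from the intensity *core* — the extreme of the original image
within the foreground (bright interiors for cytoplasmic labels, dim
interiors for membrane labels, dark cores for phase), binarized at a
configurable quantile and cleaned of specks; (iii) Voronoi-style
propagation of the seeds across the foreground. The junction-darkening
gradient at cell contacts is what makes step (ii) able to split touching
cells at all; on real data with weak junction contrast this is precisely
where classical schemes fail and learned masks are needed.

Labels are 4-connected by design: diagonal connectivity would let
touching diagonal rods bleed into one label. `clean_mask()` removes
regions below `min_region_area` (default 20 px ≈ 0.2 µm²) and fills only
those background holes whose entire boundary belongs to a single label,
so two labels can never merge; the operation is idempotent.

The boundary-recession calculation models the cost of the older
one-pixel-gap convention: a rod of given area (default width 1.0 µm,
pole-to-pole length solved from the area) is rasterized, and a net
one-pixel-wide strip along the cell's long-axis extent (half a pixel per
shared lateral edge) is counted against the total pixel count. For a
3 µm² cell at 0.1 µm pixels with both lateral edges shared this loses
about a tenth of the cell.

## Linking and temporal consistency

Candidate links between consecutive frames are ranked by shared-pixel
count and matched greedily one-to-one (ties: larger overlap, then smaller
region number). A region with exactly two strong successors that no other
region claims — each receiving at least `min_overlap_frac` (default 0.5)
of its own area from the mother, with summed area within
[`area_ratio_lo`, `area_ratio_hi`] = [0.6, 1.4] of the mother's — is a
division. Unmatched regions end (t) or appear (t+1). Greedy assignment
rather than global optimization is a deliberate simplicity choice: at
adequate frame rates (cells moving less than half a cell width per
frame) the overlap matrix is strongly diagonal and greedy matching is
exact, which the tests verify against exhaustive search on small cases.

Temporal consistency addresses division flicker (1 cell → 2 cells → 1
cell), the signature failure of per-frame segmentation at ambiguous
septa. A genuine re-merge is detected when, within `window` (default 3)
frames of a division, one daughter chain *ends* while a substantial share
(≥ 25%) of its pixels flows into the other chain's continuation — mere
sliver overlaps between adjacent daughters must not trigger suppression.
The transient daughter regions are then relabelled back to one region and
the linkage recomputed, so the division is re-called at the first frame
from which two successors persist.

Cell IDs are persistent across the movie and distinct from per-frame
region numbers: progenitors are numbered in order of first appearance, a
division ends the mother's track and opens two daughter tracks with
`mother_id` set, and regions appearing after frame 1 start tracks flagged
`orphan` or, within 2 px of the field border, `edge-entry`. External
track tables (hand corrections, third-party trackers) are re-imported
verbatim after validation with an itemized error report.

## Cytometry

Geometry comes from the medial axis. The region is skeletonized
(Zhang–Suen thinning), the skeleton pruned to its longest geodesic path
(double BFS), smoothed with a short moving average, and extended at each
end to the cell pole — the farthest region pixel along the local axis
direction within a 1.5 px band around the ray, plus half a pixel for that
pixel's own extent. Length is the arc length of the resulting polyline.
Width is measured per axis sample as the distance to the nearest boundary
pixel on each side of the local normal (the two sides measured
separately, because the discrete skeleton sits off the true center line)
plus one pixel for the two boundary pixels' extents; samples within one
cap length of either pole are excluded, since the caps bias any width
estimate downward. Near-isotropic regions whose skeleton collapses (a
disk) fall back to a single-point axis at the distance-transform maximum.
Regions under 5 px are flagged instead of measured.

Fluorescence uses a per-frame global background (median of non-cell
pixels) — robust and parameter-free; a per-region local background is a
config hook, not the default. Focus detection is difference-of-Gaussians
band-pass filtering (σ, 1.6σ) with three choices that matter in 10-pixel
wide cells: the image outside the cell is flattened to the cell's median
before filtering, because otherwise the strong cell/background edge
bleeds band-pass response across the entire interior; the robust noise
scale uses the lower quartile of absolute deviations rather than a MAD,
because a focus can legitimately cover half of a small cell's interior;
and an absolute amplitude floor (`focus_min_amp`, default 0.08 on [0, 1]
images) rejects faint junction structure. Maxima are refined to sub-pixel
positions by separable quadratic fits and projected onto the axis
polyline to give the long-axis fractional coordinate.

The elongation rate is the least-squares slope of log(length) against
time — the exponential model again — reported with its standard error and
R²; tracks under 3 frames get a flagged missing rate. The clist registry
(`descriptor_registry()`) enumerates every emitted quantity with name,
unit and definition; with two channels and focus detection it defines 89
per-cell descriptors and 34 per-frame quantities, and `assemble_clist()`
refuses any unregistered column. CSV and XLSX exports carry identical
values; the XLSX writer emits plain inline-string worksheets readable by
any spreadsheet tool.

## Evaluation metrics

**Width from contact.** Groups of touching, near-parallel cells
(orientation difference ≤ 15°) are found on the contact graph; pixels of
each group are rotated into (along-axis, perpendicular) coordinates; and
for each along-axis bin in which every participating cell is close to its
full footprint (≥ 70% of its per-bin maximum, which drops bins near cell
poles) and the per-cell intervals form a contiguous stack (no gap above
2 px — a missing middle cell must invalidate the transect), the
outer-to-outer span divided by the number of stacked cells is one width
measurement. The estimate is the median over all measurements and needs
at least 3 valid transects, else the insufficient-contact error. Because
one span crosses k cells but only two outer boundaries, boundary bias is
divided by k — the same reason the metric is a credible proxy for true
width on real data.

`width_stats()` reports bias Δμ and spread σ in both percent and
nanometers; σ is the population (1/n) standard deviation.

**Fatal errors.** Predicted regions are matched to truth cells by
majority (> 50%) pixel overlap. Four conditions are flagged per frame:
over-segmentation (≥ 2 substantial predicted regions owned by one truth
cell), under-segmentation (one predicted region holding the majority of
≥ 2 truth cells), a missed cell (no predicted region either owns it or
covers it — a dropped segmentation), and, when predicted tracks are
supplied, linking errors (a track's owning truth cell changing to a
non-daughter). A contiguous erroneous episode counts once, however many
frames it lasts. Division-timing shifts are exempt, with the exemption
applied in a second pass once persistence is known: an early call is
exempt only when the two-region split is still present at the true
division frame (a transient split that reverts *before* the division is a
real error and counts); a late call is exempt when the two truth siblings
share one predicted region from their birth frame for at most the
tolerance. The tolerance defaults to ±2 frames and is config-exposed;
predicted regions under `min_region_area` are debris, not errors.

## Visualization conventions

Vector outlines trace the region boundary along pixel edges — the 0.5
level of the indicator in the nearest-neighbour sense — so the polygon's
shoelace area equals the pixel count exactly and a 1-px region is the
unit square around its center; vertices are ordered counterclockwise in
display coordinates. Kymographs project region pixels onto the axis
polyline and average into equal-arc-length bins of normalized position.
Cell towers rotate each frame's crop so the axis is horizontal,
disambiguating the 180° pole ambiguity by minimizing the rotation change
between consecutive frames. Lineage trees draw one horizontal segment per
cell from birth to end, daughters spread vertically and mothers centered
over them. All renderers are deterministic given data and style, so
byte-identical outputs are testable.

## Numerical choices and degenerate inputs

* Exact-boundary raster ties are inclusive (epsilon 1e-9) and contested
  pixels go to the nearest rod; without this, floating-point noise can
  open spurious one-pixel gaps between touching cells.
* Empty foregrounds, blank images, all-zero masks and empty clists are
  valid outputs, not errors; unknown modalities, shape mismatches, grid
  holes and 16-bit label overflow are errors with named offenders.
* Greedy link ties break by larger overlap then smaller region number;
  division daughters are ordered by region number.
* The flicker-suppression loop is bounded (25 passes) and recomputes
  linkages after every relabelling.

## Problem sizes used by the tests

The suite validates on colonies of 31 cells over 40 frames (512×512) and
16 cells over 36 frames (256×256), with the end-to-end tracking check run
on a 60-frame colony that passes 100 cells — the size regime at which
colony-scale tracking claims become meaningful while the whole suite
stays fast enough to run habitually. The acceptance script uses a
30-frame, ~20-cell two-channel movie (faster, desynchronized growth:
18-minute doubling, division-length CV 0.1) for the descriptor-count
targets.

## Known limitations

* The baseline segmenter depends on junction contrast; membrane-label
  renders and any real low-contrast data will over- or under-segment —
  that path is served by `import_masks()`.
* The simulator's mechanics are qualitative; cell motion statistics,
  shade-off, and multilayer escape are not modelled, so registration and
  linking performance on the renders bounds only the idealized regime.
* Focus detection assumes diffraction-limited spots well inside the
  cell; foci on the membrane or at the poles are attenuated by the
  interior-restriction that keeps the false-positive rate at zero.
* The low-frame-rate fallback (centroid matching when overlap vanishes)
  is configured off by default and untested against real sparse movies.
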