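---
title: "Pore-size metrology for TEM micrographs: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pore-size metrology for TEM micrographs: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poremetry)
```

# The measurement problem

Hydrogels such as calcium-alginate microcapsules are networks of fibril-like
polymer strands; the spaces between strands ("relative pores") control which
solutes reach cells embedded in the gel. In a 2-D transmission electron
micrograph the stained fibrils render dark and the cavities bright, so the
pore structure is accessible by image analysis: segment the two phases,
compute for every cavity pixel its shortest Euclidean distance to the
surrounding solid, and read off, along the cavity centre lines, half the
wall-to-wall distance — the *relative pore radius* (rpr). The same machinery
applied to the inverted mask yields *fibril-like radii* (flr). Counting how
often each quantized radius value recurs ("frequency") and binning the
counts into nm classes gives a percent-frequency pore-size distribution
that can be compared with nitrogen-physisorption results (BET surface area,
BJH pore-size distribution) on the same material, and, with a cell-contour
mask, resolved by depth from the cell–matrix interface.

`poremetry` implements this chain end to end, plus synthetic phantoms with
known ground truth so that every stage is testable without microscope data.

# The processing chain

The pipeline order is fixed — inhomogeneity correction, total-variation
(TV) denoising, coherence-enhancing shock filtering, binarization, lumen
filtering, distance transform, skeletonization, radius sampling — and
`preprocess()` / `run_porometry()` enforce it. Reasons: the illumination
bias must go first (TV would otherwise spend its budget on the bias
gradient), and the shock filter assumes a denoised input.

## Inhomogeneity correction

`correct_inhomogeneity()` subtracts a large-footprint Gaussian estimate of
the illumination background (default sigma 64 px) and re-centres to the
input mean. Background subtraction was chosen over a frequency-domain
cutoff to avoid ringing at fibril edges. The footprint must sit well above
the fibril width (a few px) and, ideally, above the largest pore scale;
64 px ≈ 150 nm at the default calibration satisfies both. All smoothing in
the package uses reflective padding so the frame edge introduces no
artificial gradients; the residual of a pure intensity ramp after
correction is at the percent level away from a one-footprint-wide border
band.

## TV denoising

`denoise_tv()` minimises the Rudin–Osher–Fatemi objective
$TV(u) + \lVert u-f\rVert^2/(2\,w)$ with Chambolle's dual projection
iteration (step 0.248, relative-change stopping tolerance $10^{-4}$, cap
200 iterations with a warning on non-convergence). The default weight
$w = 0.032\,\times$ intensity range is calibrated so that a flat field at
the phantom's default noise level (sd 15 on a 0–255 scale) loses an order
of magnitude of variance while a two-level step keeps its full amplitude
and its half-maximum crossing within one pixel — the property that matters
for unbiased thresholding.

## Coherence-enhancing shock filtering

`shock_filter()` sharpens along the dominant local orientation: the
structure tensor (gradients at inner scale `sigma_px`, tensor smoothing at
outer scale `rho_px`) supplies the orientation; the sign of the second
directional derivative along it selects local dilation or erosion, applied
with upwind (Osher–Sethian) gradient magnitudes at step `dt` ≤ 0.5 so that
local extrema are fixed points and the scheme obeys a maximum principle.
Defaults: `sigma_px = 0.8`, `rho_px = 3`, `n_iter = 5`, `dt = 0.25`. The
inner scale is deliberately *below* the thinnest fibril width: with the
more usual `sigma_px` ≈ 1.5 the pre-smoothing erases single-pixel fibrils
before the shock term can sharpen them, and segmentation accuracy on
phantoms falls below 95%; at 0.8 px the filter still drives the histogram
towards bimodality (measured by Sarle's coefficient) without eroding thin
structures.

## Binarization and phase polarity

`binarize()` thresholds by Otsu's criterion (a fixed threshold is available
for batch reproducibility). Which side of the threshold is the solid phase
is decided by morphology: the matrix is a network of thin fibrils, the
cavities are comparatively wide, so the candidate phase with the smaller
median distance-transform value is taken as alginate (ties go to the dark
phase — osmium-stained polymer is electron-dense). A connectivity-based
rule ("the matrix is the largest connected component") was tried first and
rejected: whenever single-pixel fibrils are present the cavity phase leaks
through diagonal gaps under 8-connectivity and always wins. The thinness
rule presumes network morphology; for scenes that are not networks (e.g. a
single slit between thick walls) the `polarity` override states the known
convention explicitly.

## Lumen filtering

`filter_small_lumina()` removes cavity components below a physical area
cutoff, 275 nm² by default. Cavities are labelled with 4-connectivity and
the solid phase treated as 8-connected (the standard complementary pairing
that avoids topological paradoxes). At the default pitch of 2.34 nm/px one
pixel covers 5.4756 nm², so the cutoff sits at 50.2 px: a 50-px lumen is
removed, a 51-px lumen kept, with strict `<` for removal. The filter is
idempotent and is the only morphological cleanup applied.

## Distance transform

`distance_transform()` computes exact Euclidean distances (pixel-centre to
pixel-centre, no chamfer approximation); the test suite verifies bitwise
agreement with an $O(n^2)$ brute-force search on random masks. Pixels
outside the frame belong to no phase, so the image border never acts as a
wall — radii near the frame edge are measured only against real structure.

## Skeleton and radius sampling

`extract_skeleton()` produces a one-pixel-wide, topology-preserving centre
axis passing through the distance ridge. Anchors (never deleted) are
plateau local maxima of the distance map that exceed both neighbours along
at least one direction pair (axes or diagonals) by ≥ 0.5 px — the
quantization step of exact pixel distances, which separates genuine ridges
from the shallow lattice-aligned undulations any discrete distance map
carries. Around the anchors, boundary layers are peeled in four
directional subpasses per round (south, east, north, west borders, the
candidate set frozen per subpass), deleting a pixel only if it is a simple
point and not a curve endpoint. Consequences, all exercised by tests: an
odd-width slit keeps exactly its centre row; an even-width slit keeps one
of the two tied centre rows, chosen deterministically by the subpass order
(the smaller row index survives); a disc collapses to a few pixels
containing its centre; every cavity component retains at least one
skeleton pixel.

`measure_radii()` then takes one sample per skeleton pixel: the distance
value there, scaled by the pixel pitch. This pixel-centre convention makes
the measured radius of a width-$w$ slit $\lceil w/2\rceil$ px — within
half a pixel of the geometric half-gap, the quantization floor of the
method. Frequencies aggregate over distance values rounded to 2 decimals
in px, since exact pixel distances form a discrete set.

## Binning conventions

`bin_distribution()` supports two standard schemes — pore radii
(≤ 10, 10–20, 20–25, 25–40, 40–70, > 70 nm) and fibril radii in multiples
of the 2.34 nm pitch (≤ 2.34, …, > 9.36 nm) — plus custom edges. Classes
are right-closed, `(lo, hi]`, so the first class means "radius ≤ 10 nm" as
conventionally printed and no sample can fall between classes. Computed
distributions sum to 100 exactly and are validated at ±0.5; externally
entered printed tables carry per-class rounding and are accepted at ±1
(published columns can sum to 100.5 or 100.7). Depth bins in
`profile_by_depth()` are also `(lo, hi]` outward from the interface, so a
sample exactly on an edge goes to the shallower bin.

On pixel calibration: the instrument magnification is usually reported as
an area per pixel (2.34 nm² at 20000×), yet the standard fibril-radius
class edges are successive multiples of 2.34 nm — a length. The package
takes the *pitch* (nm per pixel side) as explicit configuration with
default 2.34 nm/px, which reproduces the standard class structure; users
with a true area calibration should pass `sqrt(area)` and note the
distinction.

# Depth-resolved interface statistics

`interface_distance_map()` measures the Euclidean distance of every matrix
pixel to the nearest cell-mask pixel (for smooth contours this is the
perpendicular distance to the interface; behaviour at strong concavities
follows the nearest-point reading). `profile_by_depth()` assigns each
radius sample to the 20-nm depth bin of its skeleton pixel, up to a 400-nm
ceiling, and flags bins with fewer than 30 samples as low-confidence. The
20-nm width matches the spatial granularity at which interface remodelling
is typically reported; both the width and ceiling are configurable.
Cell-contour delineation itself is an input (a binary mask), not an
algorithm of this package.

**Boundary censoring.** Within about one pore radius of a solid cell body
the measurement is censored whatever one does: if the cell counts as a
wall, radii near the interface are truncated by the cell itself and the
small-pore share is inflated; if the cell is excluded from the wall set,
runs extend into the unobserved region and the share is deflated. No local
convention removes this — it is the 2-D analogue of edge effects in
spatial statistics. `run_interface()` adopts the matrix-structure reading
(cell excluded from the wall set, `exclude_cell = TRUE`), which keeps
radii measurements anchored to real fibrils; depth profiles should be
compared against a same-convention reference (e.g. across culture times),
exactly as the original interface studies do. For testing the profiling
machinery itself, the generator's no-halo phantom is a *virtual-contour*
control — the matrix continues under the delineation — which is the only
construction under which a perfectly flat null profile is achievable; it
is paired with `exclude_cell = FALSE`.

# Physisorption cross-validation

`bet_surface_area()` fits the BET transform $p/(n(1-p))$ against $p/p_0$
over the classical 0.05–0.2 window (≥ 3 points required, $C > 0$ enforced)
and converts the monolayer capacity with the 0.162 nm² N₂ cross-section.
Because the capacity is the reciprocal of the fitted line evaluated at
$p/p_0 = 1$ — far outside the window — measurement noise is amplified by
extrapolation: with 2% multiplicative noise the recovery error is on the
order of 1% in expectation but individual isotherms can deviate a few
percent, so validation uses replicate isotherms.

`bjh_distribution()` implements the classical Barrett–Joyner–Halenda
descending-pressure recursion on the desorption branch: Kelvin core radius
$r_K = 0.9537/\ln(p_0/p)$ nm, Harkins–Jura film thickness
$t = 0.1\sqrt{13.99/(0.034-\log_{10}(p/p_0))}$ nm, core-to-pore area
correction $(r_p/(r_p-\bar t))^2$, and film-thinning bookkeeping over
previously emptied pores. Geometry is cylindrical even though slit-like
hysteresis (type H3) is common in gels, because that is the convention of
stock analyzer output the image results are compared against; the
thickness model is pluggable. `simulate_physisorption()` provides the
matching forward model (with delayed condensation on the adsorption branch
producing a realistic hysteresis loop) for closed-loop validation;
`classify_isotherm()` labels loops hysteretic when the branches differ
beyond 2% of maximum uptake over $0.4 < p/p_0 < 0.95$. Volume-percent BJH
classes are compared with number-percent image classes as-is — the
convention of published cross-method tables — and that caveat applies to
any such comparison.

# The phantom generators

`generate_fibril_network()` draws straight thick segments as a
*homogeneous line process*: orientation uniform on $[0,\pi)$, signed
offset from the frame centre uniform over the circumradius. Uniform
chord-centre sampling was tried first and rejected because it concentrates
line density centrally, imprinting a radial pore-size gradient that
confounds depth profiles. Fibril widths are drawn from {1, 2, 3} px with
probabilities (0.5, 0.35, 0.15), matching the observation that fibril
radii in alginate gels are dominated by the ≤ 2 px classes; a pixel
belongs to a fibril if its centre lies within width/2 of the segment axis.
The default density (50 chords on a 512-px frame at 2.34 nm/px) was chosen
once, from truth masks alone, to land the ground-truth radius distribution
in the morphology class published for 0.8% w/v alginate (≈ 45–50% of radii
≤ 10 nm with a tail beyond 40 nm); about 20 extra chords emulate the
denser 1.4% morphology.

Ground truth is measured on the clean mask by `scan_gap_widths()`, a
directional run scan (axes and diagonals, diagonal runs scaled by
$\sqrt2$, minimum run per cavity pixel, each pixel weighted by 1/width so
a channel counts by length, as centre-line sampling does). It shares no
code with the distance-transform/skeleton chain, so closed-loop tests pit
two independent measurement routes against each other. A medial-point
variant (`medial_gap_widths()`) is retained as a second cross-check; note
that raw medial plateaus double-count even-width channels relative to
one-pixel skeletons, which is why the run scan is the reference.

`render_tem()` corrupts the two-level image with a smooth additive bias
field (heavily smoothed seeded noise, default amplitude 20 intensity
units, correlation scale 100 px) and white Gaussian noise (default sd 15),
clipped to 0–255, alginate dark (60) on bright cavities (180). With both
amplitudes zero the rendering is exactly the two-level image. What the
phantoms deliberately do **not** model: electron-optical point-spread,
section-thickness projection, stain granularity, charging artefacts, or
curved fibrils. Passing closed-loop tests therefore demonstrates that the
measurement chain is unbiased under controlled corruption of known
morphology — not that segmentation of any particular real micrograph is
correct; on real data the preprocessing parameters and polarity should be
inspected per batch.

`generate_cell_phantom()` adds a disc cell and, within a halo of default
depth 40 nm, extra thin fibrils until the near-field small-gap fraction
exceeds the far field by the requested boost (measured with the same
convention the pipeline uses, so closed-loop recovery is well-defined).
All generators are bit-reproducible under a fixed seed and restore the
caller's RNG state.

# Statistical notes on validation

Skeleton samples are spatially correlated (one large pore contributes many
pixels), so raw-count chi-square tests on depth profiles overstate
significance. Flatness of the null profile is therefore tested on
block-thinned samples (one per 24-px tile per image), which are
approximately independent. Distribution agreement is summarised by
total-variation distance (half the L1 difference of the class
proportions); the closed-loop requirement is TV ≤ 0.15 against ground
truth, typically met with an order of magnitude to spare at default
settings.

Problem sizes used by the test-suite and acceptance runs — a 1024² network
phantom for distribution recovery, 256² phantoms over three densities and
five seeds for monotonicity, 384² cell phantoms (five halo, ten null) for
interface profiling, 50 random 64² masks for the distance-transform oracle,
80-point isotherms for BJH — were chosen as the smallest scenes at which
the quantities of interest are stable.

# Known limitations

* 2-D section metrology: radii are measured in the section plane; no
  stereological correction to 3-D pore sizes is attempted, matching the
  convention of directly comparing section statistics with physisorption.
* The rpr is a pixel-centre distance, so all radii carry a ±0.5 px
  convention offset relative to geometric wall-face distances.
* Auto-polarity assumes fibrils thinner than pores; override it for other
  morphologies.
* Depth bins shallower than one typical pore radius are boundary-censored
  next to solid bodies (see above); interpret them comparatively.
* BJH assumes cylindrical pores and the Harkins–Jura thickness curve;
  materials with strongly slit-like pores are mapped through the same
  convention as standard analyzer reports, not corrected for geometry.

# A worked example

```{r example, eval = FALSE}
net <- generate_fibril_network(seed = 7)          # 512 px, 2.34 nm/px
net <- render_tem(net, seed = 7)                  # bias field + noise
res <- run_porometry(list(net), pipeline_config())
res$pooled                                        # percent per rpr class
compare_distributions(res$pooled, truth_distribution(net))
```
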