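---
title: "Locating the GCLP/ICP watershed in projection-resolved OCT angiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the GCLP/ICP watershed in projection-resolved OCT angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaplexus)
```

## The problem

The inner retina is perfused by distinct capillary plexuses: the nerve fiber
layer plexus (NFLP), the ganglion cell layer plexus (GCLP), the intermediate
capillary plexus (ICP) and the deep capillary plexus (DCP). The GCLP supplies
the retinal ganglion cells — the neurons damaged in glaucoma — so measuring
its vessel density (VD) in isolation is clinically attractive. Its anterior
boundary is easy: the NFL/GCL junction is a high-contrast surface on
structural OCT. Its posterior boundary with the ICP is not an anatomic
surface at all; the ICP straddles the IPL/INL junction and the GCLP reaches
into the anterior IPL, and the GCL/IPL interface itself segments unreliably
on clinical scans.

The approach implemented here defines the boundary *functionally*, as a
vascular watershed: the depth inside the combined ganglion cell + inner
plexiform layer (GCIPL) at which vessel density reaches its minimum between
the two plexuses. Expressed as a fraction of local GCIPL thickness (0 at
NFL/GCL, 1 at IPL/INL), that watershed turns out to be remarkably constant
across the macula, which is what makes it usable as a slab definition: the
GCLP slab is the anterior 75% of the GCIPL, and the superficial vascular
complex (SVC = NFLP + GCLP) runs from the ILM to the same fractional depth.

## The measurement chain

Given a co-registered structural volume and flow (decorrelation) volume with
three segmented surfaces (ILM, NFL/GCL, IPL/INL), `analyze_eye()` runs:

1. **Projection resolution** (`resolve_projection()`). Flow projection
   artifacts ("tails") replicate a vessel's decorrelation signal into every
   deeper voxel of the same A-line. The package suppresses them by *axial
   peak retention*: scanning each A-line from the ILM down, a voxel keeps
   its flow only if it strictly exceeds the running maximum of all
   shallower flow in that A-line; all other voxels drop to the noise floor.
   Monotonically decaying tails are removed, and a deeper vessel survives
   in situ whenever it is brighter than everything above it.
2. **Reflectance-adaptive binarization** (`reflectance_reference()`,
   `adaptive_threshold_map()`, `binarize()`). Each slab angiogram (en face
   maximum projection over a half-open depth interval) is thresholded at
   `offset + slope * ref`, where `ref` is the mean structural signal in a
   reference slab extending 120 µm below the IPL/INL surface. Scaling both
   volumes jointly — e.g. a shadow from a vitreous floater — moves the
   threshold with the signal, so vessel detection sensitivity is preserved
   in attenuated regions (exactly so when `offset = 0`). Pixels whose
   reference falls below `low_signal_cutoff` are excluded from every
   regional average (`low_signal_exclusion()`).
3. **Sector aggregation** (`find_faz_center()`, `build_polar_grid()`,
   `sector_means()`). VD maps (moving average of the vessel mask,
   `vessel_density_map()`) are averaged on a polar grid centered on the
   foveal avascular zone: 0.5-mm annular rings from 0.5 mm outward and 16
   angular slices of 22.5 degrees, with the central 1-mm-diameter circle
   excluded because the plexuses merge near the FAZ. Slice 0 starts at the
   temporal horizontal; quadrants (T/S/N/I) are four contiguous slices
   centered on each principal axis. Rings beyond the circle inscribed in
   the square field are kept but flagged `partial`, since scan corners are
   noisier in practice (pupil vignetting); watershed fits drop them by
   default.
4. **Depth profiling and the watershed fit** (`subslab_vd_profiles()`,
   `fit_profile()`, `locate_extrema()`, `aggregate_quadrants()`). The
   GCIPL is divided into 20 equal-depth sub-slabs; each sub-slab's
   angiogram is binarized against the *shared* threshold map and averaged
   per sector, giving VD as a function of depth fraction with each
   sub-slab's VD attributed to its center fraction `(i + 0.5)/20`. A
   sixth-degree polynomial is fitted by ordinary least squares, per sector
   and pooled per quadrant (the headline mode); the GCLP peak and the
   GCLP/ICP watershed are read off the fitted curve.

## Extremum selection on the fitted curve

Critical points are the real roots of the fitted polynomial's derivative in
(0, 1), cross-checked against a 0.001-step grid evaluation. Two guard rules
make the selection robust on real fits:

* **Peak prominence.** Only interior maxima reaching at least 20% of the
  largest interior maximum count as plexus peaks. Degree-6 fits of profiles
  with long near-empty depth ranges wiggle at the ±0.003 level there, and
  those wiggles must not anchor a watershed.
* **Posterior rise.** A candidate trough only counts as a watershed if the
  fitted curve rises again behind it by at least 20% of the anterior peak's
  height above it. A genuine watershed separates two plexuses; without this
  rule the decaying tail of a single-plexus profile would yield a spurious
  "watershed" at a noise dip.

The trough is then the qualifying interior minimum with the smallest fitted
VD (ties resolved toward the deeper root, since the ICP lies at the IPL/INL
border), and the peak is the most prominent maximum anterior to it. A
profile with no qualifying trough — a single plexus, a monotone fit, a
constant profile — raises a `no-watershed` error rather than returning a
number.

Degenerate inputs are handled explicitly: constant profiles get
`r_squared = 0` and a `degenerate` flag; fits need more points than the
polynomial degree; sectors whose pixels are all excluded propagate `NA`
means.

## The synthetic eye

No public PR-OCTA volumes with surfaces exist, so the package ships a
phantom generator that is itself first-class, tested code. A
`phantom_config()` describes a 6 × 6-mm macular scan (400 × 400 A-lines by
default; the axial pitch defaults to 3 µm/voxel, a typical spectral-domain
scale) with:

* **Layer geometry** — an ILM with a Gaussian foveal pit; an NFL that
  collapses to ~0 at the fovea and thickens nasally into an arcuate wedge;
  a GCIPL thickest in a parafoveal annulus; INL and outer retina below.
  Thickness fields are smooth and analytic, so surface sets are exact.
* **Four plexuses** — planted as randomly oriented capillary segments
  (tubes of 1–2 px radius) in-plane; NFLP segments follow arcuate
  nerve-fiber directions radiating from the disc and are absent where the
  NFL is thinner than 18 µm, with areal density scaled by NFL thickness.
  Axial positions are truncated Gaussians in layer-fraction coordinates.
  The default GCLP/ICP shapes (centers 0.30/1.00 of GCIPL, spreads
  0.18/0.08, areal fractions 0.35/0.30) were calibrated once so that the
  planted axial density has its interior minimum at 0.752 of GCIPL depth —
  the anatomy the pipeline exists to recover. Each capillary pixel
  occupies a single axial voxel (the flow response of a capillary at this
  axial pitch), with fractional surfaces dithering the voxel rounding
  across columns; rounding never pushes a capillary above its host layer's
  anterior surface.
* **Ground truth** — the voxel label volume, the tail-free flow, and the
  planted watershed fraction computed by brute-force 0.001-step grid
  search over the analytic axial density (`planted_watershed_fraction()`;
  flat minimum plateaus resolve to their midpoint).
* **Artifacts and noise** — geometric projection tails (each tail voxel
  carries `decay = 0.5` times the voxel above, seeded at the vessel flow),
  mean-one multiplicative log-normal speckle on structure, a uniform
  additive decorrelation noise floor on flow, and an optional floater
  shadow disc attenuating both volumes.
* **Cohorts** — `cohort_eye()` derives eye *i* of a cohort
  deterministically: multiplicative jitter on layer thicknesses and plexus
  densities, a laterality draw (71% right eyes; left eyes are mirrored and
  flipped back at analysis), and repeat scans sharing the vessel scene but
  not the noise.

Near the FAZ the GCIPL plexuses merge: inside the FAZ radius (0.5 mm
default) the phantom is capillary-free except for a thin (0.1 mm) merged
ring at the border where plexus depths collapse to mid-GCIPL. The merged
ring thus lies entirely inside the excluded central circle — which is the
reason that circle is excluded in the first place.

The threshold defaults (`vd_params()`: slope 0.40, offset 0.10, 7-px
low-pass kernel, which is about 105 µm at the native pitch) are stated in
the run configuration rather than hard-coded. The offset matches the 99th
percentile of vessel-free, tail-free phantom flow (the uniform noise floor
tops out at 0.10); the slope places the nominal threshold (~0.40 in flow
units) well above the noise floor and below the vessel flow range
(0.7–1.0), and keeps detection stable under a 50% shadow.

### What the phantom does not emulate

The generator makes no attempt at optical realism: no interferometric
speckle statistics, no SSADA decorrelation physics, no eye motion, no
pathology, and no vascular trees (capillaries are independent segments, so
connectivity and flow heterogeneity along vessels are absent). Segmentation
is exact by construction, so repeatability estimates exclude segmentation
noise — thickness repeatability in particular is perfect in the phantom.
Passing tests therefore demonstrate that the *measurement chain* recovers
planted vascular anatomy under controlled artifacts, not that it would
survive every property of clinical scans.

## Peak retention and its limits

The axial-peak-retention rule reproduces the two behaviors that matter for
slab VD — tails are removed, deeper brighter vessels survive in situ — and
is exactly testable against a running-maximum oracle. It has a known
structural limitation: a deeper vessel that is *dimmer* than any vessel
above it in the same A-line is suppressed along with the tails. On
phantoms, roughly half of vertically overlapping vessel pairs lose their
deeper member. Two consequences are worth knowing:

* Binarized 2-D slab VD is robust: a slab whose top is the ILM projects
  identically with and without projection resolution, because the first
  voxel attaining each column's maximum is always retained. This is why
  SVC VD needs no projection resolution while GCLP VD does.
* Per-plexus voxel recall degrades with depth (the DCP sees the most
  occlusion). The PR recall/tail-rejection properties are therefore
  assessed on a two-plexus (NFLP + GCLP) phantom, the regime that isolates
  tail-versus-vessel discrimination; and the structure-function
  correlation experiment omits the NFLP so that occlusion (which removes
  GCLP vessels exactly where the NFL is thick) does not confound a planted
  GCLP–GCC relationship.

## The watershed recovery experiment

`config_for_watershed()` builds two-Gaussian phantoms whose planted
watershed sits at a requested depth. The design must respect what a
20-point profile over (0, 1) can see: both density humps must rise inside
the window, and no near-empty depth range may remain behind the deeper
hump (the fitted minimum would drift into it). Two regimes follow:

* targets below 0.8 use a symmetric design (equal spreads of 0.10, centers
  at `target ± h` with `h = min(0.35, target − 0.25, 1.10 − target)`), so
  the planted minimum is the midpoint exactly;
* deeper targets anchor a narrow ICP (spread 0.05) at `target + 0.15` —
  at or beyond the IPL/INL boundary, like the real ICP — and solve the
  GCLP center numerically against the brute-force truth.

Recovery is scored cohort-wise: the pooled whole-macula fit of each eye
yields one trough, and bias/SD are taken across eyes against the planted
truth. The acceptance suite runs 20 eyes per planted depth
{0.60, 0.70, 0.75, 0.85} at 200 × 200 × 320 voxels — the resolution used
for all acceptance-level phantom work, chosen so the full suite runs in
minutes on one CPU; unit tests use 80–160-pixel grids.

## Statistics

Slab statistics follow standard conventions: repeatability as the
within-subject SD of paired repeats, `sqrt(mean(d^2/2))`, divided by the
grand mean (the Bland–Altman convention for a CV); correlations as squared
Pearson coefficients over sector means, with zero-variance inputs flagged
rather than silently propagated; "significantly better correlated" via a
2000-resample bootstrap over sectors (`compare_r2_bootstrap()`), since no
closed form is standard for comparing overlapping correlations of this
kind. Population maps mirror left eyes before pooling and report the
nasal/temporal contrast of the pooled mean.

The comparison of the legacy 80%-GCC boundary with the 75%-GCIPL boundary
reduces to an identity: measured from the ILM, the depth difference is
`0.05 * GCIPL − 0.2 * NFL` µm, so the legacy boundary is too shallow
exactly where the NFL is thicker than a quarter of the GCIPL — the nasal
arcuate wedges — and slightly too deep elsewhere. `compare_gcc80_gcipl75()`
returns the signed map, and the sign law is asserted exactly in the tests.

## Known limitations

* Peak-retention projection resolution occludes deeper-dimmer vessels, as
  discussed; quantities built on 2-D slab masks are insensitive to this,
  voxel-level ones are not.
* The watershed estimate inherits the biases of a global degree-6
  polynomial fit: with a hump truncated by the window edge the fitted
  minimum can shift by roughly a hundredth of GCIPL depth, which is why
  the recovery experiment constrains hump visibility.
* Voxel-center slab membership (half-open intervals) was chosen over
  partial-volume weighting; at 3 µm axial pitch the difference is below
  the sub-slab width, and it guarantees gap-free tiling of the 20
  sub-slabs.
* Whether the study's per-sector VD should be binarized with one shared
  threshold map or per-slab recalibration is ambiguous; the shared map was
  chosen, matching the single published threshold map.
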