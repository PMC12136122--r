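# octaplexus

Quantification pipeline for macular **projection-resolved OCT angiography
(PR-OCTA)**: locating the vascular watershed between the **ganglion cell
layer plexus (GCLP)** and the **intermediate capillary plexus (ICP)**, and
measuring vessel density and thickness of the anatomic slabs that boundary
defines.

## The problem and the method

The GCLP perfuses the retinal ganglion cells, the neurons lost in glaucoma,
so isolating its vessel density (VD) is clinically valuable. Its anterior
boundary is the NFL/GCL surface, but its posterior boundary with the ICP is
not an anatomic surface — it lies inside the IPL, which cannot be segmented
reliably on clinical scans. The package implements a functional definition:
the boundary is the **watershed depth** — the depth of minimum vessel
density — inside the combined ganglion cell + inner plexiform layer
(GCIPL), expressed as a fraction *f* of local GCIPL thickness (*f* = 0 at
NFL/GCL, *f* = 1 at IPL/INL).

The measurement chain, `analyze_eye()`:

1. suppress flow projection ("tail") artifacts by **axial peak retention**:
   a voxel keeps its flow only if it strictly exceeds the running maximum
   of all shallower flow in its A-line;
2. binarize en face maximum-projection angiograms against a
   **reflectance-adaptive threshold** `offset + slope · ref(x,y)`, where
   `ref` is the mean structural signal in a sub-IPL/INL reference slab,
   with low-signal areas excluded;
3. average VD maps on a **FAZ-centered polar grid** (0.5-mm rings, 16
   slices, central 1-mm circle excluded);
4. divide the GCIPL into **20 equal sub-slabs**, build VD-versus-depth
   profiles per sector, fit a **sixth-degree polynomial** by least squares
   per quadrant, and read the GCLP peak and the GCLP/ICP watershed
   (interior minimum) off the fitted curve;
5. apply the derived boundary (anterior 75% of the GCIPL) to produce
   GCLP / SVC / GCC / GCIPL / NFL slab thickness and VD maps, sector
   tables, repeatability CVs and structure–function correlations.

Because no public PR-OCTA volumes exist, the package ships a first-class
**synthetic eye phantom** (`phantom_config()`, `cohort_eye()`,
`generate_cohort()`): layered reflectance with a foveal pit, four capillary
plexuses with controllable depths, geometric projection tails, speckle and
decorrelation noise, repeat scans, mirrored left eyes — and voxel-level
ground truth, including the planted watershed depth computed analytically
by brute force. Every pipeline stage is validated against that truth.

## Worked example

```r
library(octaplexus)

cfg <- phantom_config(grid_n = 160, n_z = 280, seed = 42)  # 6 x 6 mm eye
eye <- cohort_eye(cfg, 1, repeats = 2)                     # surfaces, truth, 2 scans
analysis <- analyze_eye(eye$volumes[[1]], eye$surfaces)
print(analysis)
#> PR-OCTA eye analysis
#>   watershed at 70.6% GCIPL depth, peak at 31.6%
#>   GCLP VD: 30.3% (32.9% without PR)
#>   SVC VD: 42.9% (42.9% without PR)
print(analysis$watershed)
#> Watershed analysis (GCIPL depth fractions)
#>   macula: peak 0.316, watershed 0.706 (fit R^2 0.93)
#>   quadrant peak_fraction trough_fraction peak_vd trough_vd r_squared ...
#> 1        T         0.212           0.710  0.0432  0.001759     0.796
#> 2        S         0.325           0.678  0.0547  0.000524     0.785
#> 3        N         0.336           0.720  0.0348  0.005144     0.696
#> 4        I         0.323           0.740  0.0514  0.000745     0.843
eye$truth$true_watershed_fraction
#> [1] 0.751
```

Reading the output: the phantom planted its GCLP/ICP watershed at 75.1% of
GCIPL depth; the quadrant-pooled polynomial fits locate it at 68–74%
(fitted minima), with the raw profile minima at the 72.5% sub-slab. GCLP VD
drops from 32.9% to 30.3% once projection tails are removed, while SVC VD
is identical with or without projection resolution — the SVC slab starts at
the ILM, so no tails can enter it from above. `write_eye_report()` exports
the depth profiles, sector tables and slab summaries as CSV (plus TIFF
maps), and `plot(analysis$watershed)` draws the VD-versus-depth scatter
with the fitted curves per quadrant.

A thin command-line front end is installed under
`system.file("cli", "octaplexus", package = "octaplexus")` with `generate`
and `analyze` subcommands operating on NIfTI volumes, CSV surface tables
and flat key=value configs.

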