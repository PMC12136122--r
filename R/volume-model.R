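#' Construct a paired structure/flow scan volume
#'
#' @param structure 3-D non-negative reflectance array, `x * y * z`
#'   (`x` fast/A-line axis, `y` B-scan axis, `z` depth).
#' @param flow 3-D non-negative decorrelation (flow) array, same shape.
#' @param lateral_spacing_mm Lateral pixel pitch, mm (default 6/400).
#' @param axial_spacing_um Axial voxel pitch, micrometres.
#' @param laterality `"OD"` or `"OS"`. OS volumes are stored as acquired
#'   (mirror image of OD); analyses flip them to canonical OD orientation.
#' @return A `scan_volume` object.
#' @export
scan_volume <- function(structure, flow,
                        lateral_spacing_mm = 6 / 400,
                        axial_spacing_um = 3,
                        laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  stopifnot(length(dim(structure)) == 3L,
            identical(dim(structure), dim(flow)))
  if (min(flow) < 0 || min(structure) < 0)
    stop("structure and flow must be non-negative", call. = FALSE)
  if (lateral_spacing_mm <= 0 || axial_spacing_um <= 0)
    stop("spacings must be positive", call. = FALSE)
  structure(list(structure = structure, flow = flow,
                 lateral_spacing_mm = lateral_spacing_mm,
                 axial_spacing_um = axial_spacing_um,
                 laterality = laterality),
            class = "scan_volume")
}

#' @export
print.scan_volume <- function(x, ...) {
  d <- dim(x$flow)
  cat(sprintf("OCTA scan volume (%s): %d x %d x %d voxels, %.1f um lateral, %.1f um axial\n",
              x$laterality, d[1], d[2], d[3],
              1000 * x$lateral_spacing_mm, x$axial_spacing_um))
  invisible(x)
}

#' Construct a retinal surface set
#'
#' Per-A-line depths of the three segmented boundaries: inner limiting
#' membrane (ILM), NFL/GCL, and IPL/INL. Depths are 0-based fractional
#' voxel units (the voxel with 0-based index `k` has center depth `k`).
#'
#' @param ilm_z,nflgcl_z,iplinl_z Matrices of depths, `x * y`.
#' @param axial_spacing_um Axial voxel pitch, micrometres.
#' @param lateral_spacing_mm Lateral pixel pitch, mm.
#' @return A `surface_set` object.
#' @export
surface_set <- function(ilm_z, nflgcl_z, iplinl_z,
                        axial_spacing_um = 3,
                        lateral_spacing_mm = 6 / 400) {
  stopifnot(is.matrix(ilm_z),
            identical(dim(ilm_z), dim(nflgcl_z)),
            identical(dim(ilm_z), dim(iplinl_z)))
  structure(list(ilm_z = ilm_z, nflgcl_z = nflgcl_z, iplinl_z = iplinl_z,
                 axial_spacing_um = axial_spacing_um,
                 lateral_spacing_mm = lateral_spacing_mm),
            class = "surface_set")
}

#' @export
print.surface_set <- function(x, ...) {
  d <- dim(x$ilm_z)
  cat(sprintf("Retinal surface set: %d x %d A-lines (ILM, NFL/GCL, IPL/INL)\n",
              d[1], d[2]))
  cat(sprintf("  mean NFL %.1f um, mean GCIPL %.1f um\n",
              mean(x$nflgcl_z - x$ilm_z) * x$axial_spacing_um,
              mean(x$iplinl_z - x$nflgcl_z) * x$axial_spacing_um))
  invisible(x)
}

#' Validate surface ordering and bounds against a volume
#'
#' Checks that ILM <= NFL/GCL <= IPL/INL at every A-line and that all
#' depths lie inside the volume. Mimics the human-grader review step:
#' surfaces are passed through unchanged when sound, otherwise a
#' segmentation error identifying the offending A-lines is raised.
#'
#' @param s A [surface_set()].
#' @param v A [scan_volume()] (or a 3-D array) the surfaces must fit.
#' @return `s`, invisibly unchanged, if valid.
#' @export
validate_surfaces <- function(s, v) {
  stopifnot(inherits(s, "surface_set"))
  vol <- if (inherits(v, "scan_volume")) v$flow else v
  d <- dim(vol)
  if (!identical(dim(s$ilm_z), d[1:2]))
    stop("surface grid does not match volume lateral grid", call. = FALSE)
  bad_order <- which(s$ilm_z > s$nflgcl_z | s$nflgcl_z > s$iplinl_z)
  if (length(bad_order)) {
    idx <- arrayInd(bad_order[seq_len(min(5L, length(bad_order)))], d[1:2])
    stop(sprintf(
      "segmentation error: surface ordering violated at %d A-line(s), e.g. (x,y) 0-based: %s",
      length(bad_order),
      paste(sprintf("(%d,%d)", idx[, 1] - 1L, idx[, 2] - 1L),
            collapse = " ")), call. = FALSE)
  }
  bad_bounds <- which(s$ilm_z < 0 | s$iplinl_z > d[3] - 1)
  if (length(bad_bounds)) {
    idx <- arrayInd(bad_bounds[seq_len(min(5L, length(bad_bounds)))], d[1:2])
    stop(sprintf(
      "segmentation error: surfaces out of volume bounds at %d A-line(s), e.g. (x,y) 0-based: %s",
      length(bad_bounds),
      paste(sprintf("(%d,%d)", idx[, 1] - 1L, idx[, 2] - 1L),
            collapse = " ")), call. = FALSE)
  }
  invisible(s)
}

#' Construct a slab
#'
#' A slab is a depth interval per A-line, `[top_z, bottom_z)` in 0-based
#' fractional voxel units; a voxel belongs to the slab iff its center depth
#' lies in that half-open interval.
#'
#' @param top_z,bottom_z Matrices of fractional voxel depths, `x * y`.
#' @param name Slab name.
#' @return A `slab` object.
#' @export
slab <- function(top_z, bottom_z, name = "slab") {
  stopifnot(is.matrix(top_z), identical(dim(top_z), dim(bottom_z)))
  if (any(top_z > bottom_z))
    stop("slab top_z must not exceed bottom_z", call. = FALSE)
  structure(list(top_z = top_z, bottom_z = bottom_z, name = name),
            class = "slab")
}

#' GCIPL depth-fraction slab
#'
#' Builds the slab between two GCIPL depth fractions, where fraction 0 is
#' the NFL/GCL surface and fraction 1 the IPL/INL surface, interpolated
#' linearly per A-line. This is the coordinate system in which the
#' GCLP/ICP watershed is expressed (e.g. the GCLP occupies fractions
#' 0 to 0.75).
#'
#' @param s A [surface_set()].
#' @param f_top,f_bottom Fractions with `0 <= f_top < f_bottom <= 1`.
#' @param name Slab name.
#' @return A [slab()].
#' @export
gcipl_fraction_slab <- function(s, f_top, f_bottom,
                                name = sprintf("GCIPL[%g,%g]", f_top, f_bottom)) {
  stopifnot(inherits(s, "surface_set"))
  if (!(f_top >= 0 && f_top < f_bottom && f_bottom <= 1))
    stop("require 0 <= f_top < f_bottom <= 1", call. = FALSE)
  th <- s$iplinl_z - s$nflgcl_z
  slab(s$nflgcl_z + f_top * th, s$nflgcl_z + f_bottom * th, name = name)
}

#' Divide the GCIPL into equal-depth sub-slabs
#'
#' Returns `n` slabs with fraction bounds `(i/n, (i+1)/n)`; adjacent slabs
#' share their boundary exactly, and together they tile the GCIPL with no
#' gap or overlap (half-open voxel inclusion). Twenty sub-slabs are used to
#' build the vessel density depth profile.
#'
#' @param s A [surface_set()].
#' @param n Number of sub-slabs (>= 2).
#' @return List of [slab()] objects, anterior to posterior, each carrying
#'   attributes `f_top`, `f_bottom` and `f_center`.
#' @export
subdivide_gcipl <- function(s, n = 20L) {
  n <- as.integer(n)
  if (n < 2L) stop("need at least 2 sub-slabs", call. = FALSE)
  lapply(seq_len(n) - 1L, function(i) {
    sl <- gcipl_fraction_slab(s, i / n, (i + 1) / n,
                              name = sprintf("GCIPL sub-slab %d/%d", i + 1L, n))
    attr(sl, "f_top") <- i / n
    attr(sl, "f_bottom") <- (i + 1) / n
    attr(sl, "f_center") <- (i + 0.5) / n
    sl
  })
}

#' Construct an en face map
#'
#' @param values 2-D `x * y` matrix.
#' @param kind One of `"angiogram"`, `"threshold"`, `"mask"`, `"vd"`,
#'   `"thickness"`, `"exclusion"`.
#' @param lateral_spacing_mm Lateral pixel pitch, mm.
#' @return An `enface_map` (matrix with attributes).
#' @export
enface_map <- function(values,
                       kind = c("angiogram", "threshold", "mask", "vd",
                                "thickness", "exclusion"),
                       lateral_spacing_mm = 6 / 400) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values))
  if (kind %in% c("mask", "exclusion") && !all(values %in% c(0, 1)))
    stop(kind, " maps must be binary {0,1}", call. = FALSE)
  if (kind == "vd" && (min(values) < 0 || max(values) > 1))
    stop("vd maps must lie in [0,1]", call. = FALSE)
  if (kind == "thickness" && min(values) < 0)
    stop("thickness maps must be non-negative", call. = FALSE)
  structure(values, kind = kind, lateral_spacing_mm = lateral_spacing_mm,
            class = c("enface_map", "matrix", "array"))
}

#' @export
print.enface_map <- function(x, ...) {
  cat(sprintf("En face %s map: %d x %d px (%.1f um/px), range [%.4g, %.4g]\n",
              attr(x, "kind"), nrow(x), ncol(x),
              1000 * attr(x, "lateral_spacing_mm"), min(x), max(x)))
  invisible(x)
}

# strip enface attributes -> plain matrix
as_matrix <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

#' Slab thickness map
#'
#' @param sl A [slab()].
#' @param axial_spacing_um Axial voxel pitch, micrometres.
#' @param lateral_spacing_mm Lateral pixel pitch, mm.
#' @return An [enface_map()] of kind `"thickness"` in micrometres.
#' @export
thickness_map <- function(sl, axial_spacing_um = 3,
                          lateral_spacing_mm = 6 / 400) {
  stopifnot(inherits(sl, "slab"))
  enface_map((sl$bottom_z - sl$top_z) * axial_spacing_um,
             kind = "thickness", lateral_spacing_mm = lateral_spacing_mm)
}

#' Mirror an en face map or surface set about the vertical axis
#'
#' Used to bring left-eye (OS) data into canonical right-eye (OD)
#' orientation: the fast (`x`) axis is reversed, swapping nasal and
#' temporal. Mirroring is involutive.
#'
#' @param x An `enface_map`, `surface_set`, matrix, or 3-D array.
#' @return Object of the same type, mirrored.
#' @export
mirror_horizontal <- function(x) {
  if (inherits(x, "surface_set")) {
    n <- nrow(x$ilm_z)
    x$ilm_z <- x$ilm_z[n:1, , drop = FALSE]
    x$nflgcl_z <- x$nflgcl_z[n:1, , drop = FALSE]
    x$iplinl_z <- x$iplinl_z[n:1, , drop = FALSE]
    return(x)
  }
  if (inherits(x, "scan_volume")) {
    n <- dim(x$flow)[1]
    x$structure <- x$structure[n:1, , , drop = FALSE]
    x$flow <- x$flow[n:1, , , drop = FALSE]
    x$laterality <- if (x$laterality == "OD") "OS" else "OD"
    return(x)
  }
  if (length(dim(x)) == 3L) return(x[dim(x)[1]:1, , , drop = FALSE])
  a <- attributes(x)
  out <- unclass(x)[nrow(x):1, , drop = FALSE]
  attributes(out) <- a
  out
}
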