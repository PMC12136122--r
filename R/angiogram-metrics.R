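#' Vessel density quantification parameters
#'
#' Parameters of the reflectance-compensated binarization pipeline. The
#' binarization threshold at a pixel is
#' `threshold_offset + threshold_slope * ref`, where `ref` is the mean
#' structural signal in a reference slab extending `ref_extent_um` below
#' the IPL/INL boundary (covering the INL through the photoreceptor inner
#' segment). The offset absorbs the flow noise floor (its default matches
#' the 99th percentile of vessel-free, tail-free phantom flow); the slope
#' scales the threshold with local OCT signal strength so that shadowed
#' regions keep comparable vessel detection sensitivity.
#'
#' @param threshold_slope Threshold gain per unit reflectance (>= 0).
#' @param threshold_offset Additive threshold floor, flow units.
#' @param lowpass_kernel_px Odd side length of the square averaging kernel
#'   that turns the binary vessel mask into a vessel density map.
#' @param low_signal_cutoff Reflectance below which a pixel is excluded
#'   from all regional averages (shadowed/unreliable).
#' @param ref_extent_um Depth extent of the reflectance reference slab
#'   below the IPL/INL surface, micrometres.
#' @param pr_noise_floor Value suppressed voxels receive during projection
#'   resolution.
#' @return A `vd_params` list.
#' @export
vd_params <- function(threshold_slope = 0.40, threshold_offset = 0.10,
                      lowpass_kernel_px = 7L, low_signal_cutoff = 0.20,
                      ref_extent_um = 120, pr_noise_floor = 0) {
  k <- as.integer(lowpass_kernel_px)
  if (k < 1L || k %% 2L == 0L)
    stop("lowpass_kernel_px must be odd and >= 1", call. = FALSE)
  if (threshold_slope < 0) stop("threshold_slope must be >= 0", call. = FALSE)
  structure(list(threshold_slope = threshold_slope,
                 threshold_offset = threshold_offset,
                 lowpass_kernel_px = k,
                 low_signal_cutoff = low_signal_cutoff,
                 ref_extent_um = ref_extent_um,
                 pr_noise_floor = pr_noise_floor),
            class = "vd_params")
}

#' En face maximum projection of a slab
#'
#' Per (x, y), the maximum flow over voxels whose centers fall in the
#' slab's half-open depth interval `[top_z, bottom_z)`. Columns where the
#' slab has zero thickness (no voxel centers inside) project to 0.
#'
#' @param flow 3-D flow array (typically projection-resolved) or a
#'   [scan_volume()].
#' @param sl A [slab()].
#' @param lateral_spacing_mm Lateral pixel pitch of the output map.
#' @return An [enface_map()] of kind `"angiogram"`.
#' @export
enface_max_projection <- function(flow, sl, lateral_spacing_mm = 6 / 400) {
  if (inherits(flow, "scan_volume")) {
    lateral_spacing_mm <- flow$lateral_spacing_mm
    flow <- flow$flow
  }
  stopifnot(inherits(sl, "slab"), length(dim(flow)) == 3L,
            identical(dim(flow)[1:2], dim(sl$top_z)))
  nz <- dim(flow)[3]
  proj <- matrix(0, nrow(sl$top_z), ncol(sl$top_z))
  k_lo <- max(floor(min(sl$top_z)), 0)
  k_hi <- min(ceiling(max(sl$bottom_z)), nz - 1)
  if (k_hi >= k_lo) {
    for (k in k_lo:k_hi) {
      inside <- sl$top_z <= k & k < sl$bottom_z
      if (any(inside)) {
        sli <- flow[, , k + 1L]
        proj[inside] <- pmax(proj[inside], sli[inside])
      }
    }
  }
  enface_map(proj, kind = "angiogram", lateral_spacing_mm = lateral_spacing_mm)
}

#' Reflectance reference map
#'
#' Mean structural OCT signal per A-line in a reference slab running from
#' the IPL/INL boundary down by `ref_extent_um` micrometres — covering the
#' INL through the photoreceptor inner segment. This map tracks local OCT
#' signal strength (shadows, vignetting) and drives the adaptive threshold
#' and the low-signal exclusion.
#'
#' @param v A [scan_volume()] or 3-D structure array.
#' @param surfaces A [surface_set()].
#' @param params A [vd_params()].
#' @return An [enface_map()] (kind `"angiogram"`, reflectance units).
#' @export
reflectance_reference <- function(v, surfaces, params = vd_params()) {
  if (inherits(v, "scan_volume")) {
    sp <- v$lateral_spacing_mm
    vol <- v$structure
  } else {
    sp <- surfaces$lateral_spacing_mm
    vol <- v
  }
  stopifnot(inherits(surfaces, "surface_set"))
  top <- surfaces$iplinl_z
  bot <- top + params$ref_extent_um / surfaces$axial_spacing_um
  nz <- dim(vol)[3]
  acc <- matrix(0, nrow(top), ncol(top))
  cnt <- matrix(0, nrow(top), ncol(top))
  k_lo <- max(floor(min(top)), 0)
  k_hi <- min(ceiling(max(bot)), nz - 1)
  for (k in k_lo:k_hi) {
    inside <- top <= k & k < bot
    if (any(inside)) {
      sli <- vol[, , k + 1L]
      acc[inside] <- acc[inside] + sli[inside]
      cnt[inside] <- cnt[inside] + 1
    }
  }
  enface_map(ifelse(cnt > 0, acc / pmax(cnt, 1), 0),
             kind = "angiogram", lateral_spacing_mm = sp)
}

#' Reflectance-adaptive threshold map
#'
#' Linear map of the reflectance reference:
#' `threshold = offset + slope * ref`. With `offset = 0`, scaling structure
#' and flow jointly by any constant leaves the binarized vessel mask
#' unchanged, which is the signal-strength compensation property the
#' adaptive threshold exists for. With `slope = 0` it degenerates to a
#' global threshold.
#'
#' @param ref Reflectance reference [enface_map()].
#' @param params A [vd_params()].
#' @return An [enface_map()] of kind `"threshold"`.
#' @export
adaptive_threshold_map <- function(ref, params = vd_params()) {
  stopifnot(inherits(ref, "enface_map"))
  if (min(ref) < 0) stop("reference map must be non-negative", call. = FALSE)
  enface_map(params$threshold_offset +
               params$threshold_slope * as_matrix(ref),
             kind = "threshold",
             lateral_spacing_mm = attr(ref, "lateral_spacing_mm"))
}

#' Binarize an angiogram against a threshold map
#'
#' Strictly greater-than comparison; ties go to background.
#'
#' @param angio Angiogram [enface_map()].
#' @param thr Threshold [enface_map()] of identical geometry.
#' @return An [enface_map()] of kind `"mask"`.
#' @export
binarize <- function(angio, thr) {
  if (!identical(dim(angio), dim(thr)))
    stop("angiogram and threshold map geometry mismatch", call. = FALSE)
  enface_map((as_matrix(angio) > as_matrix(thr)) + 0,
             kind = "mask",
             lateral_spacing_mm = attr(angio, "lateral_spacing_mm"))
}

#' Vessel density map from a binary mask
#'
#' Moving average of the vessel mask with a square kernel: the local
#' fraction of area occupied by vascular pixels. Borders are handled by
#' replication, which preserves the interior mean.
#'
#' @param mask Binary [enface_map()].
#' @param params A [vd_params()]; `lowpass_kernel_px` sets the kernel.
#' @return An [enface_map()] of kind `"vd"` with values in `[0, 1]`.
#' @export
vessel_density_map <- function(mask, params = vd_params()) {
  stopifnot(inherits(mask, "enface_map"))
  if (!all(mask %in% c(0, 1)))
    stop("vessel_density_map expects a binary mask", call. = FALSE)
  k <- params$lowpass_kernel_px
  m <- as_matrix(mask)
  out <- if (k == 1L) m else
    EBImage::filter2(m, matrix(1 / k^2, k, k), boundary = "replicate")
  enface_map(pmin(pmax(out, 0), 1), kind = "vd",
             lateral_spacing_mm = attr(mask, "lateral_spacing_mm"))
}

#' Low-signal exclusion map
#'
#' Flags pixels whose reflectance reference falls below
#' `low_signal_cutoff` — e.g. shadows cast by vitreous floaters — so they
#' can be removed from all regional averages downstream.
#'
#' @param ref Reflectance reference [enface_map()].
#' @param params A [vd_params()].
#' @return An [enface_map()] of kind `"exclusion"` (1 = excluded).
#' @export
low_signal_exclusion <- function(ref, params = vd_params()) {
  stopifnot(inherits(ref, "enface_map"))
  enface_map((as_matrix(ref) < params$low_signal_cutoff) + 0,
             kind = "exclusion",
             lateral_spacing_mm = attr(ref, "lateral_spacing_mm"))
}

#' Mean vessel density over a region
#'
#' Mean of a vessel-density or mask map over `region` minus excluded
#' pixels.
#'
#' @param vd_or_mask [enface_map()] of kind `"vd"` or `"mask"`.
#' @param region Binary [enface_map()] (1 = in region).
#' @param exclusion Optional exclusion [enface_map()] (1 = excluded).
#' @return The mean fraction (scalar).
#' @export
vd_in_region <- function(vd_or_mask, region, exclusion = NULL) {
  if (!identical(dim(vd_or_mask), dim(region)))
    stop("map and region geometry mismatch", call. = FALSE)
  sel <- as_matrix(region) == 1
  if (!is.null(exclusion)) {
    if (!identical(dim(exclusion), dim(region)))
      stop("exclusion map geometry mismatch", call. = FALSE)
    sel <- sel & as_matrix(exclusion) == 0
  }
  if (!any(sel))
    stop("missing-data: region empty after exclusion", call. = FALSE)
  mean(as_matrix(vd_or_mask)[sel])
}
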