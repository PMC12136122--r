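#' Locate the FAZ center on a whole-GCIPL vessel density map
#'
#' Finds the centroid of the largest connected avascular component
#' (VD below `vd_cutoff`) within a centered box of side `search_mm`,
#' falling back to the scan center when no avascular component exists
#' (e.g. a fully vascular map).
#'
#' @param vd Whole-GCIPL [enface_map()] of kind `"vd"`.
#' @param vd_cutoff VD below which a pixel counts as avascular.
#' @param search_mm Side of the centered search box, mm.
#' @return Length-2 numeric, FAZ center in 0-based pixel coordinates,
#'   with attribute `fallback = TRUE` when the scan center was used.
#' @export
find_faz_center <- function(vd, vd_cutoff = 0.15, search_mm = 1.5) {
  stopifnot(inherits(vd, "enface_map"))
  sp <- attr(vd, "lateral_spacing_mm")
  n <- nrow(vd)
  m <- ncol(vd)
  half_px <- search_mm / 2 / sp
  cx <- (n - 1) / 2
  cy <- (m - 1) / 2
  xs <- max(1L, ceiling(cx + 1 - half_px)):min(n, floor(cx + 1 + half_px))
  ys <- max(1L, ceiling(cy + 1 - half_px)):min(m, floor(cy + 1 + half_px))
  crop <- as_matrix(vd)[xs, ys, drop = FALSE] < vd_cutoff
  if (!any(crop)) {
    out <- c(cx, cy)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  lab <- EBImage::bwlabel(crop)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  idx <- which(lab == big, arr.ind = TRUE)
  out <- c(xs[1] - 1 + mean(idx[, 1]) - 1, ys[1] - 1 + mean(idx[, 2]) - 1)
  attr(out, "fallback") <- FALSE
  out
}

#' Build a FAZ-centered polar sector grid
#'
#' Partitions the en face plane into annular sectors: rings of `dr_mm`
#' radial increments starting at `r_inner_mm` (the central 1-mm-diameter
#' circle is excluded because the plexuses merge near the FAZ), and
#' `n_theta` angular slices of the circle. Angle 0 is the temporal
#' horizontal, counter-clockwise through superior, in OD orientation.
#' Radial and angular bins are half-open with ties to the lower bin.
#' Quadrants are four contiguous slices spanning 90 degrees centered on
#' each principal axis (T/S/N/I).
#'
#' Rings that extend beyond the circle inscribed in the field are kept but
#' flagged partial (corner pixels are assigned to their true ring); they
#' can be excluded downstream where corner variability is a concern.
#'
#' @param center_px FAZ center, 0-based pixel coordinates (length 2).
#' @param n Lateral grid size (pixels per side).
#' @param lateral_spacing_mm Lateral pixel pitch, mm.
#' @param dr_mm Radial ring increment.
#' @param n_theta Number of angular slices.
#' @param r_inner_mm Inner exclusion radius.
#' @param r_outer_mm Outer radius; default `Inf` keeps every pixel of the
#'   field.
#' @return A `sector_grid`: `sector_id_map` (0-based ids, `NA` outside the
#'   annulus), per-sector `ring`, `slice`, `quadrant`, `partial` lookup
#'   tables, and the geometry.
#' @export
build_polar_grid <- function(center_px, n, lateral_spacing_mm = 6 / 400,
                             dr_mm = 0.5, n_theta = 16L,
                             r_inner_mm = 0.5, r_outer_mm = Inf) {
  stopifnot(length(center_px) == 2L, n >= 2L, dr_mm > 0, n_theta >= 4L)
  if (center_px[1] < 0 || center_px[1] > n - 1 ||
      center_px[2] < 0 || center_px[2] > n - 1)
    stop("degenerate geometry: center outside field", call. = FALSE)
  sp <- lateral_spacing_mm
  dx <- matrix((seq_len(n) - 1 - center_px[1]) * sp, n, n)
  dy <- matrix((seq_len(n) - 1 - center_px[2]) * sp, n, n, byrow = TRUE)
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, -dx) %% (2 * pi)  # 0 = temporal, CCW, OD orientation
  ring <- floor((r - r_inner_mm) / dr_mm)
  slice <- pmin(floor(n_theta * theta / (2 * pi)), n_theta - 1)
  inside <- r >= r_inner_mm & r < r_outer_mm
  id <- matrix(NA_integer_, n, n)
  id[inside] <- as.integer(ring[inside] * n_theta + slice[inside])
  # full rings fit inside the circle inscribed in the field
  half_field <- (n / 2) * sp
  n_full_rings <- max(0L, as.integer(floor((half_field - r_inner_mm) / dr_mm)))
  ids <- sort(unique(id[!is.na(id)]))
  ring_of <- ids %/% n_theta
  slice_of <- ids %% n_theta
  q <- n_theta / 4L
  quad_lab <- c("T", "S", "N", "I")
  # quadrant = 4 slices spanning 90 deg centered on each axis; slice 0
  # starts at the temporal horizontal, so T owns the last q/2 and first
  # q/2 slices
  quadrant_of <- quad_lab[1 + (((slice_of + q %/% 2) %/% q) %% 4L)]
  structure(list(
    sector_id_map = id,
    sector_ids = ids,
    ring = ring_of, slice = slice_of,
    quadrant = quadrant_of,
    partial = ring_of >= n_full_rings,
    n_full_rings = n_full_rings,
    center_px = as.numeric(center_px), dr_mm = dr_mm,
    n_theta = as.integer(n_theta),
    r_inner_mm = r_inner_mm, r_outer_mm = r_outer_mm,
    lateral_spacing_mm = sp
  ), class = "sector_grid")
}

#' @export
print.sector_grid <- function(x, ...) {
  cat(sprintf("Polar sector grid: %d sectors (%d slices x rings 0..%d), dr %.2f mm, inner %.2f mm\n",
              length(x$sector_ids), x$n_theta, max(x$ring), x$dr_mm,
              x$r_inner_mm))
  cat(sprintf("  center (0-based px): %.1f, %.1f; %d full rings\n",
              x$center_px[1], x$center_px[2], x$n_full_rings))
  invisible(x)
}

#' Per-sector means of an en face map
#'
#' Averages a map over each sector of the grid, skipping excluded pixels.
#' Sectors whose pixels are all excluded get `NA` means and are flagged.
#'
#' @param map An [enface_map()].
#' @param grid A [build_polar_grid()] sector grid.
#' @param exclusion Optional exclusion [enface_map()] (1 = excluded).
#' @param include_partial Keep sectors in partial (corner) rings
#'   (default `TRUE`).
#' @return A `sector_table` data frame: `sector_id`, `ring_index`,
#'   `slice_index`, `quadrant`, `partial`, `n_pixels`, `n_excluded`,
#'   `mean_value`.
#' @export
sector_means <- function(map, grid, exclusion = NULL,
                         include_partial = TRUE) {
  stopifnot(inherits(grid, "sector_grid"))
  if (!identical(dim(map), dim(grid$sector_id_map)))
    stop("map and sector grid geometry mismatch", call. = FALSE)
  vals <- as_matrix(map)
  id <- grid$sector_id_map
  keep_px <- !is.na(id)
  excl <- if (is.null(exclusion)) {
    matrix(0, nrow(vals), ncol(vals))
  } else {
    if (!identical(dim(exclusion), dim(map)))
      stop("exclusion map geometry mismatch", call. = FALSE)
    as_matrix(exclusion)
  }
  fid <- factor(id[keep_px], levels = grid$sector_ids)
  v <- vals[keep_px]
  e <- excl[keep_px] == 1
  n_pixels <- as.integer(table(fid))
  n_excluded <- as.integer(tapply(e, fid, sum, default = 0L))
  sums <- tapply(ifelse(e, 0, v), fid, sum, default = 0)
  n_used <- n_pixels - n_excluded
  mean_value <- ifelse(n_used > 0, sums / n_used, NA_real_)
  out <- data.frame(
    sector_id = grid$sector_ids,
    ring_index = grid$ring,
    slice_index = grid$slice,
    quadrant = grid$quadrant,
    partial = grid$partial,
    n_pixels = n_pixels,
    n_excluded = n_excluded,
    mean_value = as.numeric(mean_value)
  )
  if (!include_partial) out <- out[!out$partial, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sector_table", "data.frame")
  out
}
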