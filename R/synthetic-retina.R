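# Lateral geometry helpers shared by the phantom generator.
# Pixel i (1-based) has center at (i - 1 - (n-1)/2) * spacing mm from the
# scan center; the fovea sits at cfg$fovea_offset_mm from the scan center.

lateral_spacing_mm <- function(cfg) cfg$lateral_size_mm / cfg$grid_n

lateral_axes_mm <- function(cfg) {
  sp <- lateral_spacing_mm(cfg)
  n <- cfg$grid_n
  (seq_len(n) - 1 - (n - 1) / 2) * sp
}

# distance (mm) and angle (rad, 0 = temporal horizontal, CCW through
# superior, OD orientation with +x nasal and +y superior) from the fovea
fovea_polar <- function(cfg) {
  ax <- lateral_axes_mm(cfg)
  n <- cfg$grid_n
  dx <- matrix(ax - cfg$fovea_offset_mm[1], n, n)
  dy <- matrix(ax - cfg$fovea_offset_mm[2], n, n, byrow = TRUE)
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, -dx) %% (2 * pi)
  list(r = r, theta = theta, dx = dx, dy = dy)
}

# fovea position in 0-based pixel coordinates
fovea_center_px <- function(cfg) {
  sp <- lateral_spacing_mm(cfg)
  cfg$fovea_offset_mm / sp + (cfg$grid_n - 1) / 2
}

# Layer thickness fields (micrometres). The pit collapse factor takes the
# inner layers smoothly to ~0 at the foveal center; the NFL adds a nasal
# wedge (arcuate bundles) on top of a thin base; the GCIPL peaks in a
# parafoveal annulus.
layer_thickness_fields <- function(cfg) {
  pol <- fovea_polar(cfg)
  lay <- cfg$layers
  collapse <- if (lay$pit_collapse_mm > 0)
    pol$r^2 / (pol$r^2 + lay$pit_collapse_mm^2) else 1
  wedge <- ((1 - cos(pol$theta)) / 2)^2
  ramp <- pmin(pol$r / 2, 1)
  nfl_um <- collapse * (lay$nfl_base_um + lay$nfl_wedge_um * wedge * ramp)
  gcipl_um <- collapse *
    (lay$gcipl_floor_um + (lay$gcipl_peak_um - lay$gcipl_floor_um) *
       exp(-((pol$r - lay$gcipl_ring_mm) / lay$gcipl_ring_sd_mm)^2 / 2))
  list(nfl_um = nfl_um, gcipl_um = gcipl_um,
       gcc_um = nfl_um + gcipl_um, r = pol$r, theta = pol$theta)
}

#' Generate retinal surfaces for a phantom eye
#'
#' Builds the three segmented boundaries (ILM, NFL/GCL, IPL/INL) implied by
#' the configured layer thickness fields and foveal pit: the ILM dips into
#' the pit, the NFL thins to near zero at the fovea and thickens nasally,
#' and the GCIPL is thickest in a parafoveal annulus and thinnest at the
#' pit.
#'
#' @param cfg A [phantom_config()].
#' @return A [surface_set()] in 0-based fractional voxel depths.
#' @export
make_surfaces <- function(cfg) {
  validate_phantom_config(cfg)
  th <- layer_thickness_fields(cfg)
  ax <- cfg$axial_spacing_um
  pit_um <- cfg$pit$depth_um *
    exp(-th$r^2 / (2 * cfg$pit$radius_mm^2))
  ilm_z <- (cfg$layers$ilm_offset_um + pit_um) / ax
  nflgcl_z <- ilm_z + th$nfl_um / ax
  iplinl_z <- nflgcl_z + th$gcipl_um / ax
  if (min(ilm_z) < 1 || max(iplinl_z) > cfg$n_z - 2)
    stop("invalid-geometry: configured layers do not fit the axial range",
         call. = FALSE)
  surface_set(ilm_z, nflgcl_z, iplinl_z,
              axial_spacing_um = ax,
              lateral_spacing_mm = lateral_spacing_mm(cfg))
}
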