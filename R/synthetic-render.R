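#' Render structure and flow volumes for a phantom eye
#'
#' Produces the paired volumes the analysis consumes. The structural volume
#' assigns each voxel the configured reflectance of its layer (vitreous,
#' NFL, GCL, IPL, INL, outer retina, deep) and applies mean-one
#' multiplicative log-normal speckle. The flow volume is the tail-free
#' planted flow plus, beneath every vessel voxel, a projection tail that
#' decays geometrically with depth (a tail voxel `d` voxels below a vessel
#' of flow `f` carries `f * decay^d`; overlapping tails take the maximum
#' seed), plus a uniform additive decorrelation noise floor. An optional
#' floater shadow attenuates both volumes in a disc of columns.
#' Deterministic given `noise_seed`.
#'
#' @param scene A `truth_scene` from [plant_vessels()].
#' @param surfaces The matching [surface_set()].
#' @param cfg The [phantom_config()].
#' @param noise_seed Seed for speckle and flow noise; repeat scans of the
#'   same eye share `scene` and differ only in this seed.
#' @param laterality `"OD"` or `"OS"`; OS volumes are mirrored about the
#'   vertical axis, as acquired.
#' @return A [scan_volume()].
#' @export
render_volumes <- function(scene, surfaces, cfg,
                           noise_seed = cfg$seed + 2L,
                           laterality = "OD") {
  validate_phantom_config(cfg)
  stopifnot(inherits(scene, "truth_scene"), inherits(surfaces, "surface_set"))
  n <- cfg$grid_n
  nz <- cfg$n_z
  stopifnot(identical(dim(scene$label), c(n, n, nz)))
  set.seed(as.integer(noise_seed))
  rf <- cfg$reflectance
  ax <- cfg$axial_spacing_um
  split_z <- surfaces$nflgcl_z +
    cfg$gcl_fraction * (surfaces$iplinl_z - surfaces$nflgcl_z)
  inl_bot <- surfaces$iplinl_z + cfg$layers$inl_um / ax
  outer_bot <- inl_bot + cfg$layers$outer_um / ax

  structure_vol <- array(rf[["vitreous"]], c(n, n, nz))
  for (k in seq_len(nz)) {
    z <- k - 1  # 0-based voxel center depth
    m <- structure_vol[, , k]
    m[z >= surfaces$ilm_z] <- rf[["nfl"]]
    m[z >= surfaces$nflgcl_z] <- rf[["gcl"]]
    m[z >= split_z] <- rf[["ipl"]]
    m[z >= surfaces$iplinl_z] <- rf[["inl"]]
    m[z >= inl_bot] <- rf[["outer"]]
    m[z >= outer_bot] <- rf[["deep"]]
    structure_vol[, , k] <- m
  }
  sd_sp <- cfg$noise$speckle_sd
  if (sd_sp > 0)
    structure_vol <- structure_vol *
      exp(sd_sp * stats::rnorm(length(structure_vol)) - sd_sp^2 / 2)

  flow <- scene$clean_flow
  decay <- cfg$tail$decay
  if (isTRUE(cfg$tail$enabled) && decay > 0) {
    tail_carry <- matrix(0, n, n)
    for (k in 2:nz) {
      tail_carry <- decay * pmax(tail_carry, scene$clean_flow[, , k - 1])
      flow[, , k] <- flow[, , k] + tail_carry
    }
  }
  if (cfg$noise$flow_floor > 0)
    flow <- flow + stats::runif(length(flow), 0, cfg$noise$flow_floor)

  if (!is.null(cfg$floater)) {
    ax_mm <- lateral_axes_mm(cfg)
    dx <- matrix(ax_mm - cfg$floater$center_mm[1], n, n)
    dy <- matrix(ax_mm - cfg$floater$center_mm[2], n, n, byrow = TRUE)
    att <- ifelse(dx^2 + dy^2 <= cfg$floater$radius_mm^2,
                  1 - cfg$floater$attenuation, 1)
    for (k in seq_len(nz)) {
      structure_vol[, , k] <- structure_vol[, , k] * att
      flow[, , k] <- flow[, , k] * att
    }
  }

  v <- scan_volume(structure_vol, flow,
                   lateral_spacing_mm = lateral_spacing_mm(cfg),
                   axial_spacing_um = ax,
                   laterality = "OD")
  if (laterality == "OS") v <- mirror_horizontal(v)
  v
}

# Deterministic per-eye jitter of a base config: thickness fields and
# plexus areal densities are scaled by mean-one Gaussian factors.
jitter_config <- function(cfg, eye_seed) {
  set.seed(eye_seed)
  tf <- function() max(0.5, 1 + stats::rnorm(1, 0, cfg$jitter$thickness_sd))
  df <- function() max(0.2, 1 + stats::rnorm(1, 0, cfg$jitter$density_sd))
  c2 <- cfg
  t_nfl <- tf(); t_gcipl <- tf()
  c2$layers$nfl_base_um <- cfg$layers$nfl_base_um * t_nfl
  c2$layers$nfl_wedge_um <- cfg$layers$nfl_wedge_um * t_nfl
  c2$layers$gcipl_floor_um <- cfg$layers$gcipl_floor_um * t_gcipl
  c2$layers$gcipl_peak_um <- cfg$layers$gcipl_peak_um * t_gcipl
  for (nm in names(c2$plexuses)) {
    a <- c2$plexuses[[nm]]$areal_fraction * df()
    c2$plexuses[[nm]]$areal_fraction <- min(max(a, 0.01), 0.95)
  }
  laterality <- if (stats::runif(1) < 0.71) "OD" else "OS"
  c2$seed <- eye_seed
  list(cfg = c2, laterality = laterality)
}

#' Generate one eye of a phantom cohort
#'
#' Deterministically derives eye `i` of a cohort: per-eye multiplicative
#' jitter of layer thicknesses and plexus densities, a laterality draw
#' (71% OD, the remainder OS and mirrored), one vessel scene, and
#' `repeats` rendered scans sharing the scene but with independent noise.
#'
#' @param cfg Base [phantom_config()].
#' @param i Eye index (1-based).
#' @param seed Cohort seed.
#' @param repeats Number of repeat scans per eye.
#' @param require_watershed Passed to [plant_vessels()].
#' @return List with `volumes` (list of [scan_volume()]), `surfaces`,
#'   `truth`, `laterality`, and the jittered `config`. For OS eyes the
#'   surfaces and truth maps are mirrored to match the volumes.
#' @export
cohort_eye <- function(cfg, i, seed = cfg$seed, repeats = 2L,
                       require_watershed = TRUE) {
  eye_seed <- as.integer(seed) + 131L * as.integer(i)
  j <- jitter_config(cfg, eye_seed)
  surf <- make_surfaces(j$cfg)
  scene <- plant_vessels(j$cfg, surf, require_watershed = require_watershed)
  vols <- lapply(seq_len(repeats), function(r)
    render_volumes(scene, surf, j$cfg,
                   noise_seed = eye_seed + 7919L * r,
                   laterality = j$laterality))
  if (j$laterality == "OS") {
    surf <- mirror_horizontal(surf)
    scene$label <- mirror_horizontal(scene$label)
    scene$clean_flow <- mirror_horizontal(scene$clean_flow)
    scene$faz_center_px[1] <- (cfg$grid_n - 1) - scene$faz_center_px[1]
  }
  list(volumes = vols, surfaces = surf, truth = scene,
       laterality = j$laterality, config = j$cfg)
}

#' Generate a phantom cohort
#'
#' Convenience wrapper materializing `n_eyes` eyes via [cohort_eye()].
#' Each eye carries full volumes; for large cohorts prefer iterating
#' [cohort_eye()] and discarding each eye after analysis.
#'
#' @param cfg Base [phantom_config()].
#' @param n_eyes Number of eyes (>= 1).
#' @param repeats Repeat scans per eye (>= 1).
#' @param seed Cohort seed.
#' @param require_watershed Passed to [plant_vessels()].
#' @return List of eyes as returned by [cohort_eye()].
#' @export
generate_cohort <- function(cfg, n_eyes, repeats = 2L, seed = cfg$seed,
                            require_watershed = TRUE) {
  stopifnot(n_eyes >= 1, repeats >= 1)
  lapply(seq_len(n_eyes), function(i)
    cohort_eye(cfg, i, seed = seed, repeats = repeats,
               require_watershed = require_watershed))
}
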