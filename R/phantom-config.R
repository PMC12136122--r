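#' Specification of one synthetic vascular plexus
#'
#' Describes a capillary plexus planted by [plant_vessels()]: the anatomic
#' layer it lives in, its axial center and spread in layer-fraction
#' coordinates, the areal fraction of the en face plane it covers, and the
#' in-plane radius of its capillary segments.
#'
#' Axial positions are expressed as fractions of the host layer's local
#' thickness (0 = anterior boundary, 1 = posterior boundary), so a center of
#' 1.0 in the `"GCIPL"` layer straddles the IPL/INL boundary, as the
#' intermediate capillary plexus does. Depths are drawn from a Gaussian
#' truncated to `[trunc_lo, trunc_hi]`.
#'
#' @param name Plexus name; one of `"NFLP"`, `"GCLP"`, `"ICP"`, `"DCP"`.
#' @param layer Host layer: `"NFL"`, `"GCIPL"`, or `"OUTER"` (a band below
#'   the IPL/INL boundary housing the deep capillary plexus).
#' @param center_frac Axial center in layer-fraction coordinates.
#' @param spread_frac SD of the truncated Gaussian of segment depths.
#' @param areal_fraction Target fraction of the en face plane covered by the
#'   plexus' vessel footprint, in (0, 1).
#' @param radius_px In-plane capillary radius in pixels (1-2 typical).
#' @param trunc_lo,trunc_hi Truncation bounds of the depth distribution.
#' @param orientation `"isotropic"` (random in-plane segment directions) or
#'   `"arcuate"` (segments follow nerve-fiber trajectories radiating from
#'   the optic disc; used for the NFLP).
#' @param center_frac_temporal Optional alternative axial center used for
#'   segments in the temporal quadrant (the GCLP peak sits deeper
#'   temporally, where the NFL is thinnest); `NULL` uses `center_frac`
#'   everywhere.
#' @return A `plexus_spec` list.
#' @seealso [phantom_config()]
#' @export
plexus_spec <- function(name, layer = c("GCIPL", "NFL", "OUTER"),
                        center_frac, spread_frac, areal_fraction,
                        radius_px = 1L,
                        trunc_lo = center_frac - 4 * spread_frac,
                        trunc_hi = center_frac + 4 * spread_frac,
                        orientation = c("isotropic", "arcuate"),
                        center_frac_temporal = NULL) {
  layer <- match.arg(layer)
  orientation <- match.arg(orientation)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(center_frac), is.numeric(spread_frac),
            spread_frac > 0,
            areal_fraction > 0, areal_fraction < 1,
            radius_px >= 1, trunc_lo < trunc_hi)
  structure(list(name = name, layer = layer,
                 center_frac = center_frac, spread_frac = spread_frac,
                 areal_fraction = areal_fraction,
                 radius_px = as.integer(radius_px),
                 trunc_lo = trunc_lo, trunc_hi = trunc_hi,
                 orientation = orientation,
                 center_frac_temporal = center_frac_temporal),
            class = "plexus_spec")
}

default_plexuses <- function() {
  list(
    nflp = plexus_spec("NFLP", layer = "NFL", center_frac = 0.50,
                       spread_frac = 0.22, areal_fraction = 0.30,
                       trunc_lo = 0.05, trunc_hi = 0.95,
                       orientation = "arcuate"),
    # GCLP/ICP spreads are calibrated so the planted axial density minimum
    # sits at 0.752 of GCIPL depth, matching the watershed anatomy the
    # pipeline is designed to recover.
    gclp = plexus_spec("GCLP", layer = "GCIPL", center_frac = 0.30,
                       spread_frac = 0.18, areal_fraction = 0.35,
                       trunc_lo = 0.00, trunc_hi = 1.00),
    icp  = plexus_spec("ICP", layer = "GCIPL", center_frac = 1.00,
                       spread_frac = 0.08, areal_fraction = 0.30,
                       trunc_lo = 0.60, trunc_hi = 1.40),
    dcp  = plexus_spec("DCP", layer = "OUTER", center_frac = 0.50,
                       spread_frac = 0.20, areal_fraction = 0.25,
                       trunc_lo = 0.05, trunc_hi = 0.95)
  )
}

#' Configure a synthetic OCTA eye phantom
#'
#' Bundles every parameter of the phantom generator: scan geometry, foveal
#' pit and avascular zone, layer thickness fields, plexus populations,
#' projection-tail model, and noise. The defaults emulate a 6 x 6-mm
#' macular HD scan (400 x 400 A-lines) of a healthy eye: an NFL that thins
#' to nothing at the fovea and thickens nasally into the arcuate wedges, a
#' GCIPL thickest in the parafoveal annulus, four capillary plexuses
#' (NFLP, GCLP, ICP, DCP), geometric flow-projection tails, multiplicative
#' speckle on structure and an additive decorrelation noise floor on flow.
#'
#' @param grid_n Lateral grid size (A-lines per B-scan = B-scan count).
#' @param n_z Number of axial voxels.
#' @param lateral_size_mm Lateral field of view (square), mm.
#' @param axial_spacing_um Axial voxel pitch, micrometres.
#' @param seed Integer seed; the phantom is bit-reproducible given
#'   `seed` + config.
#' @param fovea_offset_mm Length-2 lateral offset of the fovea from scan
#'   center, mm (`+x` nasal, `+y` superior, OD orientation).
#' @param pit List: `depth_um` (ILM depression at the pit center) and
#'   `radius_mm` (Gaussian radius of the pit).
#' @param faz_radius_mm Radius of the foveal avascular zone; the interior
#'   is capillary-free except for the merged border ring, and the default
#'   keeps it inside the excluded central 1-mm-diameter circle.
#' @param merge_ring_mm Width of the merged capillary ring at the FAZ
#'   border (just inside `faz_radius_mm`), where the GCIPL plexuses merge
#'   and their depths collapse to mid-GCIPL.
#' @param layers List of layer thickness field parameters, micrometres:
#'   `ilm_offset_um` (depth of the ILM below the volume top away from the
#'   pit), `nfl_base_um`, `nfl_wedge_um` (amplitude of the nasal NFL wedge),
#'   `gcipl_floor_um`, `gcipl_peak_um`, `gcipl_ring_mm`, `gcipl_ring_sd_mm`
#'   (parafoveal annulus of peak GCIPL thickness), `pit_collapse_mm`
#'   (radius scale over which inner layers collapse at the pit),
#'   `inl_um`, `outer_um` (layers below the IPL/INL boundary).
#' @param plexuses Named list of [plexus_spec()] objects.
#' @param tail List: `enabled` and `decay` in `[0, 1)` — each voxel of a
#'   projection tail carries `decay` times the value one voxel above, seeded
#'   by the vessel's flow.
#' @param noise List: `speckle_sd` (SD of the mean-one multiplicative
#'   log-normal speckle on structure) and `flow_floor` (upper bound of the
#'   uniform additive decorrelation noise on flow).
#' @param flow_range Range of per-segment vessel flow (decorrelation)
#'   values, drawn uniformly.
#' @param reflectance Named vector of relative per-layer reflectance:
#'   `vitreous`, `nfl`, `gcl`, `ipl`, `inl`, `outer`, `deep`.
#' @param gcl_fraction Anterior fraction of the GCIPL rendered at GCL
#'   reflectance (the remainder renders as IPL).
#' @param nflp_min_nfl_um NFL thickness below which no NFLP capillaries are
#'   planted (the NFL plexus is absent where the NFL is thinner than about
#'   18 micrometres).
#' @param gclp_coupling `"none"` (uniform GCLP areal density) or `"gcc"`
#'   (GCLP areal density proportional to local GCC thickness, for
#'   structure-function correlation experiments).
#' @param floater Optional shadow model: list with `center_mm` (length 2),
#'   `radius_mm` and `attenuation` in (0, 1]; structure and flow in the
#'   shadowed columns are multiplied by `1 - attenuation`.
#' @param jitter List of between-eye variation used by [generate_cohort()]:
#'   `thickness_sd` and `density_sd`, SDs of mean-one multiplicative
#'   Gaussian factors applied per eye.
#' @return A validated `phantom_config` list.
#' @examples
#' cfg <- phantom_config(grid_n = 100, n_z = 160, seed = 7)
#' surf <- make_surfaces(cfg)
#' @export
phantom_config <- function(grid_n = 400L, n_z = 320L,
                           lateral_size_mm = 6, axial_spacing_um = 3,
                           seed = 1L,
                           fovea_offset_mm = c(0, 0),
                           pit = list(depth_um = 110, radius_mm = 0.75),
                           faz_radius_mm = 0.5,
                           merge_ring_mm = 0.1,
                           layers = list(),
                           plexuses = default_plexuses(),
                           tail = list(enabled = TRUE, decay = 0.5),
                           noise = list(speckle_sd = 0.20, flow_floor = 0.10),
                           flow_range = c(0.7, 1.0),
                           reflectance = c(vitreous = 0.05, nfl = 1.00,
                                           gcl = 0.45, ipl = 0.80,
                                           inl = 0.35, outer = 0.90,
                                           deep = 0.02),
                           gcl_fraction = 0.6,
                           nflp_min_nfl_um = 18,
                           gclp_coupling = c("none", "gcc"),
                           floater = NULL,
                           jitter = list(thickness_sd = 0.07,
                                         density_sd = 0.10)) {
  gclp_coupling <- match.arg(gclp_coupling)
  lay <- utils::modifyList(list(
    ilm_offset_um = 45,
    nfl_base_um = 6, nfl_wedge_um = 38,
    gcipl_floor_um = 55, gcipl_peak_um = 95,
    gcipl_ring_mm = 1.5, gcipl_ring_sd_mm = 1.1,
    pit_collapse_mm = 0.45,
    inl_um = 36, outer_um = 114
  ), layers)
  tail <- utils::modifyList(list(enabled = TRUE, decay = 0.5), tail)
  noise <- utils::modifyList(list(speckle_sd = 0.20, flow_floor = 0.10), noise)
  jitter <- utils::modifyList(list(thickness_sd = 0.07, density_sd = 0.10),
                              jitter)
  cfg <- structure(list(
    grid_n = as.integer(grid_n), n_z = as.integer(n_z),
    lateral_size_mm = lateral_size_mm,
    axial_spacing_um = axial_spacing_um,
    seed = as.integer(seed),
    fovea_offset_mm = fovea_offset_mm,
    pit = pit, faz_radius_mm = faz_radius_mm,
    merge_ring_mm = merge_ring_mm,
    layers = lay, plexuses = plexuses, tail = tail, noise = noise,
    flow_range = flow_range,
    reflectance = reflectance, gcl_fraction = gcl_fraction,
    nflp_min_nfl_um = nflp_min_nfl_um,
    gclp_coupling = gclp_coupling,
    floater = floater, jitter = jitter
  ), class = "phantom_config")
  validate_phantom_config(cfg)
}

#' @rdname phantom_config
#' @param cfg A `phantom_config` to validate.
#' @export
validate_phantom_config <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (cfg$grid_n <= 0 || cfg$n_z <= 0)
    stop("grid_n and n_z must be positive", call. = FALSE)
  if (cfg$lateral_size_mm <= 0 || cfg$axial_spacing_um <= 0)
    stop("spacings must be positive", call. = FALSE)
  if (cfg$faz_radius_mm >= cfg$lateral_size_mm / 2)
    stop("faz_radius_mm must be smaller than half the field", call. = FALSE)
  th <- unlist(cfg$layers[c("nfl_base_um", "gcipl_floor_um", "gcipl_peak_um",
                            "inl_um", "outer_um")])
  if (any(th <= 0))
    stop("all layer thicknesses must be positive", call. = FALSE)
  if (cfg$tail$decay < 0 || cfg$tail$decay >= 1)
    stop("tail decay must lie in [0, 1)", call. = FALSE)
  af <- vapply(cfg$plexuses, function(p) p$areal_fraction, 0)
  if (any(af <= 0 | af >= 1))
    stop("plexus areal fractions must lie in (0, 1)", call. = FALSE)
  if (length(cfg$flow_range) != 2L || cfg$flow_range[1] <= 0 ||
      cfg$flow_range[1] > cfg$flow_range[2])
    stop("flow_range must be an increasing positive pair", call. = FALSE)
  if (!is.null(cfg$floater)) {
    stopifnot(length(cfg$floater$center_mm) == 2L,
              cfg$floater$radius_mm > 0,
              cfg$floater$attenuation > 0, cfg$floater$attenuation <= 1)
  }
  if (length(cfg$fovea_offset_mm) != 2L)
    stop("fovea_offset_mm must have length 2", call. = FALSE)
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("Phantom OCTA eye configuration\n")
  cat(sprintf("  field: %.1f x %.1f mm, %d x %d A-lines, %d x %g um axial\n",
              x$lateral_size_mm, x$lateral_size_mm, x$grid_n, x$grid_n,
              x$n_z, x$axial_spacing_um))
  cat(sprintf("  plexuses: %s\n",
              paste(vapply(x$plexuses, `[[`, "", "name"), collapse = ", ")))
  cat(sprintf("  tails: %s (decay %.2f/voxel); flow noise floor %.3f\n",
              if (isTRUE(x$tail$enabled)) "on" else "off",
              x$tail$decay, x$noise$flow_floor))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Planted axial vessel density across the GCIPL
#'
#' Evaluates the analytic axial density implied by the configured
#' GCIPL-resident plexuses (truncated-Gaussian mixture weighted by areal
#' fraction) at given GCIPL depth fractions. This is the ground-truth curve
#' whose interior minimum defines the planted watershed.
#'
#' @param cfg A [phantom_config()].
#' @param f Vector of GCIPL depth fractions.
#' @return Numeric vector of planted density (arbitrary units).
#' @export
planted_axial_density <- function(cfg, f) {
  gp <- Filter(function(p) p$layer == "GCIPL", cfg$plexuses)
  if (!length(gp)) return(rep(0, length(f)))
  d <- rep(0, length(f))
  for (p in gp) {
    zlo <- (p$trunc_lo - p$center_frac) / p$spread_frac
    zhi <- (p$trunc_hi - p$center_frac) / p$spread_frac
    norm <- stats::pnorm(zhi) - stats::pnorm(zlo)
    inside <- f >= p$trunc_lo & f <= p$trunc_hi
    d[inside] <- d[inside] + p$areal_fraction *
      stats::dnorm((f[inside] - p$center_frac) / p$spread_frac) /
      (p$spread_frac * norm)
  }
  d
}

#' Locate the planted watershed by dense grid search
#'
#' Brute-force interior minimum of [planted_axial_density()] between the
#' shallowest and deepest GCIPL plexus centers, on a 0.001-step fraction
#' grid restricted to (0, 1).
#'
#' @param cfg A [phantom_config()].
#' @param step Grid step in fraction units.
#' @return The watershed depth fraction.
#' @export
planted_watershed_fraction <- function(cfg, step = 0.001) {
  gp <- Filter(function(p) p$layer == "GCIPL", cfg$plexuses)
  if (length(gp) < 2L)
    stop("no-watershed-truth: need at least two GCIPL plexuses",
         call. = FALSE)
  centers <- vapply(gp, `[[`, 0, "center_frac")
  lo <- min(centers)
  hi <- max(centers)
  if (hi - lo < 2 * step)
    stop("no-watershed-truth: plexus centers do not bracket an interior",
         call. = FALSE)
  f <- seq(lo, hi, by = step)
  d <- planted_axial_density(cfg, f)
  tied <- which(d <= min(d) + 1e-12)
  # a flat minimum plateau (e.g. disjoint truncation supports) resolves to
  # its midpoint
  i <- tied[ceiling(length(tied) / 2)]
  if (min(tied) == 1L || max(tied) == length(f))
    stop("no-watershed-truth: planted axial density has no interior minimum",
         call. = FALSE)
  ws <- f[i]
  if (ws <= 0 || ws >= 1)
    stop("no-watershed-truth: planted minimum falls outside the GCIPL",
         call. = FALSE)
  ws
}

#' Derive a config that plants the watershed at a target depth
#'
#' Builds the two-Gaussian parameter-recovery design. A watershed can only
#' be localized between two density humps the 20-bin profile can sample,
#' and no near-empty depth range may remain behind the deeper hump (the
#' fitted minimum would drift into it). Two regimes satisfy both:
#'
#' * `target < 0.8`: symmetric design — equal spreads (0.10), centers at
#'   `target - h` and `target + h` with
#'   `h = min(0.35, target - 0.25, 1.10 - target)`, so the ICP hugs the
#'   posterior window edge and the planted minimum is the midpoint.
#' * `target >= 0.8`: edge-anchored design — a narrow ICP (spread 0.05)
#'   centered at `target + 0.15` (at or beyond the IPL/INL boundary) and
#'   the GCLP center solved numerically so the brute-force minimum of the
#'   planted density falls exactly on `target`.
#'
#' Both plexuses get equal areal fractions; every other parameter of
#' `cfg` is kept.
#'
#' @param cfg Base [phantom_config()].
#' @param target Desired watershed depth fraction in (0.3, 1).
#' @param areal Common areal fraction of the two plexuses.
#' @return A `phantom_config` whose [planted_watershed_fraction()] is
#'   `target` (to the 0.001 truth grid).
#' @export
config_for_watershed <- function(cfg, target, areal = 0.32) {
  stopifnot(target > 0.3, target < 1)
  pair <- function(mu1, s1, mu2, s2) {
    c2 <- cfg
    c2$plexuses$gclp <- plexus_spec("GCLP", layer = "GCIPL",
                                    center_frac = mu1, spread_frac = s1,
                                    areal_fraction = areal,
                                    radius_px = cfg$plexuses$gclp$radius_px)
    c2$plexuses$icp <- plexus_spec("ICP", layer = "GCIPL",
                                   center_frac = mu2, spread_frac = s2,
                                   areal_fraction = areal,
                                   radius_px = cfg$plexuses$icp$radius_px)
    c2
  }
  if (target < 0.8) {
    h <- min(0.35, target - 0.25, 1.10 - target)
    out <- pair(target - h, 0.10, target + h, 0.10)
  } else {
    icp_center <- target + 0.15
    obj <- function(mu)
      tryCatch(planted_watershed_fraction(pair(mu, 0.10, icp_center, 0.05)) -
                 target, error = function(e) NA_real_)
    mus <- seq(target - 0.45, target - 0.20, by = 0.005)
    vals <- vapply(mus, obj, 0)
    ok <- which(is.finite(vals))
    if (!length(ok))
      stop("no GCLP center yields an interior watershed", call. = FALSE)
    best <- ok[which.min(abs(vals[ok]))]
    mu <- mus[best]
    if (best > min(ok) && best < max(ok) &&
        sign(vals[best - 1]) != sign(vals[best + 1]))
      mu <- stats::uniroot(obj, c(mus[best - 1], mus[best + 1]),
                           tol = 1e-5)$root
    out <- pair(mu, 0.10, icp_center, 0.05)
  }
  achieved <- planted_watershed_fraction(out)
  if (abs(achieved - target) > 0.002)
    stop(sprintf("could not place watershed at %.3f (achieved %.3f)",
                 target, achieved), call. = FALSE)
  out
}
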