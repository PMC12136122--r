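#' Analyze one PR-OCTA eye end to end
#'
#' Runs the full quantification chain on a paired structure/flow volume:
#'
#' 1. surface validation; OS eyes are mirrored to canonical OD orientation;
#' 2. projection resolution by axial peak retention;
#' 3. reflectance reference, shared adaptive threshold map, low-signal
#'    exclusion;
#' 4. whole-GCIPL vessel density map and FAZ localization;
#' 5. FAZ-centered polar sector grid (0.5-mm rings, 16 slices, central
#'    1-mm circle excluded);
#' 6. 20 sub-slab VD depth profiles, quadrant-pooled sixth-degree
#'    polynomial fits, peak and watershed localization;
#' 7. anatomic slab metrics: GCLP / SVC / GCC / GCIPL / NFL thickness and
#'    vessel density (GCLP and SVC both with and without projection
#'    resolution).
#'
#' @param volume A [scan_volume()].
#' @param surfaces The matching [surface_set()].
#' @param params A [vd_params()].
#' @param n_subslabs Number of GCIPL sub-slabs for the depth profile.
#' @param gclp_fraction Posterior GCLP boundary (GCIPL depth fraction).
#' @param dr_mm,n_theta,r_inner_mm Sector grid geometry.
#' @param include_partial Use partial (corner) ring sectors in the
#'   watershed fits.
#' @param apply_pr Set `FALSE` to bypass projection resolution everywhere
#'   (the `--no-pr` mode of the comparison experiments).
#' @return An `eye_analysis` list; see Details.
#' @details The returned list contains `watershed` (a
#'   `watershed_analysis`), `profiles`, `grid`, `faz_center_px`,
#'   `threshold`, `exclusion`, `maps` (named en face maps: GCIPL VD, slab
#'   thickness and VD maps), `slab_vd` (data frame with VD with/without
#'   PR per slab over the sector annulus), and `sector_tables`.
#' @export
analyze_eye <- function(volume, surfaces, params = vd_params(),
                        n_subslabs = 20L, gclp_fraction = 0.75,
                        dr_mm = 0.5, n_theta = 16L, r_inner_mm = 0.5,
                        include_partial = FALSE, apply_pr = TRUE) {
  stopifnot(inherits(volume, "scan_volume"))
  if (volume$laterality == "OS") {
    volume <- mirror_horizontal(volume)
    surfaces <- mirror_horizontal(surfaces)
  }
  validate_surfaces(surfaces, volume)
  sp <- volume$lateral_spacing_mm
  n <- dim(volume$flow)[1]

  pr <- resolve_projection(volume, noise_floor = params$pr_noise_floor)
  flow_used <- if (apply_pr) pr$pr_flow else volume$flow
  ref <- reflectance_reference(volume, surfaces, params)
  thr <- adaptive_threshold_map(ref, params)
  excl <- low_signal_exclusion(ref, params)

  gcipl <- gcipl_fraction_slab(surfaces, 0, 1, name = "GCIPL")
  gcipl_mask <- binarize(enface_max_projection(flow_used, gcipl, sp), thr)
  gcipl_vd <- vessel_density_map(gcipl_mask, params)
  faz <- find_faz_center(gcipl_vd)
  grid <- build_polar_grid(faz, n, lateral_spacing_mm = sp,
                           dr_mm = dr_mm, n_theta = n_theta,
                           r_inner_mm = r_inner_mm)

  profiles <- subslab_vd_profiles(flow_used, surfaces, grid, params,
                                  threshold = thr, exclusion = excl,
                                  n = n_subslabs)
  watershed <- aggregate_quadrants(profiles,
                                   include_partial = include_partial)

  defs <- lapply(stats::setNames(nm = c("GCLP", "SVC", "GCC", "GCIPL", "NFL")),
                 slab_definition, gclp_fraction = gclp_fraction)
  slabs <- lapply(defs, resolve_slab, s = surfaces)
  thick <- lapply(slabs, thickness_map,
                  axial_spacing_um = volume$axial_spacing_um,
                  lateral_spacing_mm = sp)

  region <- enface_map((!is.na(grid$sector_id_map)) + 0, kind = "mask",
                       lateral_spacing_mm = sp)
  slab_vd <- do.call(rbind, lapply(c("GCLP", "SVC"), function(nm) {
    m_pr <- binarize(enface_max_projection(pr$pr_flow, slabs[[nm]], sp), thr)
    m_raw <- binarize(enface_max_projection(volume$flow, slabs[[nm]], sp), thr)
    data.frame(slab = nm,
               vd_with_pr = vd_in_region(m_pr, region, excl),
               vd_without_pr = vd_in_region(m_raw, region, excl))
  }))
  rownames(slab_vd) <- NULL

  vd_maps <- lapply(stats::setNames(nm = c("GCLP", "SVC")), function(nm) {
    m <- binarize(enface_max_projection(flow_used, slabs[[nm]], sp), thr)
    vessel_density_map(m, params)
  })

  sector_tables <- list(
    gcipl_vd = sector_means(gcipl_vd, grid, excl),
    gclp_vd = sector_means(vd_maps$GCLP, grid, excl),
    svc_vd = sector_means(vd_maps$SVC, grid, excl),
    nfl_thickness = sector_means(thick$NFL, grid, excl),
    gcipl_thickness = sector_means(thick$GCIPL, grid, excl),
    gcc_thickness = sector_means(thick$GCC, grid, excl))

  structure(list(
    watershed = watershed, profiles = profiles, grid = grid,
    faz_center_px = as.numeric(faz),
    threshold = thr, exclusion = excl,
    maps = c(list(gcipl_vd = gcipl_vd), vd_maps,
             stats::setNames(thick, paste0(tolower(names(thick)),
                                           "_thickness"))),
    slab_vd = slab_vd,
    sector_tables = sector_tables,
    params = params,
    laterality = volume$laterality
  ), class = "eye_analysis")
}

#' @export
print.eye_analysis <- function(x, ...) {
  cat("PR-OCTA eye analysis\n")
  if (!is.null(x$watershed$overall))
    cat(sprintf("  watershed at %.1f%% GCIPL depth, peak at %.1f%%\n",
                100 * x$watershed$overall$trough_fraction,
                100 * x$watershed$overall$peak_fraction))
  v <- x$slab_vd
  for (i in seq_len(nrow(v)))
    cat(sprintf("  %s VD: %.1f%% (%.1f%% without PR)\n", v$slab[i],
                100 * v$vd_with_pr[i], 100 * v$vd_without_pr[i]))
  invisible(x)
}

#' Write an eye analysis to CSV (and optional TIFF) files
#'
#' Emits the depth profiles, quadrant and sector extrema, sector tables,
#' and the slab VD summary as CSV; optionally the en face maps as
#' normalized TIFFs. Output is deterministic for a deterministic analysis.
#'
#' @param analysis An `eye_analysis`.
#' @param dir Output directory (created if needed).
#' @param tiff Also write TIFF maps.
#' @return `dir`, invisibly.
#' @export
write_eye_report <- function(analysis, dir, tiff = FALSE) {
  stopifnot(inherits(analysis, "eye_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pr <- analysis$profiles
  long <- data.frame(
    depth_fraction = rep(pr$depth_fractions, times = nrow(pr$sectors)),
    sector_id = rep(pr$sectors$sector_id, each = length(pr$depth_fractions)),
    quadrant = rep(pr$sectors$quadrant, each = length(pr$depth_fractions)),
    vd = as.vector(pr$vd))
  utils::write.csv(long, file.path(dir, "depth_profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$watershed$quadrant_table,
                   file.path(dir, "quadrant_extrema.csv"), row.names = FALSE)
  utils::write.csv(analysis$watershed$sector_table,
                   file.path(dir, "sector_extrema.csv"), row.names = FALSE)
  utils::write.csv(analysis$slab_vd, file.path(dir, "slab_vd.csv"),
                   row.names = FALSE)
  for (nm in names(analysis$sector_tables))
    utils::write.csv(analysis$sector_tables[[nm]],
                     file.path(dir, paste0("sectors_", nm, ".csv")),
                     row.names = FALSE)
  if (tiff)
    for (nm in names(analysis$maps))
      write_enface(analysis$maps[[nm]],
                   path_tiff = file.path(dir, paste0(nm, ".tif")))
  invisible(dir)
}
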