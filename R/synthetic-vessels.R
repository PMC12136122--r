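plexus_codes <- c(NFLP = 1L, GCLP = 2L, ICP = 3L, DCP = 4L)

rtruncnorm1 <- function(mu, s, lo, hi) {
  u <- stats::runif(1, stats::pnorm((lo - mu) / s), stats::pnorm((hi - mu) / s))
  mu + s * stats::qnorm(u)
}

disc_offsets <- function(radius_px) {
  g <- expand.grid(dx = -radius_px:radius_px, dy = -radius_px:radius_px)
  g[g$dx^2 + g$dy^2 <= radius_px^2, , drop = FALSE]
}

#' Plant capillary plexuses into a phantom eye
#'
#' Populates four capillary plexuses as randomly oriented in-plane
#' capillary segments at plexus-specific depths: the NFLP inside the NFL
#' (absent where the NFL is thinner than `nflp_min_nfl_um`, with areal
#' density scaled by local NFL thickness and segments following arcuate
#' nerve-fiber directions), the GCLP and ICP at truncated-Gaussian depths
#' within the GCIPL, and the DCP in a band below the IPL/INL boundary.
#' No capillaries are planted inside the FAZ except for a merged ring at
#' its border, where the GCIPL plexuses collapse to a single mid-GCIPL
#' depth — the plexuses merge near the FAZ, which is why the central 1-mm
#' circle is excluded from analysis.
#'
#' The ground-truth watershed depth is the brute-force interior minimum of
#' the planted GCIPL axial density ([planted_watershed_fraction()]).
#'
#' @param cfg A [phantom_config()].
#' @param surfaces A [surface_set()] for this eye (possibly jittered).
#' @param require_watershed If `TRUE` (default), a configuration whose
#'   GCIPL plexuses admit no interior density minimum is an error; with
#'   `FALSE` (e.g. single-plexus phantoms) the truth fraction is `NA`.
#' @return A `truth_scene`: integer `label` volume (0 = none, 1 = NFLP,
#'   2 = GCLP, 3 = ICP, 4 = DCP), tail-free `clean_flow` volume,
#'   `true_watershed_fraction`, `faz_center_px` (0-based), and per-plexus
#'   achieved coverage.
#' @export
plant_vessels <- function(cfg, surfaces, require_watershed = TRUE) {
  validate_phantom_config(cfg)
  stopifnot(inherits(surfaces, "surface_set"))
  n <- cfg$grid_n
  nz <- cfg$n_z
  stopifnot(identical(dim(surfaces$ilm_z), c(n, n)))
  true_ws <- if (require_watershed) planted_watershed_fraction(cfg) else {
    tryCatch(planted_watershed_fraction(cfg), error = function(e) NA_real_)
  }

  set.seed(cfg$seed + 1L)
  sp <- lateral_spacing_mm(cfg)
  ax <- cfg$axial_spacing_um
  pol <- fovea_polar(cfg)
  nfl_um <- (surfaces$nflgcl_z - surfaces$ilm_z) * ax
  gcipl_um <- (surfaces$iplinl_z - surfaces$nflgcl_z) * ax
  gcc_um <- nfl_um + gcipl_um
  outer_band_z <- (cfg$layers$inl_um + 30) / ax

  label <- array(0L, c(n, n, nz))
  clean <- array(0, c(n, n, nz))
  npx2 <- as.double(n) * n
  coverage <- numeric(0)

  disc_px <- fovea_center_px(cfg) + c(4.5 / sp, 0) + 1  # 1-based, nasal

  for (p in cfg$plexuses) {
    code <- plexus_codes[[p$name]]
    # GCIPL plexuses extend inward into a merged capillary ring bordering
    # the FAZ (inside the excluded central circle); NFLP/DCP stop at the
    # FAZ radius
    r_min <- if (p$layer == "GCIPL")
      cfg$faz_radius_mm - cfg$merge_ring_mm else cfg$faz_radius_mm
    allowed <- pol$r >= r_min
    if (p$name == "NFLP") allowed <- allowed & (nfl_um >= cfg$nflp_min_nfl_um)
    modul <- matrix(1, n, n)
    if (p$name == "NFLP" && any(allowed)) {
      sc <- stats::quantile(nfl_um[allowed], 0.9)
      modul <- pmin(nfl_um / sc, 1)
    }
    if (p$name == "GCLP" && cfg$gclp_coupling == "gcc")
      modul <- gcc_um / max(gcc_um)
    target <- p$areal_fraction * sum(allowed)
    covered <- matrix(FALSE, n, n)
    ncov <- 0
    off <- disc_offsets(p$radius_px)
    lmin <- max(4, 0.15 / sp)
    lmax <- max(8, 0.45 / sp)
    it <- 0L
    # sample centers in an expanded domain so coverage stays uniform up
    # to the field boundary (segments reaching in from outside count)
    marg <- lmax / 2 + p$radius_px + 1
    while (ncov < target && it < 40000L) {
      it <- it + 1L
      cx <- stats::runif(1, 1 - marg, n + marg)
      cy <- stats::runif(1, 1 - marg, n + marg)
      ang <- if (p$orientation == "arcuate")
        atan2(cy - disc_px[2], cx - disc_px[1]) + stats::rnorm(1, 0, 0.2)
      else stats::runif(1, 0, 2 * pi)
      acc <- modul[pmin(pmax(round(cx), 1), n), pmin(pmax(round(cy), 1), n)]
      if (stats::runif(1) > acc) next
      len <- stats::runif(1, lmin, lmax)
      t <- seq(-len / 2, len / 2, by = 0.6)
      px <- round(rep(cx + t * cos(ang), each = nrow(off)) + off$dx)
      py <- round(rep(cy + t * sin(ang), each = nrow(off)) + off$dy)
      ok <- px >= 1 & px <= n & py >= 1 & py <= n
      if (!any(ok)) next
      idx2 <- unique(px[ok] + (py[ok] - 1L) * n)
      idx2 <- idx2[allowed[idx2]]
      if (!length(idx2)) next
      mu <- p$center_frac
      lo_t <- p$trunc_lo
      hi_t <- p$trunc_hi
      if (!is.null(p$center_frac_temporal)) {
        cth <- pol$theta[pmin(pmax(round(cx), 1), n) +
                           (pmin(pmax(round(cy), 1), n) - 1L) * n]
        if (cth < pi / 4 || cth > 7 * pi / 4) {
          d <- p$center_frac_temporal - mu
          mu <- mu + d; lo_t <- lo_t + d; hi_t <- hi_t + d
        }
      }
      f <- rtruncnorm1(mu, p$spread_frac, lo_t, hi_t)
      fpix <- rep(f, length(idx2))
      if (p$layer == "GCIPL" && cfg$merge_ring_mm > 0) {
        # merged ring: plexus depths collapse to mid-GCIPL at the FAZ border
        fpix[pol$r[idx2] < cfg$faz_radius_mm] <- 0.5
      }
      z0 <- switch(p$layer,
        NFL = surfaces$ilm_z[idx2] +
          fpix * (surfaces$nflgcl_z[idx2] - surfaces$ilm_z[idx2]),
        GCIPL = surfaces$nflgcl_z[idx2] +
          fpix * (surfaces$iplinl_z[idx2] - surfaces$nflgcl_z[idx2]),
        OUTER = surfaces$iplinl_z[idx2] + fpix * outer_band_z)
      # one axial voxel per capillary pixel: the flow response of a
      # capillary at this axial sampling is a single peaked voxel, and
      # fractional surfaces dither the rounding across columns; rounding
      # must not push a capillary's voxel center above its host layer's
      # anterior surface (capillaries stay inside their layer)
      layer_top <- switch(p$layer,
        NFL = surfaces$ilm_z, GCIPL = surfaces$nflgcl_z,
        OUTER = surfaces$iplinl_z)[idx2]
      z <- pmax(round(z0), ceiling(layer_top))
      z <- pmin(pmax(z, 0), nz - 1)
      lin <- idx2 + z * npx2
      v <- stats::runif(1, cfg$flow_range[1], cfg$flow_range[2])
      sel <- clean[lin] < v
      if (any(sel)) {
        clean[lin[sel]] <- v
        label[lin[sel]] <- code
      }
      new <- idx2[!covered[idx2]]
      covered[new] <- TRUE
      ncov <- ncov + length(new)
    }
    coverage[p$name] <- ncov / max(sum(allowed), 1)
  }

  structure(list(label = label, clean_flow = clean,
                 true_watershed_fraction = true_ws,
                 faz_center_px = fovea_center_px(cfg),
                 coverage = coverage),
            class = "truth_scene")
}

#' @export
print.truth_scene <- function(x, ...) {
  d <- dim(x$label)
  cat(sprintf("Phantom truth scene: %d x %d x %d voxels, %d vessel voxels\n",
              d[1], d[2], d[3], sum(x$label > 0L)))
  cat(sprintf("  planted watershed fraction: %s\n",
              if (is.na(x$true_watershed_fraction)) "NA"
              else sprintf("%.3f", x$true_watershed_fraction)))
  cat(sprintf("  coverage: %s\n",
              paste(sprintf("%s %.2f", names(x$coverage), x$coverage),
                    collapse = ", ")))
  invisible(x)
}
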