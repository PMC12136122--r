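#' Construct a vessel density depth profile
#'
#' VD as a function of GCIPL depth fraction, typically at the 20 sub-slab
#' centers `(i + 0.5)/20`.
#'
#' @param depth_fractions Strictly increasing fractions in (0, 1).
#' @param vd_values VD fractions in `[0, 1]`, same length.
#' @param group_label Label of the profile (sector id, quadrant, cohort).
#' @return A `depth_profile`.
#' @export
depth_profile <- function(depth_fractions, vd_values, group_label = "profile") {
  stopifnot(length(depth_fractions) == length(vd_values),
            all(diff(depth_fractions) > 0),
            all(depth_fractions > 0 & depth_fractions < 1))
  if (any(vd_values < 0 | vd_values > 1))
    stop("vd_values must lie in [0,1]", call. = FALSE)
  structure(list(depth_fractions = depth_fractions,
                 vd_values = vd_values,
                 group_label = group_label),
            class = "depth_profile")
}

#' Sub-slab vessel density depth profiles per sector
#'
#' Implements the depth-profiling stage: the GCIPL is divided into `n`
#' equal sub-slabs; each sub-slab's en face maximum projection of the
#' projection-resolved flow is binarized against one shared
#' reflectance-adaptive threshold map, smoothed into a VD map, and
#' averaged per polar sector. The result is one `n`-point profile per
#' sector, with the VD of each sub-slab attributed to its center fraction.
#'
#' @param flow Projection-resolved 3-D flow array (or [scan_volume()],
#'   whose flow is then used as-is).
#' @param surfaces A [surface_set()].
#' @param grid A [build_polar_grid()] sector grid.
#' @param params A [vd_params()].
#' @param threshold Shared threshold [enface_map()]; computed from
#'   `structure_ref` when omitted.
#' @param structure_ref Optional reflectance reference [enface_map()] used
#'   to derive `threshold` and the low-signal exclusion.
#' @param exclusion Optional exclusion [enface_map()].
#' @param n Number of sub-slabs (default 20).
#' @param include_partial Keep partial (corner) ring sectors.
#' @return A `depth_profile_set`: `depth_fractions` (length `n`), `vd`
#'   (`n x n_sectors` matrix), `sectors` (sector metadata data frame), and
#'   the grid.
#' @export
subslab_vd_profiles <- function(flow, surfaces, grid, params = vd_params(),
                                threshold = NULL, structure_ref = NULL,
                                exclusion = NULL, n = 20L,
                                include_partial = TRUE) {
  if (inherits(flow, "scan_volume")) flow <- flow$flow
  if (is.null(threshold)) {
    if (is.null(structure_ref))
      stop("provide either a threshold map or a structure reference",
           call. = FALSE)
    threshold <- adaptive_threshold_map(structure_ref, params)
  }
  subs <- subdivide_gcipl(surfaces, n)
  sp <- surfaces$lateral_spacing_mm
  tables <- lapply(subs, function(sl) {
    ang <- enface_max_projection(flow, sl, lateral_spacing_mm = sp)
    mask <- binarize(ang, threshold)
    vdm <- vessel_density_map(mask, params)
    sector_means(vdm, grid, exclusion, include_partial = include_partial)
  })
  sectors <- tables[[1]][, c("sector_id", "ring_index", "slice_index",
                             "quadrant", "partial", "n_pixels",
                             "n_excluded")]
  vd <- vapply(tables, function(tb) tb$mean_value,
               numeric(nrow(sectors)))
  vd <- t(vd)  # n_subslabs x n_sectors
  structure(list(
    depth_fractions = vapply(subs, attr, 0, "f_center"),
    vd = vd, sectors = sectors, grid = grid, n_subslabs = as.integer(n)
  ), class = "depth_profile_set")
}

#' @export
print.depth_profile_set <- function(x, ...) {
  cat(sprintf("VD depth profiles: %d sub-slabs x %d sectors\n",
              x$n_subslabs, nrow(x$sectors)))
  invisible(x)
}

# evaluate polynomial with ascending coefficients at x (Horner)
eval_poly <- function(coefs, x) {
  y <- rep(coefs[length(coefs)], length(x))
  for (i in rev(seq_len(length(coefs) - 1L))) y <- y * x + coefs[i]
  y
}

#' Least-squares polynomial fit of a depth profile
#'
#' Ordinary least squares of VD on depth fraction with a sixth-degree
#' polynomial (the degree used to model VD versus GCIPL depth).
#'
#' @param p A [depth_profile()], or a list with `depth_fractions` and
#'   `vd_values`.
#' @param degree Polynomial degree (default 6).
#' @return A `poly_fit`: `coefficients` (ascending powers, length
#'   `degree + 1`), `r_squared`, `n_points`, `degenerate` flag (constant
#'   profiles get `r_squared = 0`), and the data.
#' @export
fit_profile <- function(p, degree = 6L) {
  x <- p$depth_fractions
  y <- p$vd_values
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) <= degree + 1L)
    stop(sprintf("need more than %d points for a degree-%d fit",
                 degree + 1L, degree), call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    return(structure(list(
      degree = as.integer(degree),
      coefficients = c(mean(y), rep(0, degree)),
      r_squared = 0, n_points = length(x), degenerate = TRUE,
      x = x, y = y), class = "poly_fit"))
  }
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  beta <- unname(stats::coef(fit))
  beta[is.na(beta)] <- 0
  ssr <- sum(stats::residuals(fit)^2)
  structure(list(degree = as.integer(degree), coefficients = beta,
                 r_squared = 1 - ssr / sst, n_points = length(x),
                 degenerate = FALSE, x = x, y = y),
            class = "poly_fit")
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("Degree-%d polynomial fit: %d points, R^2 = %.3f%s\n",
              x$degree, x$n_points, x$r_squared,
              if (x$degenerate) " (degenerate constant profile)" else ""))
  invisible(x)
}

#' Locate the GCLP peak and the GCLP/ICP watershed on a fitted curve
#'
#' Critical points are the real roots of the fitted polynomial's
#' derivative inside (0, 1). The peak is the interior local maximum with
#' the largest fitted VD; the watershed (trough) is the interior local
#' minimum posterior to the peak with the smallest fitted VD, ties broken
#' toward the deeper root (the watershed separates the GCLP from the ICP,
#' which sits at the IPL/INL border). A 0.001-step grid evaluation
#' cross-checks the root-based extrema.
#'
#' @param fit A `poly_fit` from [fit_profile()].
#' @param grid_step Cross-check grid step.
#' @return A `watershed_result`: `peak_fraction`, `trough_fraction`,
#'   `peak_vd`, `trough_vd`, `fit`.
#' @export
locate_extrema <- function(fit, grid_step = 1e-3) {
  stopifnot(inherits(fit, "poly_fit"))
  if (fit$degenerate)
    stop("no-watershed: degenerate constant profile", call. = FALSE)
  beta <- fit$coefficients
  dcoef <- beta[-1] * seq_len(length(beta) - 1L)
  while (length(dcoef) && dcoef[length(dcoef)] == 0)
    dcoef <- dcoef[-length(dcoef)]
  if (!length(dcoef))
    stop("no-watershed: flat fitted curve", call. = FALSE)
  roots <- polyroot(dcoef)
  re <- Re(roots[abs(Im(roots)) < 1e-8])
  re <- sort(unique(re[re > 0 & re < 1]))
  if (!length(re))
    stop("no-watershed: fitted curve is monotone on (0,1)", call. = FALSE)
  eps <- 1e-6
  is_min <- vapply(re, function(r)
    eval_poly(beta, r - eps) > eval_poly(beta, r) &&
      eval_poly(beta, r + eps) > eval_poly(beta, r), NA)
  is_max <- vapply(re, function(r)
    eval_poly(beta, r - eps) < eval_poly(beta, r) &&
      eval_poly(beta, r + eps) < eval_poly(beta, r), NA)
  maxima <- re[is_max]
  if (!length(maxima))
    stop("no-watershed: no interior local maximum", call. = FALSE)
  # only prominent maxima count as plexus peaks: low-amplitude wiggles of
  # the fit in near-empty depth ranges must not anchor a watershed
  vmaxima <- eval_poly(beta, maxima)
  maxima <- maxima[is.finite(vmaxima) & vmaxima >= 0.2 * max(vmaxima)]
  if (!length(maxima))
    stop("no-watershed: no prominent interior maximum", call. = FALSE)
  # watershed: interior local minimum posterior to a plexus peak, with the
  # smallest fitted VD; ties toward the deeper root. A genuine watershed
  # separates two plexuses, so the curve must rise again posterior to the
  # trough by at least 20% of the anterior peak's height above it —
  # otherwise the minimum is just the tail of a single plexus.
  minima <- re[is_min & re > min(maxima)]
  if (length(minima)) {
    keep <- vapply(minima, function(m) {
      fm <- eval_poly(beta, m)
      ant <- max(eval_poly(beta, maxima[maxima < m]))
      post <- max(eval_poly(beta, c(re[re > m], 1)))
      post - fm >= 0.2 * (ant - fm)
    }, NA)
    minima <- minima[keep]
  }
  if (!length(minima))
    stop("no-watershed: no interior minimum posterior to the peak",
         call. = FALSE)
  vmin <- eval_poly(beta, minima)
  best <- vmin <= min(vmin) + 1e-12
  trough <- max(minima[best])
  # plexus peak: largest fitted VD among maxima anterior to the watershed
  maxima <- maxima[maxima < trough]
  vmax <- eval_poly(beta, maxima)
  peak <- maxima[which.max(vmax)]
  # dense-grid cross-check: same selection applied to grid local minima
  g <- seq(grid_step, 1 - grid_step, by = grid_step)
  gv <- eval_poly(beta, g)
  i_loc <- which(gv < c(-Inf, gv[-length(gv)]) &
                   gv < c(gv[-1], -Inf) & g > min(maxima))
  if (length(i_loc)) {
    keepg <- vapply(i_loc, function(i) {
      post <- max(gv[g >= g[i]], eval_poly(beta, 1))
      ant <- max(gv[g <= g[i]])
      post - gv[i] >= 0.2 * (ant - gv[i])
    }, NA)
    i_loc <- i_loc[keepg]
  }
  gmin <- if (length(i_loc)) {
    cand <- g[i_loc][gv[i_loc] <= min(gv[i_loc]) + 1e-12]
    max(cand)
  } else trough
  if (abs(gmin - trough) > 2 * grid_step)
    warning(sprintf(
      "grid cross-check minimum (%.4f) differs from root-based trough (%.4f)",
      gmin, trough))
  structure(list(peak_fraction = peak,
                 trough_fraction = trough,
                 peak_vd = eval_poly(beta, peak),
                 trough_vd = eval_poly(beta, trough),
                 grid_trough_fraction = gmin,
                 fit = fit),
            class = "watershed_result")
}

#' @export
print.watershed_result <- function(x, ...) {
  cat(sprintf("GCLP/ICP watershed: peak at %.1f%% depth (VD %.3f), trough at %.1f%% depth (VD %.3f)\n",
              100 * x$peak_fraction, x$peak_vd,
              100 * x$trough_fraction, x$trough_vd))
  invisible(x)
}

profile_from_set <- function(ps, cols, label) {
  v <- ps$vd[, cols, drop = FALSE]
  vd <- rowMeans(v, na.rm = TRUE)
  keep <- is.finite(vd)
  depth_profile(ps$depth_fractions[keep], pmin(pmax(vd[keep], 0), 1), label)
}

#' Quadrant-pooled watershed analysis
#'
#' Pools the per-sector depth profiles of each quadrant (mean VD across
#' the quadrant's sectors at each depth), fits the sixth-degree
#' polynomial, and locates the peak and watershed; also fits every sector
#' individually and reports the dispersion of per-sector extrema, and a
#' whole-macula pooled fit.
#'
#' @param profiles A `depth_profile_set` from [subslab_vd_profiles()].
#' @param degree Polynomial degree.
#' @param include_partial Use sectors in partial (corner) rings. Corner
#'   sectors are noisier (field vignetting), so the default drops them.
#' @param min_raw_depth Also report the raw (unfitted) profile minimum
#'   depth per group.
#' @return A `watershed_analysis`: `overall` and per-quadrant
#'   [locate_extrema()] results, a `quadrant_table`, a `sector_table` of
#'   per-sector extrema, and summary statistics (mean and SD of
#'   per-sector peak/trough).
#' @export
aggregate_quadrants <- function(profiles, degree = 6L,
                                include_partial = FALSE,
                                min_raw_depth = TRUE) {
  stopifnot(inherits(profiles, "depth_profile_set"))
  sec <- profiles$sectors
  use <- if (include_partial) rep(TRUE, nrow(sec)) else !sec$partial
  if (!any(use)) stop("no usable sectors", call. = FALSE)
  quads <- c("T", "S", "N", "I")
  fit_one <- function(cols, label) {
    pr <- profile_from_set(profiles, cols, label)
    ws <- tryCatch(locate_extrema(fit_profile(pr, degree)),
                   error = function(e) NULL)
    list(profile = pr, ws = ws)
  }
  overall <- fit_one(which(use), "macula")
  by_quad <- lapply(quads, function(q) {
    cols <- which(use & sec$quadrant == q)
    if (!length(cols)) return(NULL)
    fit_one(cols, q)
  })
  names(by_quad) <- quads
  qtab <- do.call(rbind, lapply(quads, function(q) {
    b <- by_quad[[q]]
    if (is.null(b) || is.null(b$ws))
      return(data.frame(quadrant = q, peak_fraction = NA_real_,
                        trough_fraction = NA_real_, peak_vd = NA_real_,
                        trough_vd = NA_real_, r_squared = NA_real_,
                        raw_min_fraction = NA_real_))
    raw <- if (min_raw_depth)
      b$profile$depth_fractions[which.min(b$profile$vd_values)]
    else NA_real_
    data.frame(quadrant = q,
               peak_fraction = b$ws$peak_fraction,
               trough_fraction = b$ws$trough_fraction,
               peak_vd = b$ws$peak_vd, trough_vd = b$ws$trough_vd,
               r_squared = b$ws$fit$r_squared,
               raw_min_fraction = raw)
  }))
  sector_ext <- do.call(rbind, lapply(which(use), function(j) {
    pr <- profile_from_set(profiles, j,
                           as.character(sec$sector_id[j]))
    ws <- tryCatch(locate_extrema(fit_profile(pr, degree)),
                   error = function(e) NULL)
    data.frame(sector_id = sec$sector_id[j], quadrant = sec$quadrant[j],
               peak_fraction = if (is.null(ws)) NA_real_ else ws$peak_fraction,
               trough_fraction = if (is.null(ws)) NA_real_ else ws$trough_fraction)
  }))
  structure(list(
    overall = overall$ws,
    overall_profile = overall$profile,
    quadrants = lapply(by_quad, function(b) if (is.null(b)) NULL else b$ws),
    quadrant_profiles = lapply(by_quad, function(b)
      if (is.null(b)) NULL else b$profile),
    quadrant_table = qtab,
    sector_table = sector_ext,
    summary = list(
      mean_peak = mean(sector_ext$peak_fraction, na.rm = TRUE),
      sd_peak = stats::sd(sector_ext$peak_fraction, na.rm = TRUE),
      mean_trough = mean(sector_ext$trough_fraction, na.rm = TRUE),
      sd_trough = stats::sd(sector_ext$trough_fraction, na.rm = TRUE))
  ), class = "watershed_analysis")
}

#' @export
print.watershed_analysis <- function(x, ...) {
  cat("Watershed analysis (GCIPL depth fractions)\n")
  if (!is.null(x$overall))
    cat(sprintf("  macula: peak %.3f, watershed %.3f (fit R^2 %.2f)\n",
                x$overall$peak_fraction, x$overall$trough_fraction,
                x$overall$fit$r_squared))
  print(x$quadrant_table, digits = 3)
  cat(sprintf("  per-sector trough: %.3f +/- %.3f (n = %d)\n",
              x$summary$mean_trough, x$summary$sd_trough,
              sum(is.finite(x$sector_table$trough_fraction))))
  invisible(x)
}

#' Plot VD depth profiles with their polynomial fits
#'
#' Scatter of sector-pooled VD against GCIPL depth fraction per quadrant,
#' with the fitted sixth-degree curves and the located extrema.
#'
#' @param x A `watershed_analysis`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.watershed_analysis <- function(x, ...) {
  cols <- c(T = "#D55E00", S = "#0072B2", N = "#009E73", I = "#CC79A7")
  prs <- Filter(Negate(is.null), x$quadrant_profiles)
  ylim <- range(unlist(lapply(prs, `[[`, "vd_values")))
  plot(NA, xlim = c(0, 1), ylim = ylim,
       xlab = "GCIPL depth fraction", ylab = "Vessel density (fraction)",
       main = "VD vs depth by quadrant", ...)
  g <- seq(0.01, 0.99, by = 0.005)
  for (q in names(prs)) {
    p <- prs[[q]]
    points(p$depth_fractions, p$vd_values, col = cols[q], pch = 16,
           cex = 0.7)
    ws <- x$quadrants[[q]]
    if (!is.null(ws)) {
      lines(g, eval_poly(ws$fit$coefficients, g), col = cols[q])
      abline(v = ws$trough_fraction, col = cols[q], lty = 3)
    }
  }
  legend("topright", legend = names(prs), col = cols[names(prs)],
         pch = 16, bty = "n")
  invisible(x)
}
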