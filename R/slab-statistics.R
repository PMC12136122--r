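#' Named anatomic slab definitions
#'
#' Standard slabs expressed as surface anchors, resolvable against any
#' [surface_set()]:
#' * `GCIPL`: NFL/GCL to IPL/INL.
#' * `GCLP`: NFL/GCL to 75% GCIPL depth (the ganglion cell layer plexus;
#'   its posterior boundary is the GCLP/ICP watershed).
#' * `SVC`: ILM to 75% GCIPL depth (superficial vascular complex =
#'   NFLP + GCLP).
#' * `GCC`: ILM to IPL/INL (ganglion cell complex).
#' * `NFL`: ILM to NFL/GCL.
#'
#' @param name One of `"GCLP"`, `"SVC"`, `"GCC"`, `"GCIPL"`, `"NFL"`.
#' @param gclp_fraction Posterior GCLP boundary as a GCIPL depth fraction
#'   (default 0.75).
#' @return A `slab_definition`.
#' @export
slab_definition <- function(name = c("GCLP", "SVC", "GCC", "GCIPL", "NFL"),
                            gclp_fraction = 0.75) {
  name <- match.arg(name)
  def <- switch(name,
    GCIPL = list(top = list(surface = "nflgcl_z"),
                 bottom = list(surface = "iplinl_z")),
    GCLP = list(top = list(surface = "nflgcl_z"),
                bottom = list(gcipl_fraction = gclp_fraction)),
    SVC = list(top = list(surface = "ilm_z"),
               bottom = list(gcipl_fraction = gclp_fraction)),
    GCC = list(top = list(surface = "ilm_z"),
               bottom = list(surface = "iplinl_z")),
    NFL = list(top = list(surface = "ilm_z"),
               bottom = list(surface = "nflgcl_z")))
  structure(c(list(name = name), def), class = "slab_definition")
}

resolve_anchor <- function(anchor, s) {
  if (!is.null(anchor$surface)) {
    if (!anchor$surface %in% c("ilm_z", "nflgcl_z", "iplinl_z"))
      stop("unknown surface anchor: ", anchor$surface, call. = FALSE)
    return(s[[anchor$surface]])
  }
  if (!is.null(anchor$gcipl_fraction))
    return(s$nflgcl_z +
             anchor$gcipl_fraction * (s$iplinl_z - s$nflgcl_z))
  stop("unknown slab anchor", call. = FALSE)
}

#' Resolve a slab definition against surfaces
#'
#' @param def A [slab_definition()].
#' @param s A [surface_set()].
#' @return A [slab()].
#' @export
resolve_slab <- function(def, s) {
  stopifnot(inherits(def, "slab_definition"), inherits(s, "surface_set"))
  slab(resolve_anchor(def$top, s), resolve_anchor(def$bottom, s),
       name = def$name)
}

#' Boundary depth difference: 80% GCC versus 75% GCIPL
#'
#' Signed depth difference (micrometres, positive = 80% GCC deeper) between
#' the legacy posterior SVC boundary at 80% of GCC depth and the revised
#' boundary at NFL + 75% of GCIPL depth, both measured from the ILM.
#' Algebraically the difference is `0.05 * GCIPL - 0.2 * NFL`, so the 80%
#' GCC boundary is shallower exactly where the NFL is thicker than a
#' quarter of the GCIPL — the thick nasal arcuate wedges — and deeper
#' elsewhere.
#'
#' @param s A [surface_set()].
#' @return An [enface_map()] (kind `"angiogram"`; signed micrometres).
#' @export
compare_gcc80_gcipl75 <- function(s) {
  stopifnot(inherits(s, "surface_set"))
  ax <- s$axial_spacing_um
  nfl <- (s$nflgcl_z - s$ilm_z) * ax
  gcipl <- (s$iplinl_z - s$nflgcl_z) * ax
  d80 <- 0.80 * (nfl + gcipl)
  d75 <- nfl + 0.75 * gcipl
  enface_map(d80 - d75, kind = "angiogram",
             lateral_spacing_mm = s$lateral_spacing_mm)
}

#' Squared Pearson correlation of paired sector means
#'
#' @param x,y Paired numeric vectors (>= 3 finite pairs).
#' @return `r_squared` scalar; `NA` with a warning when either input has
#'   zero variance.
#' @export
pearson_r2 <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("need at least 3 paired sectors", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: r^2 undefined")
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' Two-sided paired t-test
#'
#' @param a,b Paired per-eye values (equal length >= 2).
#' @return List with `t`, `p`, `mean_difference`, `df`, and a `degenerate`
#'   flag set when the paired differences have zero variance but a
#'   non-zero mean (the statistic is unbounded).
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1, mean_difference = 0,
                  df = length(d) - 1L, degenerate = FALSE))
    return(list(t = Inf * sign(mean(d)), p = 0, mean_difference = mean(d),
                df = length(d) - 1L, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_difference = unname(tt$estimate), df = unname(tt$parameter),
       degenerate = FALSE)
}

#' Within-visit repeatability as a coefficient of variation
#'
#' Pooled within-subject SD of paired repeat measurements
#' (`sqrt(mean(d^2 / 2))` over eyes, `d` the repeat difference —
#' the Bland-Altman convention) divided by the grand mean.
#'
#' @param repeat1,repeat2 Per-eye values from the two repeat scans.
#' @return List with `cv`, `within_subject_sd`, `grand_mean`.
#' @export
repeatability_cv <- function(repeat1, repeat2) {
  stopifnot(length(repeat1) == length(repeat2), length(repeat1) >= 1L)
  d <- repeat1 - repeat2
  ws_sd <- sqrt(mean(d^2 / 2))
  gm <- mean(c(repeat1, repeat2))
  if (gm == 0) stop("grand mean is zero: CV undefined", call. = FALSE)
  list(cv = ws_sd / gm, within_subject_sd = ws_sd, grand_mean = gm)
}

#' Bootstrap comparison of two correlations sharing one variable
#'
#' Tests whether `r^2(x, y1)` exceeds `r^2(x, y2)` by resampling sectors
#' with replacement (the significance machinery for "better correlated
#' with" statements).
#'
#' @param x Common variable (e.g. GCLP VD sector means).
#' @param y1,y2 Competing covariates (e.g. GCC and GCIPL thickness).
#' @param n_boot Number of resamples.
#' @param seed RNG seed.
#' @return List with `delta_r2` (observed `r2(x,y1) - r2(x,y2)`), `p`
#'   (one-sided bootstrap probability that the difference is <= 0), and
#'   the two observed `r2` values.
#' @export
compare_r2_bootstrap <- function(x, y1, y2, n_boot = 2000L, seed = 1L) {
  keep <- is.finite(x) & is.finite(y1) & is.finite(y2)
  x <- x[keep]; y1 <- y1[keep]; y2 <- y2[keep]
  r2_1 <- pearson_r2(x, y1)
  r2_2 <- pearson_r2(x, y2)
  set.seed(seed)
  n <- length(x)
  deltas <- replicate(n_boot, {
    i <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[i]) == 0 || stats::sd(y1[i]) == 0 ||
        stats::sd(y2[i]) == 0) return(NA_real_)
    stats::cor(x[i], y1[i])^2 - stats::cor(x[i], y2[i])^2
  })
  list(delta_r2 = r2_1 - r2_2,
       p = mean(deltas <= 0, na.rm = TRUE),
       r2_1 = r2_1, r2_2 = r2_2)
}

#' Pool per-eye en face maps into population mean and SD maps
#'
#' Left-eye (OS) maps are mirrored about the vertical axis to the
#' canonical right-eye orientation before pooling; pixelwise mean and SD
#' maps are returned together with the nasal-versus-temporal contrast of
#' the pooled mean.
#'
#' @param maps List of [enface_map()]s, one per eye, common geometry.
#' @param lateralities Character vector, `"OD"`/`"OS"` per eye.
#' @param center_px Field center used to split nasal/temporal halves
#'   (default: geometric center).
#' @return A `cohort_maps` list: `mean`, `sd` (en face maps), `n_eyes`,
#'   `nasal_mean`, `temporal_mean`, `nasal_temporal_ratio`.
#' @export
population_maps <- function(maps, lateralities,
                            center_px = NULL) {
  stopifnot(length(maps) == length(lateralities), length(maps) >= 2L)
  d <- dim(maps[[1]])
  sp <- attr(maps[[1]], "lateral_spacing_mm")
  kind <- attr(maps[[1]], "kind")
  acc <- matrix(0, d[1], d[2])
  acc2 <- matrix(0, d[1], d[2])
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    if (!identical(dim(m), d))
      stop("geometry mismatch across eyes", call. = FALSE)
    m <- as_matrix(m)
    if (lateralities[i] == "OS") m <- m[d[1]:1, , drop = FALSE]
    acc <- acc + m
    acc2 <- acc2 + m^2
  }
  n <- length(maps)
  mu <- acc / n
  varm <- pmax(acc2 / n - mu^2, 0)
  if (is.null(center_px)) center_px <- (d[1] - 1) / 2
  xs <- seq_len(d[1]) - 1
  nasal <- xs > center_px
  temporal <- xs < center_px
  structure(list(
    mean = enface_map(mu, kind = kind, lateral_spacing_mm = sp),
    sd = enface_map(sqrt(varm * n / max(n - 1, 1)),
                    kind = if (kind == "vd") "angiogram" else kind,
                    lateral_spacing_mm = sp),
    n_eyes = n,
    nasal_mean = mean(mu[nasal, ]),
    temporal_mean = mean(mu[temporal, ]),
    nasal_temporal_ratio = mean(mu[nasal, ]) / mean(mu[temporal, ])
  ), class = "cohort_maps")
}

#' @export
print.cohort_maps <- function(x, ...) {
  cat(sprintf("Cohort maps over %d eyes: grand mean %.4f, mean pixel SD %.4f\n",
              x$n_eyes, mean(x$mean), mean(x$sd)))
  cat(sprintf("  nasal %.4f vs temporal %.4f (ratio %.3f)\n",
              x$nasal_mean, x$temporal_mean, x$nasal_temporal_ratio))
  invisible(x)
}
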