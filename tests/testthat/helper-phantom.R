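# Shared fixtures, built in code. Sizes are chosen so the default suite
# runs in minutes; the acceptance tests use the full 200 x 200 x 320
# phantom resolution.

tiny_cfg <- function(...) {
  phantom_config(grid_n = 80L, n_z = 160L, seed = 11L, ...)
}

small_cfg <- function(...) {
  phantom_config(grid_n = 160L, n_z = 280L, seed = 11L, ...)
}

# constant-thickness, pit-free configuration (parallel-plane surfaces)
flat_cfg <- function(..., gcipl_um = 84) {
  phantom_config(
    grid_n = 80L, n_z = 160L, seed = 11L,
    pit = list(depth_um = 0, radius_mm = 0.75),
    layers = list(pit_collapse_mm = 0, nfl_wedge_um = 0, nfl_base_um = 24,
                  gcipl_floor_um = gcipl_um, gcipl_peak_um = gcipl_um),
    ...)
}

flat_surfaces <- function(n = 10, ilm = 10, nflgcl = 20, iplinl = 40,
                          axial = 3, lateral = 0.015) {
  surface_set(matrix(ilm, n, n), matrix(nflgcl, n, n), matrix(iplinl, n, n),
              axial_spacing_um = axial, lateral_spacing_mm = lateral)
}

# cached default-anatomy eye (two repeats) shared across test files
.cache <- new.env(parent = emptyenv())

cached_small_eye <- function() {
  if (is.null(.cache$eye))
    .cache$eye <- cohort_eye(small_cfg(), 1L, seed = 21L, repeats = 2L)
  .cache$eye
}

cached_small_analysis <- function() {
  if (is.null(.cache$analysis)) {
    eye <- cached_small_eye()
    .cache$analysis <- analyze_eye(eye$volumes[[1]], eye$surfaces)
  }
  .cache$analysis
}

# independent truncated-normal mixture density (oracle; no package code)
oracle_mix_density <- function(f, mus, sds, los, his, amps) {
  d <- rep(0, length(f))
  for (i in seq_along(mus)) {
    z <- (f - mus[i]) / sds[i]
    norm <- pnorm((his[i] - mus[i]) / sds[i]) -
      pnorm((los[i] - mus[i]) / sds[i])
    inside <- f >= los[i] & f <= his[i]
    d[inside] <- d[inside] + amps[i] * dnorm(z[inside]) / (sds[i] * norm)
  }
  d
}
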