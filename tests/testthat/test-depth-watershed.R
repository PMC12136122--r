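# expand polynomial coefficients of s * (x - a)^2 (x - b)^2 + c
two_well_coefs <- function(a, b, s, c) {
  pa <- c(a^2, -2 * a, 1)
  pb <- c(b^2, -2 * b, 1)
  prod <- rep(0, 5)
  for (i in 0:2) for (j in 0:2)
    prod[i + j + 1] <- prod[i + j + 1] + pa[i + 1] * pb[j + 1]
  out <- c(prod * s, 0, 0)
  out[1] <- out[1] + c
  out
}

eval_poly_oracle <- function(beta, x) {
  sapply(x, function(xi) sum(beta * xi^(seq_along(beta) - 1)))
}

test_that("an exact degree-6 profile is interpolated with R^2 = 1", {
  beta <- c(0.2, 0.3, -0.8, 0.5, 0.4, -0.3, 0.1) / 4
  x <- (seq_len(20) - 0.5) / 20
  y <- eval_poly_oracle(beta, x)
  fit <- fit_profile(depth_profile(x, y))
  expect_equal(fit$coefficients, beta, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_false(fit$degenerate)
})

test_that("constant profiles are flagged degenerate with R^2 = 0", {
  x <- (seq_len(20) - 0.5) / 20
  fit <- fit_profile(depth_profile(x, rep(0.3, 20)))
  expect_true(fit$degenerate)
  expect_identical(fit$r_squared, 0)
  expect_equal(fit$coefficients[-1], rep(0, 6))
  expect_error(locate_extrema(fit), "degenerate")
  expect_error(fit_profile(depth_profile(x[1:5], runif(5))), "points")
})

test_that("least squares matches a normal-equations oracle", {
  set.seed(61)
  x <- (seq_len(20) - 0.5) / 20
  X <- outer(x, 0:6, `^`)
  for (i in 1:20) {
    y <- pmin(pmax(0.3 + 0.2 * sin(7 * x + i) + rnorm(20, 0, 0.05), 0), 1)
    fit <- fit_profile(depth_profile(x, y))
    beta_o <- solve(crossprod(X), crossprod(X, y))[, 1]
    ss_o <- sum((y - X %*% beta_o)^2)
    ss_f <- sum((y - eval_poly_oracle(fit$coefficients, x))^2)
    expect_lt(abs(ss_f - ss_o) / max(ss_o, 1e-12), 1e-8)
  }
})

test_that("extrema of a two-well polynomial are recovered analytically", {
  beta <- two_well_coefs(0.3, 0.75, 1, 0.05)
  fit <- structure(list(degree = 6L, coefficients = beta, r_squared = 1,
                        n_points = 20L, degenerate = FALSE),
                   class = "poly_fit")
  ws <- locate_extrema(fit)
  expect_equal(ws$trough_fraction, 0.75, tolerance = 1e-3)
  expect_equal(ws$peak_fraction, (0.3 + 0.75) / 2, tolerance = 1e-3)
  expect_equal(ws$trough_vd, 0.05, tolerance = 1e-9)
})

test_that("monotone fits raise the no-watershed error", {
  x <- (seq_len(20) - 0.5) / 20
  fit <- fit_profile(depth_profile(x, 0.1 + 0.5 * x))
  expect_error(locate_extrema(fit), "no-watershed")
})

test_that("root-based extrema agree with a dense grid-search oracle", {
  grid_oracle <- function(beta) {
    g <- seq(1e-3, 1 - 1e-3, by = 1e-3)
    v <- eval_poly_oracle(beta, g)
    interior_max <- which(v > c(Inf, v[-length(v)]) & v > c(v[-1], Inf))
    interior_min <- which(v < c(-Inf, v[-length(v)]) & v < c(v[-1], -Inf))
    if (!length(interior_max)) return(NULL)
    prom <- interior_max[v[interior_max] >= 0.2 * max(v[interior_max])]
    cand <- interior_min[g[interior_min] > min(g[prom])]
    f1 <- eval_poly_oracle(beta, 1)
    cand <- cand[vapply(cand, function(i) {
      post <- max(v[seq_along(v) >= i], f1)
      ant <- max(v[prom[prom < i]])
      post - v[i] >= 0.2 * (ant - v[i])
    }, NA)]
    if (!length(cand)) return(NULL)
    best <- cand[v[cand] <= min(v[cand]) + 1e-12]
    trough <- max(g[best])
    pk <- prom[g[prom] < trough]
    c(peak = g[pk[which.max(v[pk])]], trough = trough)
  }
  set.seed(62)
  found <- 0
  x <- (seq_len(20) - 0.5) / 20
  for (i in 1:100) {
    # random two-hump profiles of the kind the pipeline fits
    m1 <- runif(1, 0.2, 0.45)
    m2 <- runif(1, 0.8, 1.15)
    s1 <- runif(1, 0.08, 0.2)
    s2 <- runif(1, 0.08, 0.15)
    y <- runif(1, 0.2, 0.5) * dnorm((x - m1) / s1) +
      runif(1, 0.2, 0.5) * dnorm((x - m2) / s2) + runif(1, 0, 0.02)
    y <- pmin(y / max(4 * max(y), 1), 1)
    fit <- fit_profile(depth_profile(x, y))
    ws <- tryCatch(suppressWarnings(locate_extrema(fit)),
                   error = function(e) NULL)
    oracle <- grid_oracle(fit$coefficients)
    if (is.null(ws) || is.null(oracle)) next  # extremum too close to an
    found <- found + 1                        # endpoint for a 1e-3 grid
    expect_lte(abs(ws$trough_fraction - oracle["trough"]), 1e-3)
    expect_lte(abs(ws$peak_fraction - oracle["peak"]), 1e-3)
  }
  expect_gt(found, 20)  # the family yields plenty of two-hump cases
})

test_that("single-plexus phantoms yield no interior trough", {
  cfg <- tiny_cfg(plexuses = list(
    gclp = plexus_spec("GCLP", center_frac = 0.30, spread_frac = 0.15,
                       areal_fraction = 0.35, trunc_lo = 0, trunc_hi = 0.7)),
    noise = list(speckle_sd = 0.1, flow_floor = 0.05))
  eye <- cohort_eye(cfg, 1L, seed = 13L, repeats = 1L,
                    require_watershed = FALSE)
  an <- analyze_eye(eye$volumes[[1]], eye$surfaces)
  # pooled profile: monotone decreasing after its peak, so no watershed
  p <- an$watershed$overall_profile
  pk <- which.max(p$vd_values)
  expect_true(all(diff(p$vd_values[pk:length(p$vd_values)]) <= 0.01))
  expect_null(an$watershed$overall)
})

test_that("two-plexus phantoms produce the expected profile topology", {
  an <- cached_small_analysis()
  eye <- cached_small_eye()
  p <- an$watershed$overall_profile
  v <- p$vd_values
  # two local maxima (GCLP hump and the rising ICP edge) and an interior
  # trough near the planted watershed
  imax <- which(v > c(-Inf, v[-length(v)]) & v >= c(v[-1], -Inf))
  expect_gte(length(imax), 2L)
  truth <- eye$truth$true_watershed_fraction
  expect_lt(abs(an$watershed$overall$trough_fraction - truth), 0.05)
  interior <- which.min(v[6:19]) + 5L
  expect_lt(abs(p$depth_fractions[interior] - truth), 0.06)
})

test_that("zero flow gives an all-zero profile", {
  cfg <- tiny_cfg()
  s <- make_surfaces(cfg)
  flow <- array(0, c(cfg$grid_n, cfg$grid_n, cfg$n_z))
  g <- build_polar_grid(c(39.5, 39.5), cfg$grid_n,
                        lateral_spacing_mm = cfg$lateral_size_mm / cfg$grid_n)
  thr <- enface_map(matrix(0.3, cfg$grid_n, cfg$grid_n), kind = "threshold")
  ps <- subslab_vd_profiles(flow, s, g, vd_params(), threshold = thr)
  expect_true(all(ps$vd == 0))
  expect_identical(dim(ps$vd), c(20L, nrow(ps$sectors)))
})

test_that("quadrant pooling recovers symmetric and planted-contrast depths", {
  # identical plexus depths in all quadrants, homogeneous flat geometry,
  # sharply peaked GCLP, noise off: peak spread < 0.02 by symmetry
  cfg <- phantom_config(
    grid_n = 240L, n_z = 280L, seed = 11L,
    pit = list(depth_um = 0, radius_mm = 0.75),
    layers = list(pit_collapse_mm = 0, nfl_wedge_um = 0, nfl_base_um = 24,
                  gcipl_floor_um = 84, gcipl_peak_um = 84),
    noise = list(speckle_sd = 0, flow_floor = 0),
    jitter = list(thickness_sd = 0, density_sd = 0))
  cfg$plexuses$gclp <- plexus_spec("GCLP", center_frac = 0.30,
                                   spread_frac = 0.10,
                                   areal_fraction = 0.45,
                                   trunc_lo = 0, trunc_hi = 0.7)
  cfg$plexuses$icp <- plexus_spec("ICP", center_frac = 1.00,
                                  spread_frac = 0.08,
                                  areal_fraction = 0.40,
                                  trunc_lo = 0.6, trunc_hi = 1.4)
  eye <- cohort_eye(cfg, 1L, seed = 17L, repeats = 1L)
  an <- analyze_eye(eye$volumes[[1]], eye$surfaces, include_partial = TRUE)
  qt <- an$watershed$quadrant_table
  expect_true(all(is.finite(qt$peak_fraction)))
  expect_lt(diff(range(qt$peak_fraction)), 0.02)
  # pooled and per-sector troughs agree for homogeneous profiles
  expect_lt(abs(mean(qt$trough_fraction) - an$watershed$summary$mean_trough),
            0.01)
  # temporal GCLP planted deeper: quadrant fits recover the contrast
  cfg2 <- small_cfg()
  cfg2$plexuses$gclp <- plexus_spec(
    "GCLP", center_frac = 0.30, spread_frac = 0.15, areal_fraction = 0.35,
    trunc_lo = 0, trunc_hi = 0.75, center_frac_temporal = 0.43)
  eye2 <- cohort_eye(cfg2, 1L, seed = 18L, repeats = 1L)
  an2 <- analyze_eye(eye2$volumes[[1]], eye2$surfaces)
  qt2 <- an2$watershed$quadrant_table
  tpk <- qt2$peak_fraction[qt2$quadrant == "T"]
  others <- qt2$peak_fraction[qt2$quadrant != "T"]
  expect_gt(tpk, max(others) + 0.05)
})
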