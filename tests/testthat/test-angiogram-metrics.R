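test_that("en face max projection obeys the half-open slab rule", {
  flow <- array(0, c(6, 6, 20))
  flow[3, 4, 10] <- 9              # 0-based voxel center z = 9
  sl <- slab(matrix(8, 6, 6), matrix(12, 6, 6))
  proj <- enface_max_projection(flow, sl)
  expect_equal(proj[3, 4], 9)
  expect_equal(sum(proj), 9)
  # voxel at the bottom boundary is excluded (half-open)
  sl2 <- slab(matrix(8, 6, 6), matrix(9, 6, 6))
  expect_equal(enface_max_projection(flow, sl2)[3, 4], 0)
  # ... but included at the top boundary
  sl2b <- slab(matrix(9, 6, 6), matrix(10, 6, 6))
  expect_equal(enface_max_projection(flow, sl2b)[3, 4], 9)
  # zero-thickness columns project to zero
  sl3 <- slab(matrix(10.2, 6, 6), matrix(10.4, 6, 6))
  expect_true(all(enface_max_projection(flow, sl3) == 0))
})

test_that("union slab projection is the voxelwise max of sub-slab projections", {
  set.seed(41)
  flow <- array(runif(8 * 8 * 30), c(8, 8, 30))
  top <- matrix(runif(64, 2, 5), 8)
  mid <- top + matrix(runif(64, 1, 8), 8)
  bot <- mid + matrix(runif(64, 1, 10), 8)
  a <- enface_max_projection(flow, slab(top, mid))
  b <- enface_max_projection(flow, slab(mid, bot))
  u <- enface_max_projection(flow, slab(top, bot))
  expect_equal(unclass(u), pmax(unclass(a), unclass(b)),
               ignore_attr = TRUE)
})

test_that("a slab below all vessels projects to zero after PR (noise off)", {
  cfg <- tiny_cfg(noise = list(speckle_sd = 0, flow_floor = 0))
  s <- make_surfaces(cfg)
  scene <- plant_vessels(cfg, s)
  v <- render_volumes(scene, s, cfg)
  pr <- resolve_projection(v)
  deep_top <- s$iplinl_z + (cfg$layers$inl_um + 60) / cfg$axial_spacing_um
  deep <- slab(deep_top, deep_top + 20)
  expect_true(all(enface_max_projection(pr$pr_flow, deep) == 0))
  # without PR the same slab carries projected tails
  expect_gt(max(enface_max_projection(v$flow, deep)), 0)
})

test_that("reflectance reference is the slab mean and scales with shadows", {
  vol <- array(2.5, c(6, 6, 60))
  s <- flat_surfaces(n = 6, ilm = 5, nflgcl = 10, iplinl = 20, axial = 3)
  ref <- reflectance_reference(vol, s, vd_params(ref_extent_um = 60))
  expect_true(all(abs(ref - 2.5) < 1e-12))
  vol2 <- vol
  vol2[2, 3, ] <- vol2[2, 3, ] * 0.1
  ref2 <- reflectance_reference(vol2, s, vd_params(ref_extent_um = 60))
  expect_equal(ref2[2, 3], 0.25)
  expect_equal(ref2[1, 1], 2.5)
})

test_that("adaptive threshold is linear in the reference", {
  ref <- enface_map(matrix(runif(36), 6), kind = "angiogram")
  p <- vd_params(threshold_slope = 0.4, threshold_offset = 0.07)
  thr <- adaptive_threshold_map(ref, p)
  expect_equal(unclass(thr), 0.07 + 0.4 * unclass(ref), ignore_attr = TRUE)
  # slope 0 degenerates to a global threshold
  thr0 <- adaptive_threshold_map(ref, vd_params(threshold_slope = 0,
                                                threshold_offset = 0.2))
  expect_true(all(thr0 == 0.2))
  # doubling the reference doubles threshold minus offset
  ref2 <- enface_map(2 * unclass(ref), kind = "angiogram")
  thr2 <- adaptive_threshold_map(ref2, p)
  expect_equal(unclass(thr2) - 0.07, 2 * (unclass(thr) - 0.07),
               ignore_attr = TRUE)
})

test_that("binarization is strict and geometry-checked", {
  a <- enface_map(matrix(c(0, 1, 2, 3), 2), kind = "angiogram")
  t1 <- enface_map(matrix(2, 2, 2), kind = "threshold")
  expect_equal(as.vector(binarize(a, t1)), c(0, 0, 0, 1))
  # ties go to background
  t2 <- enface_map(matrix(c(0, 1, 2, 3), 2), kind = "threshold")
  expect_true(all(binarize(a, t2) == 0))
  expect_error(binarize(a, enface_map(matrix(1, 3, 3), kind = "threshold")),
               "mismatch")
})

test_that("vessel density map is a mean-preserving moving average", {
  p <- vd_params(lowpass_kernel_px = 5)
  ones <- enface_map(matrix(1, 9, 9), kind = "mask")
  expect_true(all(abs(vessel_density_map(ones, p) - 1) < 1e-9))
  single <- matrix(0, 21, 21)
  single[11, 11] <- 1
  vdm <- vessel_density_map(enface_map(single, kind = "mask"), p)
  expect_equal(vdm[11, 11], 1 / 25, tolerance = 1e-9)
  expect_equal(vdm[11, 13], 1 / 25, tolerance = 1e-9)
  expect_equal(vdm[11, 14], 0, tolerance = 1e-9)
  # interior-supported mask: global mean preserved exactly
  set.seed(42)
  m <- matrix(0, 30, 30)
  m[8:22, 8:22] <- rbinom(225, 1, 0.4)
  vdm2 <- vessel_density_map(enface_map(m, kind = "mask"), p)
  expect_equal(mean(vdm2), mean(m), tolerance = 1e-9)
})

test_that("low-signal exclusion flags floater shadows found in the truth", {
  p <- vd_params(low_signal_cutoff = 0)
  ref <- enface_map(matrix(runif(100, 0.1, 1), 10), kind = "angiogram")
  expect_true(all(low_signal_exclusion(ref, p) == 0))
  cfg <- tiny_cfg(floater = list(center_mm = c(1, -1), radius_mm = 0.5,
                                 attenuation = 0.9))
  s <- make_surfaces(cfg)
  scene <- plant_vessels(cfg, s)
  v <- render_volumes(scene, s, cfg)
  ref2 <- reflectance_reference(v, s, vd_params())
  excl <- low_signal_exclusion(ref2, vd_params())
  n <- cfg$grid_n
  sp <- cfg$lateral_size_mm / n
  ax <- (seq_len(n) - 1 - (n - 1) / 2) * sp
  dx <- matrix(ax - 1, n, n)
  dy <- matrix(ax + 1, n, n, byrow = TRUE)
  inside <- dx^2 + dy^2 <= (0.4)^2    # margin inside the disc
  outside <- dx^2 + dy^2 >= (0.7)^2
  expect_gt(mean(excl[inside]), 0.95)
  expect_lt(mean(excl[outside]), 0.05)
})

test_that("regional VD equals an exhaustive pixel count", {
  set.seed(43)
  mask <- matrix(rbinom(100, 1, 0.5), 10)
  region <- matrix(rbinom(100, 1, 0.7), 10)
  excl <- matrix(rbinom(100, 1, 0.2), 10)
  got <- vd_in_region(enface_map(mask, kind = "mask"),
                      enface_map(region, kind = "mask"),
                      enface_map(excl, kind = "exclusion"))
  num <- den <- 0
  for (i in 1:10) for (j in 1:10)
    if (region[i, j] == 1 && excl[i, j] == 0) {
      den <- den + 1
      num <- num + mask[i, j]
    }
  expect_equal(got, num / den, tolerance = 1e-12)
  expect_equal(vd_in_region(enface_map(matrix(1, 4, 4), kind = "mask"),
                            enface_map(matrix(1, 4, 4), kind = "mask")), 1)
  expect_error(vd_in_region(enface_map(mask, kind = "mask"),
                            enface_map(matrix(0, 10, 10), kind = "mask")),
               "missing-data")
})

test_that("joint rescaling of structure and flow leaves masks unchanged at offset 0", {
  cfg <- tiny_cfg()
  s <- make_surfaces(cfg)
  scene <- plant_vessels(cfg, s)
  v <- render_volumes(scene, s, cfg)
  p0 <- vd_params(threshold_offset = 0)
  sl <- gcipl_fraction_slab(s, 0, 0.75)
  mask_of <- function(scale) {
    ref <- reflectance_reference(v$structure * scale, s, p0)
    thr <- adaptive_threshold_map(ref, p0)
    binarize(enface_max_projection(v$flow * scale, sl,
                                   lateral_spacing_mm = v$lateral_spacing_mm),
             thr)
  }
  expect_identical(unclass(mask_of(1)), unclass(mask_of(3.7)))
})

test_that("reflectance compensation preserves detection inside shadows", {
  # single-plexus phantom: the slab maximum at a vessel pixel is that
  # vessel's own flow, so the threshold contrast is interpretable
  cfg <- small_cfg(floater = list(center_mm = c(1.2, -1.2), radius_mm = 0.6,
                                  attenuation = 0.5),
                   flow_range = c(0.55, 1.0),
                   plexuses = list(
                     gclp = plexus_spec("GCLP", center_frac = 0.30,
                                        spread_frac = 0.15,
                                        areal_fraction = 0.25,
                                        trunc_lo = 0, trunc_hi = 0.7)))
  s <- make_surfaces(cfg)
  scene <- plant_vessels(cfg, s, require_watershed = FALSE)
  v <- render_volumes(scene, s, cfg)
  pr <- resolve_projection(v)
  params <- vd_params()
  ref <- reflectance_reference(v, s, params)
  sl <- gcipl_fraction_slab(s, 0, 1)
  ang <- enface_max_projection(pr$pr_flow, sl,
                               lateral_spacing_mm = v$lateral_spacing_mm)
  gclp_px <- apply(scene$label == 2L, c(1, 2), any)
  n <- cfg$grid_n
  sp <- cfg$lateral_size_mm / n
  ax <- (seq_len(n) - 1 - (n - 1) / 2) * sp
  dx <- matrix(ax - 1.2, n, n)
  dy <- matrix(ax + 1.2, n, n, byrow = TRUE)
  inside <- dx^2 + dy^2 <= 0.5^2
  outside <- dx^2 + dy^2 >= 0.8^2
  sens <- function(mask, where) mean(mask[gclp_px & where])
  # compensated: adaptive threshold follows the attenuated reference
  m_comp <- binarize(ang, adaptive_threshold_map(ref, params))
  gap_comp <- sens(m_comp, outside) - sens(m_comp, inside)
  # uncompensated: global threshold calibrated on unshadowed reference
  glob <- vd_params(threshold_slope = 0,
                    threshold_offset = params$threshold_offset +
                      params$threshold_slope * median(ref[outside]))
  m_glob <- binarize(ang, adaptive_threshold_map(ref, glob))
  gap_glob <- sens(m_glob, outside) - sens(m_glob, inside)
  expect_lt(abs(gap_comp), 0.05)
  expect_gt(gap_glob, 0.20)
})
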