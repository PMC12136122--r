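test_that("polar grid bins are half-open and partition the annulus", {
  # pixel at exactly r = 0.5 mm falls in ring 0
  n <- 201
  sp <- 0.01
  center <- c(100, 100)  # 0-based
  g <- build_polar_grid(center, n, lateral_spacing_mm = sp)
  expect_identical(g$sector_id_map[151, 101] %/% g$n_theta, 0L)  # dx = 0.5 mm
  # brute-force oracle over every pixel
  for (px in list(c(151, 101), c(100, 30), c(7, 190))) {
    dx <- (px[1] - 1 - center[1]) * sp
    dy <- (px[2] - 1 - center[2]) * sp
    r <- sqrt(dx^2 + dy^2)
    if (r < 0.5) {
      expect_true(is.na(g$sector_id_map[px[1], px[2]]))
    } else {
      theta <- atan2(dy, -dx) %% (2 * pi)
      expect_identical(
        g$sector_id_map[px[1], px[2]],
        as.integer(floor((r - 0.5) / 0.5) * 16 +
                     min(floor(16 * theta / (2 * pi)), 15)))
    }
  }
  # disjoint cover: every in-annulus pixel has exactly one id
  ax <- (seq_len(n) - 1 - center[1]) * sp
  rmat <- sqrt(outer(ax^2, ax^2, "+"))
  expect_identical(!is.na(g$sector_id_map), rmat >= 0.5)
  tab <- table(g$sector_id_map)
  expect_identical(sum(tab), sum(rmat >= 0.5))
})

test_that("a 6-mm field holds 5 full rings; corners are partial rings", {
  g <- build_polar_grid(c(199.5, 199.5), 400, lateral_spacing_mm = 6 / 400)
  expect_identical(g$n_full_rings, 5L)
  expect_true(all(g$partial[g$ring >= 5]))
  expect_false(any(g$partial[g$ring < 5]))
  # brute-force pixel count of ring 0 (0.5 <= r < 1.0 mm)
  ax <- (seq_len(400) - 1 - 199.5) * 6 / 400
  r <- sqrt(outer(ax^2, ax^2, "+"))
  expect_identical(sum(table(g$sector_id_map[r >= 0.5 & r < 1.0])),
                   sum(r >= 0.5 & r < 1.0))
  # corner pixels beyond the inscribed circle keep their true ring
  corner_ring <- g$sector_id_map[1, 1] %/% 16L
  expect_identical(corner_ring, as.integer(floor((r[1, 1] - 0.5) / 0.5)))
  # r_outer cuts the grid
  g3 <- build_polar_grid(c(199.5, 199.5), 400, lateral_spacing_mm = 6 / 400,
                         r_outer_mm = 3.0)
  expect_true(all(is.na(g3$sector_id_map[r >= 3.0])))
})

test_that("quadrants are 90-degree wedges centered on the axes", {
  g <- build_polar_grid(c(100, 100), 201, lateral_spacing_mm = 0.01)
  q <- setNames(g$quadrant, g$slice)[as.character(0:15)]
  expect_identical(unname(q[c("15", "0", "1")]), c("T", "T", "T"))
  expect_identical(unname(q[c("3", "4", "5")]), c("S", "S", "S"))
  expect_identical(unname(q[c("7", "8", "9")]), c("N", "N", "N"))
  expect_identical(unname(q[c("11", "12", "13")]), c("I", "I", "I"))
  # nasal pixels (+x) land in N sectors
  id <- g$sector_id_map[180, 101]
  expect_identical(g$quadrant[match(id, g$sector_ids)], "N")
})

test_that("sector means match an exhaustive per-pixel loop", {
  n <- 41
  g <- build_polar_grid(c(20, 20), n, lateral_spacing_mm = 0.05)
  set.seed(51)
  vals <- matrix(runif(n * n), n)
  excl <- matrix(rbinom(n * n, 1, 0.15), n)
  tb <- sector_means(enface_map(vals, kind = "angiogram",
                                lateral_spacing_mm = 0.05),
                     g, enface_map(excl, kind = "exclusion",
                                   lateral_spacing_mm = 0.05))
  sums <- cnts <- setNames(numeric(nrow(tb)), tb$sector_id)
  exc <- setNames(numeric(nrow(tb)), tb$sector_id)
  tot <- setNames(numeric(nrow(tb)), tb$sector_id)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    id <- g$sector_id_map[i, j]
    if (is.na(id)) next
    key <- as.character(id)
    tot[key] <- tot[key] + 1
    if (excl[i, j] == 1) { exc[key] <- exc[key] + 1; next }
    sums[key] <- sums[key] + vals[i, j]
    cnts[key] <- cnts[key] + 1
  }
  expect_equal(tb$n_pixels, unname(as.integer(tot)))
  expect_equal(tb$n_excluded, unname(as.integer(exc)))
  expect_equal(tb$mean_value,
               unname(ifelse(cnts > 0, sums / cnts, NA_real_)),
               tolerance = 1e-12)
  # constant map: every sector mean is the constant
  tb2 <- sector_means(enface_map(matrix(0.37, n, n), kind = "angiogram",
                                 lateral_spacing_mm = 0.05), g)
  expect_true(all(abs(tb2$mean_value - 0.37) < 1e-12))
  # map = ring index: sector mean equals its ring
  ringmap <- matrix(NA_real_, n, n)
  ringmap[!is.na(g$sector_id_map)] <-
    g$sector_id_map[!is.na(g$sector_id_map)] %/% 16
  ringmap[is.na(ringmap)] <- 0
  tb3 <- sector_means(enface_map(ringmap, kind = "angiogram",
                                 lateral_spacing_mm = 0.05), g)
  expect_equal(tb3$mean_value, tb3$ring_index, tolerance = 1e-12)
})

test_that("rotating map and grid by a quarter turn permutes sector means", {
  n <- 81
  g <- build_polar_grid(c(40, 40), n, lateral_spacing_mm = 0.025)
  set.seed(52)
  vals <- matrix(runif(n * n), n)
  tb <- sector_means(enface_map(vals, kind = "angiogram",
                                lateral_spacing_mm = 0.025), g)
  # rotate the map 90 degrees counter-clockwise (x' = -y, y' = x)
  rot <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    rot[41 - (j - 41), 41 + (i - 41)] <- vals[i, j]
  tbr <- sector_means(enface_map(rot, kind = "angiogram",
                                 lateral_spacing_mm = 0.025), g)
  # an in-plane quarter turn shifts the slice index by n_theta/4 (the
  # angle runs from the temporal axis, so the shift is -4 slices here)
  shifted <- (tb$slice_index - 4L) %% 16L + tb$ring_index * 16L
  expect_equal(tbr$mean_value[match(shifted, tbr$sector_id)],
               tb$mean_value, tolerance = 1e-12)
})

test_that("mirrored (OS) analysis matches with temporal and nasal swapped", {
  n <- 80
  center <- c(39.3, 39.5)
  sp <- 0.03
  set.seed(53)
  vals <- matrix(runif(n * n), n)
  g <- build_polar_grid(center, n, lateral_spacing_mm = sp)
  tb <- sector_means(enface_map(vals, kind = "angiogram",
                                lateral_spacing_mm = sp), g)
  gm <- build_polar_grid(c(n - 1 - center[1], center[2]), n,
                         lateral_spacing_mm = sp)
  tbm <- sector_means(enface_map(vals[n:1, ], kind = "angiogram",
                                 lateral_spacing_mm = sp), gm)
  # x-flip maps slice s to (23 - s) mod 16 (theta -> pi - theta)
  mirrored <- tb$ring_index * 16L + (23L - tb$slice_index) %% 16L
  got <- tbm$mean_value[match(mirrored, tbm$sector_id)]
  expect_equal(got, tb$mean_value, tolerance = 1e-12)
  # quadrant labels: T <-> N, S and I fixed
  qm <- tbm$quadrant[match(mirrored, tbm$sector_id)]
  swap <- c(T = "N", N = "T", S = "S", I = "I")
  expect_identical(qm, unname(swap[tb$quadrant]))
})

test_that("FAZ center is recovered from the whole-GCIPL VD map", {
  an <- cached_small_analysis()
  eye <- cached_small_eye()
  expect_lt(max(abs(an$faz_center_px - eye$truth$faz_center_px)), 3)
  # offset fovea
  cfg <- phantom_config(grid_n = 140L, n_z = 240L, seed = 11L,
                        fovea_offset_mm = c(0.3, 0))
  eye2 <- cohort_eye(cfg, 1L, seed = 33L, repeats = 1L)
  an2 <- analyze_eye(eye2$volumes[[1]], eye2$surfaces)
  truth2 <- eye2$truth$faz_center_px
  if (eye2$laterality == "OS") truth2[1] <- (cfg$grid_n - 1) - truth2[1]
  expect_lt(max(abs(an2$faz_center_px - truth2)), 3)
  # fully vascular map falls back to scan center
  full <- enface_map(matrix(0.9, 100, 100), kind = "vd",
                     lateral_spacing_mm = 0.015)
  c0 <- find_faz_center(full)
  expect_true(attr(c0, "fallback"))
  expect_equal(as.numeric(c0), c(49.5, 49.5))
})
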