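test_that("the equal-area projection round-trips and preserves area scale", {
  set.seed(2)
  lat <- 45 + rnorm(20); lon <- -51 + rnorm(20)
  ctr <- c(45, -51)
  xy <- project_laea(lat, lon, ctr)
  back <- unproject_laea(xy$x, xy$y, ctr)
  expect_equal(back$lat, lat, tolerance = 1e-9)
  expect_equal(back$lon, lon, tolerance = 1e-9)
  ## one degree of latitude is ~111 km near the centre
  p <- project_laea(c(45, 46), c(-51, -51), ctr)
  expect_equal(diff(p$y), 111.2, tolerance = 0.5)
})

test_that("UD mass is exactly 1 and LSCV matches a brute-force scan", {
  set.seed(14)
  pts <- data.frame(lat = 45 + rnorm(200, sd = 1.2), lon = -51 + rnorm(200, sd = 1.6))
  ud <- fit_kernel_ud(pts, grid_km = 50)
  expect_equal(sum(ud$z), 1, tolerance = 1e-6)
  ## dense scan of the LSCV score: chosen bandwidth within one grid step
  xy <- project_laea(pts$lat, pts$lon, c(mean(pts$lat), mean(pts$lon)))
  d2 <- as.numeric(dist(xy))^2
  attr(d2, "n") <- nrow(xy)
  h_ref <- sqrt((var(xy$x) + var(xy$y)) / 2) * nrow(xy)^(-1 / 6)
  dense <- exp(seq(log(0.1 * h_ref), log(3 * h_ref), length.out = 400))
  scores <- vapply(dense, murrelog:::lscv_score, numeric(1), d2 = d2)
  h_star <- dense[which.min(scores)]
  step <- exp(diff(log(c(0.1, 3) * h_ref)) / 29)
  expect_lt(max(ud$bandwidth_km / h_star, h_star / ud$bandwidth_km), step * 1.01)
})

test_that("a Gaussian UD's 50% core area matches the closed form", {
  ## ten coincident points smoothed at h = 100 km form an exact
  ## bivariate normal with sigma = 100 km
  pts <- data.frame(lat = rep(45, 10), lon = rep(-51, 10))
  ud <- fit_kernel_ud(pts, grid_km = 50, bandwidth = 100)
  core <- core_contour(ud, 0.5)
  analytic <- 2 * pi * 100^2 * log(2)
  expect_lt(abs(core$area_km2 - analytic) / analytic, 0.1)
  ## nested property and full support at level 1
  expect_lt(core$area_km2, core_contour(ud, 0.95)$area_km2)
  full <- core_contour(ud, 1)
  expect_equal(full$area_km2, length(ud$x) * length(ud$y) * ud$cell_km^2)
})

test_that("core area grows with bandwidth for a tight cluster", {
  pts <- data.frame(lat = rep(45, 12), lon = rep(-51, 12))
  a1 <- core_contour(fit_kernel_ud(pts, 50, bandwidth = 80), 0.5)$area_km2
  a2 <- core_contour(fit_kernel_ud(pts, 50, bandwidth = 160), 0.5)$area_km2
  expect_lt(a1, a2)
})

test_that("directional overlap handles identity, disjoint and nested cores", {
  grid <- expand.grid(x = seq(25, by = 50, length.out = 10),
                      y = seq(25, by = 50, length.out = 10))
  f <- core_area(grid[1:20, ], 50)
  expect_equal(overlap_hr(f, f), list(hr_fm = 1, hr_mf = 1, mean_overlap = 1,
                                      intersection_km2 = 20 * 2500))
  far <- grid[41:60, ]; far$x <- far$x + 2000
  expect_equal(overlap_hr(f, core_area(far, 50))$mean_overlap, 0)
  ## male core (10 cells) strictly inside female core (20 cells)
  m <- core_area(grid[1:10, ], 50)
  ov <- overlap_hr(f, m)
  expect_equal(ov$hr_fm, 0.5)
  expect_equal(ov$hr_mf, 1.0)
  expect_equal(ov$mean_overlap, 0.75)
  ## intersection is symmetric; directions differ only via denominators
  ov2 <- overlap_hr(m, f)
  expect_equal(ov$intersection_km2, ov2$intersection_km2)
  expect_error(overlap_hr(f, core_area(grid[0, ], 50)), "empty")
})

test_that("the UD is invariant to point order and input translation", {
  set.seed(6)
  pts <- data.frame(lat = 45 + rnorm(60, sd = 0.8), lon = -51 + rnorm(60, sd = 1))
  ud1 <- fit_kernel_ud(pts, 50, bandwidth = 90)
  ud2 <- fit_kernel_ud(pts[sample(60), ], 50, bandwidth = 90)
  expect_equal(ud1$z, ud2$z)
  ## translating all points moves the UD but not the core area
  shifted <- data.frame(lat = pts$lat + 2, lon = pts$lon + 3)
  a1 <- core_contour(fit_kernel_ud(pts, 50, bandwidth = 90), 0.5)$area_km2
  a2 <- core_contour(fit_kernel_ud(shifted, 50, bandwidth = 90), 0.5)$area_km2
  expect_lt(abs(a1 - a2) / a1, 0.05)
})

test_that("core areas export as valid GeoJSON cells", {
  pts <- data.frame(lat = rep(45, 10), lon = rep(-51, 10))
  core <- core_contour(fit_kernel_ud(pts, 50, bandwidth = 100), 0.5)
  path <- tempfile(fileext = ".geojson")
  write_core_geojson(core, path)
  gj <- jsonlite::read_json(path)
  expect_identical(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), nrow(core$cells))
})
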