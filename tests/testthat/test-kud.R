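test_that("tangent-plane projection is accurate and invertible", {
  org <- c(158.3, -19.87)
  p0 <- project_points(data.frame(lon = org[1], lat = org[2], depth_m = 500),
                       org)
  expect_equal(unname(p0), matrix(c(0, 0, 0.5), 1), tolerance = 1e-12)

  north <- project_points(data.frame(lon = org[1], lat = org[2] + 1,
                                     depth_m = 0), org)
  expect_equal(unname(north[1, "y"]), 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(unname(north[1, "x"]), 0)

  # round trip at ~500 km
  pts <- data.frame(lon = org[1] + c(4, -4.5), lat = org[2] + c(2, -3),
                    depth_m = c(100, 900))
  back <- unproject_points(project_points(pts, org), org)
  expect_equal(back$lon, pts$lon, tolerance = 1e-9)
  expect_equal(back$lat, pts$lat, tolerance = 1e-9)
  # projected distance vs great-circle distance agrees within 0.1%
  d_true <- haversine_km(org[1], org[2], pts$lon[1], pts$lat[1])
  xy <- project_points(pts, org)
  d_proj <- sqrt(xy[1, "x"]^2 + xy[1, "y"]^2)
  expect_lt(abs(d_proj - d_true) / d_true, 0.001)
})

test_that("fitted density integrates to one and validates input", {
  set.seed(1)
  p <- matrix(rnorm(5000 * 3), ncol = 3)
  k <- fit_kud(p, grid_n = 48)
  expect_equal(sum(k$density) * k$cell_km3, 1, tolerance = 1e-6)

  expect_error(fit_kud(p[1:5, ]), "at least 10")
  expect_error(fit_kud(matrix(1, 100, 3)), "zero variance")
  # a single degenerate axis is floored, not fatal
  p2 <- cbind(rnorm(100), rnorm(100), 0.02)
  expect_s3_class(fit_kud(p2, "normal_scale", grid_n = 16), "kud3d")
})

test_that("volume contours are nested, monotone, and cover the grid limit", {
  set.seed(2)
  k <- fit_kud(matrix(rnorm(2000 * 3), ncol = 3), "normal_scale", grid_n = 32)
  v <- volume_contour(k, c(0.2, 0.5, 0.95, 0.999))
  expect_true(all(diff(v$volume_km3) > 0))
  expect_true(all(diff(v$threshold) < 0))
  grid_vol <- length(k$density) * k$cell_km3
  expect_lt(v$volume_km3[4], grid_vol)
  expect_gt(v$volume_km3[4], v$volume_km3[3])
  expect_error(volume_contour(k, 1.2), "mass")
})

test_that("KDE scale equivariance: scaling points by c scales volumes by c^3", {
  set.seed(3)
  p <- matrix(rnorm(2000 * 3), ncol = 3)
  v1 <- kud_volumes(p, mass = 0.95, bandwidth_method = "normal_scale",
                    grid_n = 32)
  v2 <- kud_volumes(2 * p, mass = 0.95, bandwidth_method = "normal_scale",
                    grid_n = 32)
  expect_equal(v2$volume_km3 / v1$volume_km3, 8, tolerance = 0.05)
})

test_that("duplicating every point leaves the density surface unchanged", {
  set.seed(4)
  p <- matrix(rnorm(500 * 3), ncol = 3)
  h <- c(0.3, 0.3, 0.3)
  k1 <- fit_kud(p, grid_n = 24, h = h)
  k2 <- fit_kud(rbind(p, p), grid_n = 24, h = h)
  expect_equal(k2$density, k1$density, tolerance = 1e-12)
})

test_that("translation shifts the contour but not its volume", {
  set.seed(5)
  p <- matrix(rnorm(1500 * 3), ncol = 3)
  shift <- matrix(rep(c(100, -50, 0.3), each = 1500), ncol = 3)
  v1 <- kud_volumes(p, mass = 0.95, bandwidth_method = "normal_scale",
                    grid_n = 32)
  v2 <- kud_volumes(p + shift, mass = 0.95, bandwidth_method = "normal_scale",
                    grid_n = 32)
  k <- fit_kud(p, "normal_scale", grid_n = 32)
  expect_lt(abs(v2$volume_km3 - v1$volume_km3), 2 * k$cell_km3)
})

test_that("predict interpolates the fitted surface", {
  set.seed(6)
  p <- matrix(rnorm(2000 * 3), ncol = 3)
  k <- fit_kud(p, "normal_scale", grid_n = 32)
  d_at_mode <- predict(k, matrix(0, 1, 3))
  d_far <- predict(k, matrix(c(50, 50, 50), 1, 3))
  expect_gt(d_at_mode, 0.01)
  expect_equal(d_far, 0)  # outside the padded grid
})

test_that("print, summary and plot methods run", {
  set.seed(7)
  k <- fit_kud(matrix(rnorm(600), ncol = 3), "normal_scale", grid_n = 16)
  expect_output(print(k), "kernel utilisation")
  expect_output(print(summary(k, mass = c(0.5, 0.95))), "95% volume")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(k))
})
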