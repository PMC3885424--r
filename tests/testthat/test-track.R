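shelf_grid <- function() {
  # shallow 100 m shelf west of 158.5, deep 2000 m basin east of it
  make_bathymetry(c(158, 159, -20.2, -19.8), 4, function(lon, lat)
    ifelse(lon < 158.5, 100, 2000))
}

test_that("bathymetric correction relocates only implausible points", {
  bg <- shelf_grid()
  trk <- data.frame(tag_id = "T", date = as.Date("2010-09-01") + 0:2,
                    lon = c(158.2, 158.2, 158.8), lat = -20,
                    max_daily_depth_m = c(0, 1136, 1136),
                    stringsAsFactors = FALSE)
  out <- bathymetric_correct(trk, bg, search_radius_km = 60)
  # consistent points unchanged
  expect_false(out$corrected[1])
  expect_equal(out$lon[1], 158.2)
  expect_false(out$corrected[3])
  # shelf point with a 1136 m dive relocates east into the basin
  expect_true(out$corrected[2])
  expect_gt(out$lon[2], 158.45)
  ij <- coraltrack:::locate_cell(bg, out$lon[2], out$lat[2])
  expect_gte(bg$depth_m[ij[1], ij[2]], 1136)
  expect_lte(out$displacement_km[2], 60)
})

test_that("correction flags infeasible points and is idempotent", {
  bg <- make_bathymetry(c(158, 159, -20.2, -19.8), 4,
                        function(lon, lat) rep(100, length(lon)))
  trk <- data.frame(lon = 158.5, lat = -20, max_daily_depth_m = 1136)
  out <- bathymetric_correct(trk, bg, 60)
  expect_true(out$infeasible)
  expect_equal(out$lon, 158.5)  # not moved

  bg2 <- shelf_grid()
  trk2 <- data.frame(lon = c(158.2, 158.9), lat = -20,
                     max_daily_depth_m = c(800, 800))
  once <- bathymetric_correct(trk2, bg2, 60)
  twice <- bathymetric_correct(once[c("lon", "lat", "max_daily_depth_m")],
                               bg2, 60)
  expect_equal(twice$lon, once$lon)
  expect_false(any(twice$corrected))

  # zero dive depth everywhere: nothing changes
  none <- bathymetric_correct(data.frame(lon = 158.2, lat = -20,
                                         max_daily_depth_m = 0), bg2, 60)
  expect_false(none$corrected)

  expect_error(bathymetric_correct(data.frame(lon = 170, lat = -20,
                                              max_daily_depth_m = 10),
                                   bg2, 60), "outside")
})

test_that("confidence radii cap the relocation search", {
  bg <- shelf_grid()
  trk <- data.frame(lon = 158.05, lat = -20, max_daily_depth_m = 1136,
                    ci_radius_km = 5)
  out <- bathymetric_correct(trk, bg, search_radius_km = 100)
  expect_true(out$infeasible)  # basin is ~47 km away, beyond the 5 km CI
})

test_that("displacement from release is an order-free maximum", {
  rel <- c(158.3, -19.87)
  expect_equal(displacement_from_release(
    data.frame(lon = rel[1], lat = rel[2]), rel), 0)

  # straight meridional transit of 1141 km
  lat_end <- rel[2] - 1141 / (6371 * pi / 180)
  trk <- data.frame(lon = rel[1], lat = seq(rel[2], lat_end, length.out = 50))
  expect_equal(displacement_from_release(trk, rel), 1141, tolerance = 0.01)
  set.seed(2)
  expect_equal(displacement_from_release(trk[sample(50), ], rel),
               displacement_from_release(trk, rel))

  expect_error(displacement_from_release(trk[0, ], rel), "non-empty")
})

test_that("depth-temperature summaries use half-metre modal bins", {
  s <- data.frame(depth_m = rep(40, 10), temp_c = rep(25, 10))
  out <- depth_temp_summary(s)
  expect_equal(out$max_depth_m, 40)
  expect_equal(out$modal_depth_m, 40)
  expect_equal(out$mean_depth_m, 40)

  # two-mode series dominated by the 40 m shallow mode
  set.seed(5)
  shallow <- rnorm(800, 40, 0.1)
  deep <- runif(100, 200, 600)
  out2 <- depth_temp_summary(data.frame(depth_m = c(shallow, deep),
                                        temp_c = 20))
  expect_equal(out2$modal_depth_m, 40)

  # ties resolve to the shallowest bin
  out3 <- depth_temp_summary(data.frame(depth_m = c(10, 10, 30, 30),
                                        temp_c = c(20, 20, 21, 21)))
  expect_equal(out3$modal_depth_m, 10)
  expect_equal(out3$modal_temp_c, 20)

  expect_error(depth_temp_summary(s[0, ]), "non-empty")
})

test_that("summary statistics match direct recomputation and ignore order", {
  set.seed(9)
  for (rep in 1:5) {
    d <- runif(1000, 0, 1200)
    tc <- runif(1000, 4, 30)
    s <- data.frame(depth_m = d, temp_c = tc)
    out <- depth_temp_summary(s)
    expect_equal(out$mean_depth_m, mean(d))
    expect_equal(out$max_temp_c, max(tc))
    expect_equal(out$min_temp_c, min(tc))
    expect_true(out$min_temp_c <= out$mean_temp_c &&
                  out$mean_temp_c <= out$max_temp_c)
    expect_equal(depth_temp_summary(s[sample(1000), ]), out)
  }
})
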