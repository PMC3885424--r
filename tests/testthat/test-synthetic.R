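test_that("identical seed and config give bit-identical output", {
  cfg <- sim_config(seed = 3, duration_days = 10, regime = "transient",
                    argos_n_outliers = 2)
  s1 <- simulate_telemetry(cfg)
  s2 <- simulate_telemetry(cfg)
  expect_identical(s1$truth$steps, s2$truth$steps)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$argos, s2$argos)
  expect_identical(s1$depth, s2$depth)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(duration_days = -1), "duration_days")
  expect_error(sim_config(step_minutes = 0), "step_minutes")
  expect_error(sim_config(detection_range_m = c(900, 800)), "detection_range_m")
  expect_error(sim_config(tag_delay_s = c(10, 20)), "tag_delay_s")
  expect_error(sim_config(detection_p_at_half_range = 1.2), "half_range")
})

test_that("a zero step-length resident walk stays at the release point", {
  cfg <- sim_config(seed = 5, duration_days = 2, step_len_km = 0,
                    regime = "resident")
  tr <- simulate_track(cfg)
  expect_true(all(tr$steps$x_km == 0))
  expect_true(all(tr$steps$y_km == 0))
  expect_true(all(is.finite(tr$steps$lon)))
})

test_that("resident sharks stay near the array centre", {
  frac_near <- vapply(1:20, function(s) {
    tr <- simulate_track(sim_config(seed = s, duration_days = 432,
                                    regime = "resident"))
    mean(sqrt(tr$steps$x_km^2 + tr$steps$y_km^2) <= 25)
  }, numeric(1))
  expect_gte(mean(frac_near), 0.90)
})

test_that("passers-by never re-enter detection range after day 30", {
  for (s in 1:5) {
    cfg <- sim_config(seed = s, duration_days = 120, regime = "passer_by")
    tr <- simulate_track(cfg)
    late <- tr$steps[as.numeric(tr$steps$time - cfg$release_time,
                                units = "days") > 30, ]
    rk <- coraltrack:::lonlat_to_km(cfg$receivers$lon, cfg$receivers$lat,
                                    cfg$origin)
    dmin <- Inf
    for (j in seq_len(nrow(rk)))
      dmin <- min(dmin, sqrt((late$x_km - rk[j, 1])^2 +
                               (late$y_km - rk[j, 2])^2))
    expect_gt(dmin * 1000, cfg$detection_range_m[2])
  }
})

test_that("emission intervals respect the transmitter delay bounds", {
  cfg <- sim_config(seed = 9, duration_days = 2, tag_delay_s = c(40, 80))
  tr <- simulate_track(cfg)
  gaps <- diff(tr$emission_s)
  expect_gte(length(gaps), 1000)
  expect_true(all(gaps >= 40 & gaps <= 80))
})

test_that("no detection occurs beyond the maximum detection range", {
  for (s in c(2, 4)) {
    cfg <- sim_config(seed = s, duration_days = 30, regime = "pseudo_resident")
    tr <- simulate_track(cfg)
    det <- simulate_detections(tr)
    em <- attr(det, "emissions")
    hit <- !is.na(em$receiver_id)
    if (!any(hit)) next
    t_s <- as.numeric(tr$steps$time - cfg$release_time, units = "secs")
    es <- as.numeric(em$time[hit] - cfg$release_time, units = "secs")
    ex <- approx(t_s, tr$steps$x_km, xout = es)$y
    ey <- approx(t_s, tr$steps$y_km, xout = es)$y
    rk <- coraltrack:::lonlat_to_km(cfg$receivers$lon, cfg$receivers$lat,
                                    cfg$origin)
    i <- match(em$receiver_id[hit], cfg$receivers$receiver_id)
    d_m <- sqrt((ex - rk[i, 1])^2 + (ey - rk[i, 2])^2) * 1000
    expect_true(all(d_m <= cfg$detection_range_m[2] + 1e-6))
  }
})

test_that("a shark parked on a receiver yields the expected detection count", {
  # stationary at station R01; expected detections/day =
  # 86400 / mean(delay) * p(0)
  counts <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s, duration_days = 1, step_len_km = 0,
                      regime = "resident", tag_delay_s = c(40, 80))
    det <- simulate_detections(simulate_track(cfg))
    sum(det$receiver_id == "R01")
  }, numeric(1))
  cfg <- sim_config(seed = 1, tag_delay_s = c(40, 80))
  expected <- 86400 / 60 * coraltrack:::detection_probability(0, cfg)
  expect_lt(abs(mean(counts) - expected) / expected, 0.10)
})

test_that("sharks far from every receiver are never detected", {
  cfg <- sim_config(seed = 6, duration_days = 1, step_len_km = 0,
                    regime = "resident")
  # receiver array 10 km away from the (stationary) shark
  far <- make_receivers(coraltrack:::km_to_lonlat(10, 0, cfg$origin)[1, ],
                        cfg$release_time, duration_days = 2)
  det <- simulate_detections(simulate_track(cfg), receivers = far)
  expect_equal(nrow(det), 0)
})

test_that("argos error scales shape the displacement distribution", {
  # zero error -> fixes equal true positions exactly
  cfg0 <- sim_config(seed = 8, duration_days = 30,
                     argos_error_m = c(`3` = 0, `2` = 0, `1` = 0, `0` = 0,
                                       A = 0, B = 0))
  a0 <- simulate_argos(simulate_track(cfg0))
  tru <- attr(a0, "truth")
  nz <- a0$loc_class != "Z"
  expect_equal(a0$lon[nz], tru$true_lon[nz])
  expect_equal(a0$lat[nz], tru$true_lat[nz])

  # class-3-only fixes with 250 m scale: median displacement is the
  # Rayleigh median, inside [150, 350] m
  cfg3 <- sim_config(seed = 8, duration_days = 400, argos_fixes_per_day = 3,
                     argos_class_probs = c(`3` = 1))
  a3 <- simulate_argos(simulate_track(cfg3))
  tru3 <- attr(a3, "truth")
  expect_gte(nrow(a3), 1000)
  disp_m <- haversine_km(a3$lon, a3$lat, tru3$true_lon, tru3$true_lat) * 1000
  expect_gt(median(disp_m), 150)
  expect_lt(median(disp_m), 350)
})

test_that("injected argos outliers are flagged in the truth sidecar", {
  cfg <- sim_config(seed = 12, duration_days = 60, argos_n_outliers = 5)
  a <- simulate_argos(simulate_track(cfg))
  tru <- attr(a, "truth")
  expect_equal(sum(tru$outlier), 5)
  disp <- haversine_km(a$lon[tru$outlier], a$lat[tru$outlier],
                       tru$true_lon[tru$outlier], tru$true_lat[tru$outlier])
  expect_true(all(disp > 400))
  expect_true(all(a$loc_class[tru$outlier] == "B"))
})

test_that("dive-profile generator honours its depth bounds", {
  cfg <- sim_config(seed = 4, duration_days = 5,
                    dive = list(deep_rate_per_day = 0))
  z <- simulate_depth_series(cfg)
  expect_lte(max(z$depth_m), cfg$dive$shallow_max_m)
  expect_gte(min(z$depth_m), 0)

  # point-mass deep-dive depth reproduces an exact maximum
  cfg2 <- sim_config(seed = 4, duration_days = 10,
                     dive = list(deep_depth_fixed_m = 1136))
  z2 <- simulate_depth_series(cfg2)
  expect_equal(max(z2$depth_m), 1136)
})

test_that("temperature decreases monotonically with depth up to sensor noise", {
  cfg <- sim_config(seed = 4, duration_days = 10)
  z <- simulate_depth_series(cfg)
  dv <- cfg$dive
  mu <- dv$surface_temp_c -
    (dv$surface_temp_c - dv$deep_temp_c) * z$depth_m / (z$depth_m + 300)
  expect_lt(sd(z$temp_c - mu), 2 * dv$temp_noise_sd)
  expect_lt(cor(z$depth_m, z$temp_c), -0.5)
})

test_that("synthetic bathymetry grids evaluate the seafloor function", {
  const <- make_bathymetry(c(158, 159, -20, -19), 10,
                           function(lon, lat) rep(2000, length(lon)))
  expect_true(all(const$depth_m == 2000))

  shelf <- make_bathymetry(c(158, 159, -20, -19), 5,
                           function(lon, lat) 1 + 1999 * (lon - 158))
  mid <- shelf$depth_m[which.min(abs(shelf$lon - 158.5)), 1]
  expect_lt(abs(mid - 1000), 60)

  ridge <- make_bathymetry(c(158, 159, -20, -19), 5,
                           function(lon, lat) 100 + 1900 * abs(lat + 19.5))
  shallowest <- apply(ridge$depth_m, 1, which.min)
  expect_true(all(shallowest == which.min(abs(ridge$lat + 19.5))))

  expect_error(make_bathymetry(c(158, 159, -20, -19), 10,
                               function(lon, lat) rep(NaN, length(lon))),
               "non-finite")
})

test_that("write_simulation emits readable files plus truth sidecars", {
  dir <- withr::local_tempdir()
  sim <- simulate_telemetry(sim_config(seed = 2, duration_days = 10,
                                       argos_n_outliers = 1))
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("detections.csv", "receivers.csv", "tags.csv", "argos.csv",
      "depth.csv", "truth_steps.csv", "truth_argos.csv")))))
  ts <- read.csv(file.path(dir, "truth_steps.csv"))
  expect_equal(nrow(ts), nrow(sim$truth$steps))
})
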