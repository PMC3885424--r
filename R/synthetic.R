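# Synthetic telemetry generator. Emulates the observation process of a
# combined acoustic/satellite shark-tagging study: multi-regime movement
# around a receiver array, transmitter duty cycles, finite acoustic
# detection range, Argos class-dependent position error, and two-mode dive
# behaviour. Every simulated dataset carries its ground truth so downstream
# estimators can be checked against known answers.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic telemetry generator with validation.
#' Defaults describe a shark tagged on an isolated oceanic reef array and
#' monitored for 432 days: a 7-receiver lagoon array, V16-style transmitter
#' (50-130 s pulse delay, 696-day battery), 400-800 m detection range, and
#' Argos error scales of 250/500/1500 m for classes 3/2/1 and 3 km for
#' classes 0/A/B.
#'
#' @param seed integer RNG seed; every `simulate_*` call derives its stream
#'   from it, so identical config + seed gives bit-identical output.
#' @param duration_days positive integer monitoring span.
#' @param step_minutes movement time step (minutes).
#' @param regime one of `"resident"`, `"pseudo_resident"`, `"transient"`,
#'   `"passer_by"`.
#' @param attraction mean-reversion strength toward the current activity
#'   centre, per step, in \[0, 1).
#' @param step_len_km step-length scale (km) of the random-walk innovation.
#' @param persistence directional persistence of the velocity process in
#'   \[0, 1).
#' @param origin c(lon, lat) of the array centre (release point).
#' @param receivers receiver table (see [make_receivers()]); `NULL` builds
#'   the default 7-station array around `origin`.
#' @param detection_range_m c(min, max) acoustic detection range in metres.
#' @param detection_p_at_half_range detection probability at half the
#'   maximum range, in (0, 1).
#' @param tag_delay_s c(min, max) transmitter pulse delay in seconds; must
#'   be one of the three manufacturer configurations (50-130, 40-80,
#'   30-90).
#' @param argos_error_m named vector of per-axis position error scales (m)
#'   for classes 3, 2, 1, 0, A, B.
#' @param argos_class_probs named mixture over location classes (includes
#'   Z, which carries no coordinates).
#' @param argos_fixes_per_day mean surfacing fixes per day.
#' @param argos_n_outliers number of injected implausible (500 km off
#'   track, class B) fixes, for filter testing.
#' @param dive list of dive-profile parameters: `shallow_mean_m`,
#'   `shallow_sd_m`, `shallow_max_m`, `deep_rate_per_day`,
#'   `deep_depth_min_m`, `deep_depth_max_m`, `deep_depth_fixed_m` (optional
#'   point mass), `max_depth_m`, `dive_duration_min`, `sample_interval_s`,
#'   `surface_temp_c`, `deep_temp_c`, `temp_noise_sd`.
#' @param tag_id tag identifier stamped on simulated records.
#' @param release_time POSIXct release instant (UTC).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       duration_days = 432L,
                       step_minutes = 10,
                       regime = c("resident", "pseudo_resident",
                                  "transient", "passer_by"),
                       attraction = 0.05,
                       step_len_km = 0.4,
                       persistence = 0.6,
                       origin = c(158.3, -19.87),
                       receivers = NULL,
                       detection_range_m = c(400, 800),
                       detection_p_at_half_range = 0.5,
                       tag_delay_s = c(50, 130),
                       argos_error_m = c(`3` = 250, `2` = 500, `1` = 1500,
                                         `0` = 3000, A = 3000, B = 3000),
                       argos_class_probs = c(`3` = 0.10, `2` = 0.15, `1` = 0.20,
                                             `0` = 0.15, A = 0.15, B = 0.20,
                                             Z = 0.05),
                       argos_fixes_per_day = 3,
                       argos_n_outliers = 0L,
                       dive = list(),
                       tag_id = "SIM1",
                       release_time = as.POSIXct("2010-08-12 00:00:00",
                                                 tz = "UTC")) {
  regime <- match.arg(regime)
  if (!is.numeric(duration_days) || duration_days <= 0)
    stop_ct("duration_days must be a positive number")
  if (!is.numeric(step_minutes) || step_minutes <= 0)
    stop_ct("step_minutes must be positive")
  if (detection_range_m[1] > detection_range_m[2] || any(detection_range_m <= 0))
    stop_ct("detection_range_m must satisfy 0 < min <= max")
  if (tag_delay_s[1] >= tag_delay_s[2])
    stop_ct("tag_delay_s must satisfy min < max")
  key <- paste(tag_delay_s[1], tag_delay_s[2])
  if (!key %in% paste(TAG_CONFIGS$delay_min_s, TAG_CONFIGS$delay_max_s))
    stop_ct("tag_delay_s must be one of 50-130, 40-80, 30-90")
  if (detection_p_at_half_range <= 0 || detection_p_at_half_range >= 1)
    stop_ct("detection_p_at_half_range must lie in (0, 1)")
  if (any(argos_error_m < 0)) stop_ct("argos_error_m scales must be >= 0")
  if (attraction < 0 || attraction >= 1) stop_ct("attraction must be in [0, 1)")
  if (persistence < 0 || persistence >= 1) stop_ct("persistence must be in [0, 1)")
  if (step_len_km < 0) stop_ct("step_len_km must be >= 0")
  dive_def <- list(shallow_mean_m = 20, shallow_sd_m = 8, shallow_max_m = 40,
                   deep_rate_per_day = 2, deep_depth_min_m = 200,
                   deep_depth_max_m = 800, deep_depth_fixed_m = NULL,
                   max_depth_m = 1200, dive_duration_min = 45,
                   sample_interval_s = 600, surface_temp_c = 26,
                   deep_temp_c = 4, temp_noise_sd = 0.3)
  dive <- utils::modifyList(dive_def, dive)
  if (dive$deep_rate_per_day < 0 || dive$max_depth_m <= 0 ||
      dive$shallow_max_m <= 0 || dive$sample_interval_s <= 0)
    stop_ct("invalid dive parameters")
  cfg <- structure(list(
    seed = as.integer(seed), duration_days = duration_days,
    step_minutes = step_minutes, regime = regime, attraction = attraction,
    step_len_km = step_len_km, persistence = persistence, origin = origin,
    receivers = receivers, detection_range_m = detection_range_m,
    detection_p_at_half_range = detection_p_at_half_range,
    tag_delay_s = tag_delay_s, argos_error_m = argos_error_m,
    argos_class_probs = argos_class_probs / sum(argos_class_probs),
    argos_fixes_per_day = argos_fixes_per_day,
    argos_n_outliers = as.integer(argos_n_outliers), dive = dive,
    tag_id = tag_id, release_time = release_time), class = "sim_config")
  if (is.null(cfg$receivers))
    cfg$receivers <- make_receivers(origin, release_time,
                                    duration_days = duration_days)
  cfg
}

#' Build a receiver array around an origin
#'
#' Places stations at fixed km offsets from the array centre (a compact
#' lagoon-style layout) with a deployment interval covering the whole
#' simulated monitoring span.
#'
#' @param origin c(lon, lat) array centre.
#' @param release_time deployment reference instant.
#' @param duration_days monitoring span the deployment must cover.
#' @param offsets_km two-column matrix of station offsets (km east, km
#'   north) from the origin.
#' @param array_name array label.
#' @return receiver data.frame in the `receivers.csv` dialect.
#' @export
make_receivers <- function(origin, release_time, duration_days = 432,
                           offsets_km = cbind(c(0, 3, -3, 5, -5, 2, -1),
                                              c(0, 2, 2, -2, -3, -5, 6)),
                           array_name = "SimArray") {
  ll <- km_to_lonlat(offsets_km[, 1], offsets_km[, 2], origin)
  data.frame(receiver_id = sprintf("R%02d", seq_len(nrow(offsets_km))),
             array_name = array_name,
             lon = ll[, "lon"], lat = ll[, "lat"],
             mooring_depth_m = 15,
             deployed_from = release_time - 30 * 86400,
             deployed_to = release_time + (duration_days + 30) * 86400,
             stringsAsFactors = FALSE)
}

# Day-resolution activity schedule for a movement regime. States: "array"
# (station-keeping at the array centre), "away" (excursion to an offshore
# activity centre), "gone" (permanent departure). Bout lengths are drawn
# from the regime's characteristic ranges.
schedule_days <- function(regime, duration_days) {
  D <- ceiling(duration_days)
  states <- character(0)
  if (regime == "resident") {
    states <- rep("array", D)
  } else if (regime == "pseudo_resident") {
    while (length(states) < D)
      states <- c(states, rep("array", round(runif(1, 7, 9))),
                  rep("away", round(runif(1, 20, 24))))
  } else if (regime == "transient") {
    states <- rep("array", 2)
    while (length(states) < D)
      states <- c(states, rep("away", round(runif(1, 40, 75))),
                  rep("array", round(runif(1, 2, 3))))
  } else { # passer_by: leaves the array region permanently within 10 days
    depart <- round(runif(1, 4, 10))
    states <- c(rep("array", depart), rep("gone", D - depart))
  }
  states[seq_len(D)]
}

#' Simulate a movement track with ground truth
#'
#' First-order correlated random walk with mean reversion toward the
#' current activity centre (an Ornstein-Uhlenbeck-style velocity process on
#' a local tangent plane in km). The four regimes differ only in their
#' activity-centre schedule: residents stay on the array; pseudo-residents
#' alternate ~8 days on / ~22 days off; transients revisit briefly after
#' gaps of 40-75 days; passers-by depart permanently within 10 days of
#' release for a centre ~200 km away. Transmitter emission times are a
#' renewal process with intervals uniform on the configured delay interval.
#'
#' @param config a [sim_config()].
#' @return object of class `truth_record`: list with `steps` (data.frame of
#'   per-step time, x/y km, lon/lat, depth, state), `emission_s` (emission
#'   offsets from release, seconds), `regime`, `origin`, `config`.
#' @export
simulate_track <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dt_min <- config$step_minutes
  n <- ceiling(config$duration_days * 1440 / dt_min) + 1L
  day_states <- schedule_days(config$regime, config$duration_days)
  step_day <- pmin(floor((seq_len(n) - 1) * dt_min / 1440) + 1L,
                   length(day_states))
  states <- day_states[step_day]

  # per-run activity centres (km relative to array centre at the origin)
  r <- rle(states)
  centres <- matrix(0, length(r$lengths), 2)
  for (i in seq_along(r$lengths)) {
    s <- r$values[i]
    if (s == "away") {
      th <- runif(1, 0, 2 * pi); d <- runif(1, 35, 60)
      centres[i, ] <- d * c(cos(th), sin(th))
    } else if (s == "gone") {
      th <- runif(1, 0, 2 * pi)
      centres[i, ] <- 200 * c(cos(th), sin(th))
    }
  }

  rho <- config$persistence; kap <- config$attraction
  sig <- config$step_len_km * sqrt(1 - rho^2)  # innovation scale
  x <- numeric(n); y <- numeric(n)
  vx0 <- vy0 <- 0; px <- py <- 0; pos <- 1L
  for (i in seq_along(r$lengths)) {
    len <- r$lengths[i]; cx <- centres[i, 1]; cy <- centres[i, 2]
    vx <- stats::filter(rnorm(len, 0, sig), rho, "recursive", init = vx0)
    vy <- stats::filter(rnorm(len, 0, sig), rho, "recursive", init = vy0)
    # p_t = (1-kap) p_{t-1} + kap*c + v_t
    xx <- stats::filter(kap * cx + as.numeric(vx), 1 - kap, "recursive",
                        init = px)
    yy <- stats::filter(kap * cy + as.numeric(vy), 1 - kap, "recursive",
                        init = py)
    idx <- pos:(pos + len - 1L)
    x[idx] <- xx; y[idx] <- yy
    vx0 <- vx[len]; vy0 <- vy[len]; px <- xx[len]; py <- yy[len]
    pos <- pos + len
  }
  x <- c(0, x[-n]); y <- c(0, y[-n])  # position 0 = release point

  # shallow-occupancy depth along the track (deep-dive structure lives in
  # simulate_depth_series)
  dv <- config$dive
  dep <- dv$shallow_mean_m +
    as.numeric(stats::filter(rnorm(n, 0, dv$shallow_sd_m * 0.5), 0.9,
                             "recursive", init = 0))
  dep <- pmin(pmax(dep, 0), dv$shallow_max_m)

  ll <- km_to_lonlat(x, y, config$origin)
  times <- config$release_time + (seq_len(n) - 1) * dt_min * 60
  total_s <- config$duration_days * 86400
  n_em <- ceiling(total_s / config$tag_delay_s[1]) + 10L
  gaps <- runif(n_em, config$tag_delay_s[1], config$tag_delay_s[2])
  em <- cumsum(gaps)
  em <- em[em <= total_s]

  structure(list(
    steps = data.frame(time = times, x_km = x, y_km = y,
                       lon = ll[, "lon"], lat = ll[, "lat"],
                       depth_m = dep, state = states, stringsAsFactors = FALSE),
    emission_s = em, regime = config$regime, origin = config$origin,
    config = config), class = "truth_record")
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("truth_record: regime %s, %d steps over %g days, %d emissions\n",
              x$regime, nrow(x$steps), x$config$duration_days,
              length(x$emission_s)))
  invisible(x)
}

# Logistic detection-probability curve: p equals
# `detection_p_at_half_range` at half the maximum range, falls with
# distance (slope scale = max range / 10), and is exactly 0 beyond the
# maximum range.
detection_probability <- function(dist_m, config) {
  rmax <- config$detection_range_m[2]
  s <- rmax / 10
  d0 <- rmax / 2 - s * log((1 - config$detection_p_at_half_range) /
                             config$detection_p_at_half_range)
  p <- 1 / (1 + exp((dist_m - d0) / s))
  p[dist_m > rmax] <- 0
  p
}

#' Simulate acoustic detections of a simulated track
#'
#' Interpolates the true position at each transmitter emission, evaluates
#' the distance-decaying detection probability at every receiver, and draws
#' independent detection outcomes. No detection can occur beyond the
#' maximum detection range.
#'
#' @param truth a [simulate_track()] result.
#' @param receivers receiver table; defaults to the config's array.
#' @param config the [sim_config()] (defaults to the one embedded in
#'   `truth`).
#' @return time-sorted detections data.frame (`tag_id`, `receiver_id`,
#'   `timestamp`) with an `"emissions"` attribute giving, per emission, the
#'   first detecting receiver (or `NA`).
#' @export
simulate_detections <- function(truth, receivers = NULL, config = truth$config) {
  stopifnot(inherits(truth, "truth_record"))
  receivers <- receivers %||% config$receivers
  if (is.null(receivers) || nrow(receivers) == 0)
    stop_ct("simulate_detections needs at least one receiver")
  set.seed(config$seed + 1L)
  em <- truth$emission_s
  st <- truth$steps
  t_s <- as.numeric(st$time - config$release_time, units = "secs")
  ex <- approx(t_s, st$x_km, xout = em, rule = 2)$y
  ey <- approx(t_s, st$y_km, xout = em, rule = 2)$y
  rk <- lonlat_to_km(receivers$lon, receivers$lat, truth$origin)
  first_rec <- rep(NA_character_, length(em))
  rows <- vector("list", nrow(receivers))
  for (j in seq_len(nrow(receivers))) {
    dist_m <- sqrt((ex - rk[j, 1])^2 + (ey - rk[j, 2])^2) * 1000
    inr <- which(dist_m <= config$detection_range_m[2])
    if (!length(inr)) next
    p <- detection_probability(dist_m[inr], config)
    hit <- inr[runif(length(inr)) < p]
    if (!length(hit)) next
    rows[[j]] <- data.frame(tag_id = config$tag_id,
                            receiver_id = receivers$receiver_id[j],
                            timestamp = config$release_time + em[hit],
                            emission = hit, stringsAsFactors = FALSE)
  }
  det <- do.call(rbind, rows)
  if (is.null(det))
    det <- data.frame(tag_id = character(), receiver_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      emission = integer(), stringsAsFactors = FALSE)
  det <- det[order(det$timestamp, det$receiver_id), , drop = FALSE]
  if (nrow(det)) {
    f <- det[!duplicated(det$emission), ]
    first_rec[f$emission] <- f$receiver_id
  }
  out <- det[c("tag_id", "receiver_id", "timestamp")]
  rownames(out) <- NULL
  attr(out, "emissions") <- data.frame(
    time = config$release_time + em, receiver_id = first_rec,
    stringsAsFactors = FALSE)
  out
}

#' Simulate Argos surface fixes from a simulated track
#'
#' Surfacing times are a Poisson subsample of the track; each fix adds
#' isotropic Gaussian error with a class-dependent scale, classes are drawn
#' from the configured mixture, class Z fixes carry no coordinates, and an
#' optional number of gross outliers (class B, 500 km off track) can be
#' injected and flagged in the truth sidecar for filter testing.
#'
#' @inheritParams simulate_detections
#' @return time-sorted Argos data.frame (`tag_id`, `timestamp`,
#'   `loc_class`, `lon`, `lat`) with a `"truth"` attribute holding the true
#'   position and an `outlier` flag per fix.
#' @export
simulate_argos <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "truth_record"))
  set.seed(config$seed + 2L)
  total_s <- config$duration_days * 86400
  n_fix <- rpois(1, config$argos_fixes_per_day * config$duration_days)
  ft <- sort(runif(n_fix, 0, total_s))
  st <- truth$steps
  t_s <- as.numeric(st$time - config$release_time, units = "secs")
  tx <- approx(t_s, st$x_km, xout = ft, rule = 2)$y
  ty <- approx(t_s, st$y_km, xout = ft, rule = 2)$y
  cls <- sample(names(config$argos_class_probs), n_fix, replace = TRUE,
                prob = config$argos_class_probs)
  err_km <- unname(config$argos_error_m[cls]) / 1000
  err_km[cls == "Z"] <- 0
  fx <- tx + rnorm(n_fix, 0, 1) * err_km
  fy <- ty + rnorm(n_fix, 0, 1) * err_km
  outlier <- rep(FALSE, n_fix)
  if (config$argos_n_outliers > 0) {
    cand <- which(cls != "Z")
    k <- min(config$argos_n_outliers, length(cand))
    pick <- sample(cand, k)
    th <- runif(k, 0, 2 * pi)
    cls[pick] <- "B"
    fx[pick] <- tx[pick] + 500 * cos(th)
    fy[pick] <- ty[pick] + 500 * sin(th)
    outlier[pick] <- TRUE
  }
  ll <- km_to_lonlat(fx, fy, truth$origin)
  tru <- km_to_lonlat(tx, ty, truth$origin)
  out <- data.frame(tag_id = config$tag_id,
                    timestamp = config$release_time + ft,
                    loc_class = cls,
                    lon = ifelse(cls == "Z", NA_real_, ll[, "lon"]),
                    lat = ifelse(cls == "Z", NA_real_, ll[, "lat"]),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- data.frame(
    timestamp = out$timestamp, true_lon = tru[, "lon"],
    true_lat = tru[, "lat"], loc_class = cls, outlier = outlier,
    stringsAsFactors = FALSE)
  out
}

#' Simulate an archival depth-temperature series
#'
#' Two-state dive behaviour: autocorrelated shallow occupancy bounded by
#' `shallow_max_m`, interrupted by episodic deep dives (Poisson events with
#' a triangular descent/ascent profile reaching a drawn - or fixed - target
#' depth). Temperature decreases monotonically with depth
#' (`T(d) = T_surf - (T_surf - T_deep) d / (d + 300)`) plus sensor noise.
#'
#' @param config a [sim_config()]; dive behaviour comes from `config$dive`.
#' @return time-sorted data.frame (`tag_id`, `timestamp`, `depth_m`,
#'   `temp_c`).
#' @export
simulate_depth_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  dv <- config$dive
  n <- ceiling(config$duration_days * 86400 / dv$sample_interval_s)
  dep <- dv$shallow_mean_m +
    as.numeric(stats::filter(rnorm(n, 0, dv$shallow_sd_m * 0.5), 0.9,
                             "recursive", init = 0))
  dep <- pmin(pmax(dep, 0), dv$shallow_max_m)
  n_dive <- rpois(1, dv$deep_rate_per_day * config$duration_days)
  if (n_dive > 0) {
    dur_steps <- max(3L, ceiling(dv$dive_duration_min * 60 / dv$sample_interval_s))
    half <- dur_steps %/% 2L
    starts <- sort(sample.int(max(1L, n - dur_steps), n_dive, replace = TRUE))
    for (s in starts) {
      target <- if (!is.null(dv$deep_depth_fixed_m)) dv$deep_depth_fixed_m
                else runif(1, dv$deep_depth_min_m, dv$deep_depth_max_m)
      target <- min(target, dv$max_depth_m)
      prof <- c(seq(dep[s], target, length.out = half + 1L),
                seq(target, dv$shallow_mean_m, length.out = dur_steps - half)[-1])
      idx <- s:(s + length(prof) - 1L)
      dep[idx] <- prof
    }
  }
  dep <- pmin(pmax(dep, 0), dv$max_depth_m)
  tc <- dv$surface_temp_c -
    (dv$surface_temp_c - dv$deep_temp_c) * dep / (dep + 300) +
    rnorm(n, 0, dv$temp_noise_sd)
  tc <- pmin(pmax(tc, -4.9), 44.9)
  data.frame(tag_id = config$tag_id,
             timestamp = config$release_time +
               (seq_len(n) - 1) * dv$sample_interval_s,
             depth_m = dep, temp_c = tc, stringsAsFactors = FALSE)
}

#' Build a synthetic bathymetry grid
#'
#' Evaluates a seafloor-depth function on a regular lon/lat grid with the
#' requested cell size (km converted to degrees at the extent's centre
#' latitude).
#'
#' @param extent c(lon_min, lon_max, lat_min, lat_max) in degrees.
#' @param cell_km positive cell edge length in km.
#' @param seafloor_fn vectorised function `(lon, lat) -> depth_m > 0`.
#' @return a `bathymetry_grid`.
#' @export
make_bathymetry <- function(extent, cell_km, seafloor_fn) {
  if (cell_km <= 0) stop_ct("cell_km must be positive")
  lat0 <- mean(extent[3:4])
  dlon <- cell_km / (KM_PER_DEG * cos(lat0 * pi / 180))
  dlat <- cell_km / KM_PER_DEG
  lon <- seq(extent[1], extent[2], by = dlon)
  lat <- seq(extent[3], extent[4], by = dlat)
  z <- outer(lon, lat, seafloor_fn)
  if (any(!is.finite(z))) stop_ct("seafloor_fn produced non-finite depths")
  bathymetry_grid(lon, lat, z)
}

#' Simulate a full telemetry dataset
#'
#' Convenience wrapper running track, detections, Argos and depth-series
#' simulation from one config, plus the matching tag and receiver metadata
#' tables.
#'
#' @param config a [sim_config()].
#' @return list with elements `config`, `tags`, `receivers`, `truth`,
#'   `detections`, `argos`, `depth`.
#' @export
simulate_telemetry <- function(config) {
  truth <- simulate_track(config)
  det <- simulate_detections(truth)
  argos <- simulate_argos(truth)
  depth <- simulate_depth_series(config)
  i <- match(paste(config$tag_delay_s[1], config$tag_delay_s[2]),
             paste(TAG_CONFIGS$delay_min_s, TAG_CONFIGS$delay_max_s))
  tags <- data.frame(tag_id = config$tag_id, shark_id = config$tag_id,
                     sex = "F", total_length_cm = 300,
                     maturity = "sub_adult", clasper_state = "not_applicable",
                     release_time = config$release_time,
                     release_lon = config$origin[1],
                     release_lat = config$origin[2],
                     battery_days = TAG_CONFIGS$battery_days[i],
                     delay_min_s = config$tag_delay_s[1],
                     delay_max_s = config$tag_delay_s[2],
                     stringsAsFactors = FALSE)
  list(config = config, tags = tags, receivers = config$receivers,
       truth = truth, detections = det, argos = argos, depth = depth)
}

#' Write a simulated dataset to a directory
#'
#' Emits the pipeline CSV dialects plus truth sidecar files
#' (`truth_steps.csv`, `truth_argos.csv`) for test harnesses.
#'
#' @param sim result of [simulate_telemetry()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_detections(sim$detections, file.path(dir, "detections.csv"))
  write_receivers(sim$receivers, file.path(dir, "receivers.csv"))
  write_tags(sim$tags, file.path(dir, "tags.csv"))
  write_argos(sim$argos, file.path(dir, "argos.csv"))
  write_depth_series(sim$depth, file.path(dir, "depth.csv"))
  st <- sim$truth$steps
  st$time <- format_utc(st$time)
  write.csv(st, file.path(dir, "truth_steps.csv"), row.names = FALSE,
            quote = FALSE)
  tr <- attr(sim$argos, "truth")
  if (!is.null(tr)) {
    tr$timestamp <- format_utc(tr$timestamp)
    write.csv(tr, file.path(dir, "truth_argos.csv"), row.names = FALSE,
              quote = FALSE)
  }
  invisible(dir)
}

#' Regime-recovery harness
#'
#' Simulates full telemetry datasets across seeds and regimes and checks
#' whether the behaviour classification recovers the simulated movement
#' regime: the package's end-to-end ground-truth validation.
#'
#' @param seeds integer vector of simulation seeds.
#' @param regimes regimes to test.
#' @param duration_days monitoring span per simulation.
#' @return data.frame (`regime`, `n`, `n_recovered`, `rate`).
#' @export
regime_recovery <- function(seeds = 1:20,
                            regimes = c("resident", "pseudo_resident",
                                        "transient", "passer_by"),
                            duration_days = 432) {
  out <- lapply(regimes, function(rg) {
    hits <- vapply(seeds, function(s) {
      sim <- simulate_telemetry(sim_config(seed = s, regime = rg,
                                           duration_days = duration_days))
      win <- monitoring_window(sim$tags, sim$receivers)
      daily <- daily_detections(sim$detections, sim$receivers, win)
      classify_behaviour(daily, win) == rg
    }, logical(1))
    data.frame(regime = rg, n = length(seeds),
               n_recovered = sum(hits), rate = mean(hits),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
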