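# Shared fixtures and independent oracles, built in code at test time.

UTC <- function(x) as.POSIXct(x, tz = "UTC")

# One-row tag table with a valid configuration.
make_tag <- function(tag_id = "T1", release = UTC("2010-08-16 00:00:00"),
                     battery_days = 1448L, delay = c(30, 90),
                     lon = 158.3, lat = -19.87) {
  data.frame(tag_id = tag_id, shark_id = tag_id, sex = "M",
             total_length_cm = 310, maturity = "mature",
             clasper_state = "calcified", release_time = release,
             release_lon = lon, release_lat = lat,
             battery_days = battery_days, delay_min_s = delay[1],
             delay_max_s = delay[2], stringsAsFactors = FALSE)
}

# Minimal receiver array; deployment covers [release - 30 d, release + days].
make_recs <- function(release = UTC("2010-08-16 00:00:00"), days = 432,
                      lon = c(158.3, 158.5), lat = c(-19.87, -19.80),
                      array = "CI") {
  data.frame(receiver_id = sprintf("R%02d", seq_along(lon)),
             array_name = array, lon = lon, lat = lat, mooring_depth_m = 15,
             deployed_from = release - 30 * 86400,
             deployed_to = release + days * 86400, stringsAsFactors = FALSE)
}

# Daily-detection table from a vector of detected day offsets post-release.
daily_from_offsets <- function(offsets, release = UTC("2010-08-16 00:00:00"),
                               tag_id = "T1", array = "CI") {
  n <- length(offsets)
  data.frame(tag_id = rep(tag_id, n), array_name = rep(array, n),
             day = as.Date(release, tz = "UTC") + offsets,
             n_detections = rep(1L, n), stringsAsFactors = FALSE)
}

# Detections data.frame from timestamps (single receiver by default).
det_at <- function(times, tag_id = "T1", receiver_id = "R01") {
  n <- length(times)
  data.frame(tag_id = rep_len(tag_id, n), receiver_id = rep_len(receiver_id, n),
             timestamp = times, stringsAsFactors = FALSE)
}

# Brute-force oracle for the Argos speed filter: for every coarse-class fix
# it rebuilds the full anchor candidate set from scratch (initial anchors
# plus every class 1-3 fix at or before the fix time) and tests the most
# recent one explicitly. Independent of the package's sequential
# implementation.
brute_filter_kept <- function(positions, anchors, vmax_kmh = 3.5) {
  n <- nrow(positions)
  kept <- logical(n)
  hi <- positions$loc_class %in% c("3", "2", "1")
  cand_t <- c(as.numeric(anchors$timestamp),
              as.numeric(positions$timestamp)[hi])
  cand_lon <- c(anchors$lon, positions$lon[hi])
  cand_lat <- c(anchors$lat, positions$lat[hi])
  for (i in seq_len(n)) {
    cls <- positions$loc_class[i]
    if (cls == "Z") next
    if (cls %in% c("3", "2", "1")) { kept[i] <- TRUE; next }
    ti <- as.numeric(positions$timestamp[i])
    sel <- which(cand_t <= ti)
    if (!length(sel)) next
    j <- sel[which.max(cand_t[sel])]
    dt_h <- max((ti - cand_t[j]) / 3600, 1 / 60)
    d <- haversine_km(cand_lon[j], cand_lat[j],
                      positions$lon[i], positions$lat[i])
    kept[i] <- d <= vmax_kmh * dt_h
  }
  kept
}

# Random filter instance with distinct times and a mix of classes.
rand_argos_instance <- function(seed, max_n = 200) {
  set.seed(seed)
  n <- sample(5:max_n, 1)
  t0 <- UTC("2010-01-01 00:00:00")
  times <- t0 + sort(sample.int(30 * 86400, n))
  cls <- sample(c("3", "2", "1", "0", "A", "B", "Z"), n, replace = TRUE)
  lon <- 158 + cumsum(rnorm(n, 0, 0.05))
  lat <- -20 + cumsum(rnorm(n, 0, 0.05))
  lon[cls == "Z"] <- NA
  lat[cls == "Z"] <- NA
  list(positions = data.frame(tag_id = "T", timestamp = times,
                              loc_class = cls, lon = lon, lat = lat,
                              stringsAsFactors = FALSE),
       anchors = data.frame(timestamp = t0 - 3600, lon = 158, lat = -20,
                            stringsAsFactors = FALSE))
}
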