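# Location-class and swim-speed plausibility filter for Argos surface
# fixes. High-accuracy classes (3, 2, 1) are always kept and become
# anchors; coarse classes (0, A, B) are kept only if reachable from the
# most recent prior anchor at a maximum sustained swim speed; class Z fixes
# carry no position and are dropped.

#' Filter Argos positions by location class and swim speed
#'
#' Processes time-sorted fixes in order. Class 3/2/1 fixes are kept
#' unconditionally and appended to the anchor set. Class 0/A/B fixes are
#' kept iff their great-circle distance to the most recent anchor at or
#' before the fix time is within `vmax_kmh` times the elapsed hours
#' (elapsed time floored at one minute to avoid division artifacts); kept
#' coarse fixes are NOT promoted to anchors. Class Z fixes are always
#' rejected. Anchors seed from prior known positions: at minimum the
#' capture/release location, plus any acoustic-detection receiver
#' positions.
#'
#' @param positions time-sorted Argos data.frame (`tag_id`, `timestamp`,
#'   `loc_class`, `lon`, `lat`), one tag.
#' @param anchors data.frame (`timestamp`, `lon`, `lat`) of known-position
#'   events; must be non-empty.
#' @param vmax_kmh maximum plausible sustained swim speed (km/h).
#' @return the input positions with `kept` (logical) and `reason` columns;
#'   one decision per input fix. Reasons: `class_1_3`,
#'   `within_speed_of_anchor`, `rejected_speed`, `rejected_class_z`,
#'   `no_anchor`.
#' @export
filter_positions <- function(positions, anchors, vmax_kmh = 3.5) {
  if (!nrow(anchors)) stop_ct("anchor set must be non-empty")
  if (is.unsorted(as.numeric(positions$timestamp)))
    stop_ct("positions must be sorted by time")
  if (vmax_kmh <= 0) stop_ct("vmax_kmh must be positive")
  anc_t <- as.numeric(anchors$timestamp)
  anc_lon <- anchors$lon; anc_lat <- anchors$lat
  o <- order(anc_t)
  anc_t <- anc_t[o]; anc_lon <- anc_lon[o]; anc_lat <- anc_lat[o]

  n <- nrow(positions)
  kept <- logical(n); reason <- character(n)
  for (i in seq_len(n)) {
    cls <- positions$loc_class[i]
    ti <- as.numeric(positions$timestamp[i])
    if (cls == "Z") {
      reason[i] <- "rejected_class_z"
      next
    }
    if (cls %in% c("3", "2", "1")) {
      kept[i] <- TRUE; reason[i] <- "class_1_3"
      # kept high-accuracy fixes become anchors for later coarse fixes
      pos <- findInterval(ti, anc_t)
      anc_t <- append(anc_t, ti, after = pos)
      anc_lon <- append(anc_lon, positions$lon[i], after = pos)
      anc_lat <- append(anc_lat, positions$lat[i], after = pos)
      next
    }
    j <- findInterval(ti, anc_t)  # most recent anchor at or before the fix
    if (j == 0) {
      reason[i] <- "no_anchor"
      next
    }
    dt_h <- max((ti - anc_t[j]) / 3600, 1 / 60)
    d_km <- haversine_km(anc_lon[j], anc_lat[j],
                         positions$lon[i], positions$lat[i])
    if (d_km <= vmax_kmh * dt_h) {
      kept[i] <- TRUE; reason[i] <- "within_speed_of_anchor"
    } else {
      reason[i] <- "rejected_speed"
    }
  }
  out <- positions
  out$kept <- kept
  out$reason <- reason
  out
}

#' Anchor set for the speed filter
#'
#' Builds the (timestamp, lon, lat) anchor table from a tag's release
#' record and its acoustic detections (receiver positions at detection
#' times).
#'
#' @param tag single-row tag data.frame.
#' @param detections optional detections for this tag.
#' @param receivers receiver table (needed when detections are given).
#' @return data.frame (`timestamp`, `lon`, `lat`) sorted by time.
#' @export
build_anchors <- function(tag, detections = NULL, receivers = NULL) {
  anc <- data.frame(timestamp = tag$release_time, lon = tag$release_lon,
                    lat = tag$release_lat, stringsAsFactors = FALSE)
  if (!is.null(detections) && nrow(detections)) {
    if (is.null(receivers)) stop_ct("receivers needed to anchor detections")
    i <- match(detections$receiver_id, receivers$receiver_id)
    ok <- !is.na(i)
    anc <- rbind(anc, data.frame(timestamp = detections$timestamp[ok],
                                 lon = receivers$lon[i[ok]],
                                 lat = receivers$lat[i[ok]],
                                 stringsAsFactors = FALSE))
  }
  anc[order(anc$timestamp), , drop = FALSE]
}
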