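# Readers and writers for the pipeline's CSV dialects, with row-level
# validation. Every reader returns a typed, time-sorted data.frame carrying a
# "report" attribute (data.frame of rejected source rows and reasons);
# structural problems (missing file, wrong header) are errors.
#
# Dialects (comma-separated, ISO-8601 UTC timestamps):
#   detections.csv : tag_id,receiver_id,timestamp
#   receivers.csv  : receiver_id,array_name,lon,lat,mooring_depth_m,
#                    deployed_from,deployed_to
#   tags.csv       : tag_id,shark_id,sex,total_length_cm,maturity,
#                    clasper_state,release_time,release_lon,release_lat,
#                    battery_days,delay_min_s,delay_max_s
#   argos.csv      : tag_id,timestamp,loc_class,lon,lat
#   depth.csv      : tag_id,timestamp,depth_m,temp_c
#   bathymetry.csv : lon,lat,seafloor_depth_m  (complete regular grid)

# The three acoustic tag configurations: battery life is tied to the pulse
# delay interval by the manufacturer's specification.
TAG_CONFIGS <- data.frame(
  battery_days = c(696L, 835L, 1448L),
  delay_min_s  = c(50, 40, 30),
  delay_max_s  = c(130, 80, 90)
)

read_dialect <- function(path, required_cols) {
  if (!file.exists(path)) stop_ct("file not found: %s", path)
  # read everything as character: type conversion is explicit per reader
  # (read.csv would otherwise guess a column of "F" sexes as logical)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = "character")
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop_ct("%s: missing required column(s): %s", path,
            paste(missing, collapse = ", "))
  df
}

finish_records <- function(df, keep, reasons, order_by = NULL) {
  report <- data.frame(row = which(!keep),
                       reason = reasons[!keep],
                       stringsAsFactors = FALSE)
  out <- df[keep, , drop = FALSE]
  if (!is.null(order_by) && nrow(out)) out <- out[order(out[[order_by]]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}

#' Validation report of a read
#'
#' @param x a data.frame returned by one of the `read_*` functions.
#' @return data.frame with columns `row` (source row number) and `reason`.
#' @export
validation_report <- function(x) {
  attr(x, "report") %||% data.frame(row = integer(), reason = character())
}

reject_reason <- function(n) rep(NA_character_, n)
mark <- function(reasons, bad, why) {
  ifelse(is.na(reasons) & bad, why, reasons)
}

#' Read acoustic detection logs
#'
#' @param path CSV with columns `tag_id,receiver_id,timestamp`.
#' @param receivers optional receiver table; when given, detections outside
#'   the receiver's deployment interval are rejected with a reason.
#' @return data.frame (`tag_id`, `receiver_id`, `timestamp`) sorted by time,
#'   with a validation report attribute (see [validation_report()]).
#' @export
read_detections <- function(path, receivers = NULL) {
  df <- read_dialect(path, c("tag_id", "receiver_id", "timestamp"))
  n <- nrow(df)
  ts <- parse_utc(df$timestamp)
  reasons <- reject_reason(n)
  reasons <- mark(reasons, is.na(ts), "unparseable timestamp")
  reasons <- mark(reasons, !nzchar(df$tag_id), "empty tag_id")
  reasons <- mark(reasons, !nzchar(df$receiver_id), "empty receiver_id")
  out <- data.frame(tag_id = as.character(df$tag_id),
                    receiver_id = as.character(df$receiver_id),
                    timestamp = ts, stringsAsFactors = FALSE)
  if (!is.null(receivers)) {
    i <- match(out$receiver_id, receivers$receiver_id)
    bad <- !is.na(i) & !is.na(ts) &
      (ts < receivers$deployed_from[i] | ts > receivers$deployed_to[i])
    reasons <- mark(reasons, bad, "outside receiver deployment interval")
    reasons <- mark(reasons, is.na(i), "unknown receiver_id")
  }
  finish_records(out, is.na(reasons), reasons, "timestamp")
}

#' Read receiver (station) metadata
#'
#' @param path CSV in the `receivers.csv` dialect.
#' @return validated data.frame with parsed deployment instants.
#' @export
read_receivers <- function(path) {
  cols <- c("receiver_id", "array_name", "lon", "lat", "mooring_depth_m",
            "deployed_from", "deployed_to")
  df <- read_dialect(path, cols)
  n <- nrow(df)
  from <- parse_utc(df$deployed_from); to <- parse_utc(df$deployed_to)
  reasons <- reject_reason(n)
  reasons <- mark(reasons, is.na(suppressWarnings(as.numeric(df$lat))) |
                    abs(as.numeric(df$lat)) > 90, "latitude out of range")
  reasons <- mark(reasons, is.na(suppressWarnings(as.numeric(df$lon))) |
                    abs(as.numeric(df$lon)) > 180, "longitude out of range")
  reasons <- mark(reasons, is.na(from) | is.na(to), "unparseable timestamp")
  reasons <- mark(reasons, !is.na(from) & !is.na(to) & from >= to,
                  "deployed_from not before deployed_to")
  reasons <- mark(reasons, suppressWarnings(as.numeric(df$mooring_depth_m)) < 0,
                  "negative mooring depth")
  out <- data.frame(receiver_id = as.character(df$receiver_id),
                    array_name = as.character(df$array_name),
                    lon = as.numeric(df$lon), lat = as.numeric(df$lat),
                    mooring_depth_m = as.numeric(df$mooring_depth_m),
                    deployed_from = from, deployed_to = to,
                    stringsAsFactors = FALSE)
  finish_records(out, is.na(reasons), reasons)
}

#' Read tag deployment metadata
#'
#' Validates that `battery_days` and the delay interval come from one of the
#' three manufacturer configurations (696 d with 50-130 s, 835 d with
#' 40-80 s, 1448 d with 30-90 s).
#'
#' @param path CSV in the `tags.csv` dialect.
#' @return validated data.frame with parsed release instants.
#' @export
read_tags <- function(path) {
  cols <- c("tag_id", "shark_id", "sex", "total_length_cm", "maturity",
            "clasper_state", "release_time", "release_lon", "release_lat",
            "battery_days", "delay_min_s", "delay_max_s")
  df <- read_dialect(path, cols)
  n <- nrow(df)
  rel <- parse_utc(df$release_time)
  tl <- suppressWarnings(as.numeric(df$total_length_cm))
  reasons <- reject_reason(n)
  reasons <- mark(reasons, is.na(rel), "unparseable release_time")
  reasons <- mark(reasons, !(df$sex %in% c("M", "F")), "sex must be M or F")
  reasons <- mark(reasons, is.na(tl) | tl <= 50 | tl >= 600,
                  "total_length_cm outside (50, 600)")
  reasons <- mark(reasons,
                  !(df$maturity %in% c("juvenile", "sub_adult", "mature")),
                  "unknown maturity")
  reasons <- mark(reasons,
                  !(df$clasper_state %in%
                      c("none", "semi_calcified", "calcified", "not_applicable")),
                  "unknown clasper_state")
  reasons <- mark(reasons, abs(suppressWarnings(as.numeric(df$release_lat))) > 90,
                  "latitude out of range")
  reasons <- mark(reasons, abs(suppressWarnings(as.numeric(df$release_lon))) > 180,
                  "longitude out of range")
  key <- paste(df$battery_days, df$delay_min_s, df$delay_max_s)
  ok_key <- paste(TAG_CONFIGS$battery_days, TAG_CONFIGS$delay_min_s,
                  TAG_CONFIGS$delay_max_s)
  reasons <- mark(reasons, !(key %in% ok_key),
                  "battery/delay not a known tag configuration")
  out <- data.frame(tag_id = as.character(df$tag_id),
                    shark_id = as.character(df$shark_id),
                    sex = df$sex, total_length_cm = tl,
                    maturity = df$maturity, clasper_state = df$clasper_state,
                    release_time = rel,
                    release_lon = as.numeric(df$release_lon),
                    release_lat = as.numeric(df$release_lat),
                    battery_days = as.integer(df$battery_days),
                    delay_min_s = as.numeric(df$delay_min_s),
                    delay_max_s = as.numeric(df$delay_max_s),
                    stringsAsFactors = FALSE)
  finish_records(out, is.na(reasons), reasons)
}

#' Read Argos satellite positions
#'
#' Class Z uplinks carry no usable coordinates: their lon/lat must be empty
#' and are stored as `NA`. Non-Z rows with missing or out-of-range
#' coordinates are rejected.
#'
#' @param path CSV in the `argos.csv` dialect.
#' @return validated, time-sorted data.frame.
#' @export
read_argos <- function(path) {
  df <- read_dialect(path, c("tag_id", "timestamp", "loc_class", "lon", "lat"))
  n <- nrow(df)
  ts <- parse_utc(df$timestamp)
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  cls <- as.character(df$loc_class)
  reasons <- reject_reason(n)
  reasons <- mark(reasons, is.na(ts), "unparseable timestamp")
  reasons <- mark(reasons, !(cls %in% c("3", "2", "1", "0", "A", "B", "Z")),
                  "unknown location class")
  nonz <- cls != "Z"
  reasons <- mark(reasons, nonz & (is.na(lat) | abs(lat) > 90),
                  "latitude out of range")
  reasons <- mark(reasons, nonz & (is.na(lon) | abs(lon) > 180),
                  "longitude out of range")
  reasons <- mark(reasons, !nonz & (!is.na(lon) | !is.na(lat)),
                  "class Z must not carry coordinates")
  out <- data.frame(tag_id = as.character(df$tag_id), timestamp = ts,
                    loc_class = cls, lon = lon, lat = lat,
                    stringsAsFactors = FALSE)
  finish_records(out, is.na(reasons), reasons, "timestamp")
}

#' Read an archival depth-temperature series
#'
#' @param path CSV in the `depth.csv` dialect.
#' @return validated, time-sorted data.frame.
#' @export
read_depth_series <- function(path) {
  df <- read_dialect(path, c("tag_id", "timestamp", "depth_m", "temp_c"))
  ts <- parse_utc(df$timestamp)
  d <- suppressWarnings(as.numeric(df$depth_m))
  tc <- suppressWarnings(as.numeric(df$temp_c))
  reasons <- reject_reason(nrow(df))
  reasons <- mark(reasons, is.na(ts), "unparseable timestamp")
  reasons <- mark(reasons, !is.finite(d) | d < 0, "depth must be finite and >= 0")
  reasons <- mark(reasons, !is.finite(tc) | tc <= -5 | tc >= 45,
                  "temperature outside (-5, 45)")
  out <- data.frame(tag_id = as.character(df$tag_id), timestamp = ts,
                    depth_m = d, temp_c = tc, stringsAsFactors = FALSE)
  finish_records(out, is.na(reasons), reasons, "timestamp")
}

#' Read a gridded bathymetry file
#'
#' Long-format CSV (`lon,lat,seafloor_depth_m`) that must tile a complete
#' regular lon/lat grid with strictly positive seafloor depths.
#'
#' @param path CSV in the `bathymetry.csv` dialect.
#' @return a `bathymetry_grid` object: list with `lon`, `lat` axis vectors
#'   and a `depth_m` matrix (rows = lon, cols = lat).
#' @export
read_bathymetry <- function(path) {
  df <- read_dialect(path, c("lon", "lat", "seafloor_depth_m"))
  for (cc in names(df)) df[[cc]] <- as.numeric(df[[cc]])
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  if (length(lon) < 2 || length(lat) < 2)
    stop_ct("bathymetry grid needs at least 2 x 2 cells")
  if (nrow(df) != length(lon) * length(lat))
    stop_ct("bathymetry file does not tile a complete regular grid")
  if (any(!is.finite(df$seafloor_depth_m)) || any(df$seafloor_depth_m <= 0))
    stop_ct("bathymetry depths must be finite and > 0")
  z <- matrix(NA_real_, length(lon), length(lat))
  z[cbind(match(df$lon, lon), match(df$lat, lat))] <- df$seafloor_depth_m
  bathymetry_grid(lon, lat, z)
}

bathymetry_grid <- function(lon, lat, depth_m) {
  stopifnot(length(lon) == nrow(depth_m), length(lat) == ncol(depth_m))
  if (is.unsorted(lon, strictly = TRUE) || is.unsorted(lat, strictly = TRUE))
    stop_ct("bathymetry axes must be strictly increasing")
  if (any(!is.finite(depth_m)) || any(depth_m <= 0))
    stop_ct("bathymetry depths must be finite and > 0")
  structure(list(lon = lon, lat = lat, depth_m = depth_m),
            class = "bathymetry_grid")
}

#' @export
print.bathymetry_grid <- function(x, ...) {
  cat(sprintf("bathymetry grid: %d x %d cells, lon [%.3f, %.3f], lat [%.3f, %.3f], depth %g-%g m\n",
              length(x$lon), length(x$lat), min(x$lon), max(x$lon),
              min(x$lat), max(x$lat), min(x$depth_m), max(x$depth_m)))
  invisible(x)
}

# -- writers -----------------------------------------------------------------

write_timestamped <- function(df, path, time_cols) {
  out <- df
  for (cc in intersect(time_cols, names(out))) out[[cc]] <- format_utc(out[[cc]])
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write records in the package CSV dialects
#'
#' Each writer emits exactly the header its matching reader expects, so a
#' write-then-read round trip is the identity on all record types.
#'
#' @param x records as returned by the matching reader (or simulator).
#' @param path output file.
#' @name writers
NULL

#' @rdname writers
#' @export
write_detections <- function(x, path)
  write_timestamped(x[c("tag_id", "receiver_id", "timestamp")], path, "timestamp")

#' @rdname writers
#' @export
write_receivers <- function(x, path)
  write_timestamped(x[c("receiver_id", "array_name", "lon", "lat",
                        "mooring_depth_m", "deployed_from", "deployed_to")],
                    path, c("deployed_from", "deployed_to"))

#' @rdname writers
#' @export
write_tags <- function(x, path)
  write_timestamped(x[c("tag_id", "shark_id", "sex", "total_length_cm",
                        "maturity", "clasper_state", "release_time",
                        "release_lon", "release_lat", "battery_days",
                        "delay_min_s", "delay_max_s")], path, "release_time")

#' @rdname writers
#' @export
write_argos <- function(x, path)
  write_timestamped(x[c("tag_id", "timestamp", "loc_class", "lon", "lat")],
                    path, "timestamp")

#' @rdname writers
#' @export
write_depth_series <- function(x, path)
  write_timestamped(x[c("tag_id", "timestamp", "depth_m", "temp_c")],
                    path, "timestamp")

#' @rdname writers
#' @export
write_bathymetry <- function(x, path) {
  stopifnot(inherits(x, "bathymetry_grid"))
  df <- expand.grid(lon = x$lon, lat = x$lat, KEEP.OUT.ATTRS = FALSE)
  df$seafloor_depth_m <- as.vector(x$depth_m)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
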