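# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

KM_PER_DEG <- 6371 * pi / 180  # great-circle km per degree of arc

#' Parse ISO-8601 timestamps to UTC
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS` (optionally with a trailing `Z`) or the
#' space-separated equivalent, and bare dates. Unparseable entries become
#' `NA` and are reported by the readers' validation layer.
#'
#' @param x character vector of timestamps.
#' @return `POSIXct` vector in UTC.
#' @keywords internal
parse_utc <- function(x) {
  x <- sub("Z$", "", sub("T", " ", as.character(x)))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  out
}

format_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")

#' Convert UTC instants to local wall-clock time via a fixed offset
#'
#' Diel statistics use a per-dataset fixed UTC offset (e.g. +11 for New
#' Caledonia) with no daylight-saving logic; the conversion is exactly
#' invertible.
#'
#' @param t `POSIXct` vector (UTC).
#' @param utc_offset_hours fixed offset in hours (may be fractional).
#' @return `POSIXct` shifted so that `format()` in UTC shows local clock time.
#' @export
to_local <- function(t, utc_offset_hours) {
  stopifnot(is.numeric(utc_offset_hours), length(utc_offset_hours) == 1)
  t + utc_offset_hours * 3600
}

local_date <- function(t, utc_offset_hours = 0) {
  as.Date(to_local(t, utc_offset_hours), tz = "UTC")
}

stop_ct <- function(...) stop(sprintf(...), call. = FALSE)

is_instant <- function(x) inherits(x, "POSIXct")
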