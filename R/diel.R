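# Diel detection statistics: fixed day/night windows in local wall-clock
# time and the equal-expectation one-degree-of-freedom chi-square.

#' Split detections into day and night counts
#'
#' Day is the local wall-clock window \[06:00, 18:00) and night its
#' complement (18:00-05:59), under a fixed per-dataset UTC offset (no
#' daylight-saving logic). A detection at exactly 06:00 is day; at exactly
#' 18:00, night.
#'
#' @param detections detections data.frame (any number of tags).
#' @param utc_offset_hours fixed local-time offset in hours.
#' @return data.frame (`tag_id`, `day_count`, `night_count`), one row per
#'   tag.
#' @export
diel_split <- function(detections, utc_offset_hours) {
  lt <- to_local(detections$timestamp, utc_offset_hours)
  secs <- as.numeric(lt) %% 86400
  is_day <- secs >= 6 * 3600 & secs < 18 * 3600
  tags <- sort(unique(detections$tag_id))
  data.frame(
    tag_id = tags,
    day_count = as.integer(vapply(tags, function(tg)
      sum(is_day[detections$tag_id == tg]), integer(1))),
    night_count = as.integer(vapply(tags, function(tg)
      sum(!is_day[detections$tag_id == tg]), integer(1))),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Equal-expectation diel chi-square
#'
#' One-degree-of-freedom goodness-of-fit of day vs night detection counts
#' against equal expected proportions (12 h day / 12 h night), without
#' continuity correction: `X2 = (day - night)^2 / (day + night)`, with the
#' upper-tail chi-square(1) p-value. Vectorised.
#'
#' @param day_count,night_count non-negative integer counts (recycled).
#' @return data.frame (`day_count`, `night_count`, `statistic`, `p_value`,
#'   `p_label`), where `p_label` is the 3-decimal display form with the
#'   `"<0.001"` convention.
#' @export
diel_chi_square <- function(day_count, night_count) {
  n <- max(length(day_count), length(night_count))
  d <- rep_len(as.numeric(day_count), n)
  k <- rep_len(as.numeric(night_count), n)
  if (any(d < 0 | k < 0)) stop_ct("counts must be non-negative")
  if (any(d + k < 1)) stop_ct("day_count + night_count must be >= 1")
  stat <- (d - k)^2 / (d + k)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  data.frame(day_count = d, night_count = k, statistic = stat, p_value = p,
             p_label = format_p_value(p), stringsAsFactors = FALSE)
}

#' Format p-values for reporting
#'
#' Three decimals, printing `"<0.001"` for any p below 0.001 - the
#' convention under which the equal-expectation test reproduces published
#' diel tables.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
format_p_value <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

#' Per-tag diel summary
#'
#' @inheritParams diel_split
#' @return data.frame with counts, statistic, p-value and label per tag.
#' @export
diel_summary <- function(detections, utc_offset_hours) {
  counts <- diel_split(detections, utc_offset_hours)
  if (!nrow(counts))
    return(cbind(counts, statistic = numeric(0), p_value = numeric(0),
                 p_label = character(0)))
  chi <- diel_chi_square(counts$day_count, counts$night_count)
  cbind(counts, chi[c("statistic", "p_value", "p_label")])
}
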