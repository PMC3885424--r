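# Residency metrics and the four-category occurrence classification.
#
# The monitoring window bounds the days a tag could have been detected:
# from release until the earlier of battery exhaustion and the last array
# service (retrieval) time. The Residency Index (RI) is the number of
# distinct detected days divided by those potential days. Occurrence
# categories:
#   resident        - detected in >=10 distinct calendar months within every
#                     year-block of the window and RI > 0.30
#   pseudo-resident - >=5 detected days in each of >=3 calendar months of a
#                     year, RI < 0.30
#   transient       - re-detected after a gap > 31 days (from the previous
#                     detection or from release)
#   passer-by       - never detected after day 31 post-release

#' Monitoring window for a tag deployment
#'
#' @param tag single-row tag data.frame (as from [read_tags()]).
#' @param receivers receiver table; the window ends at the latest
#'   `deployed_to` (last array service) if that precedes battery
#'   exhaustion.
#' @return list of class `monitoring_window` with `tag_id`, `start`, `end`
#'   and `potential_days` (whole calendar days, release day counted, never
#'   less than 1).
#' @export
monitoring_window <- function(tag, receivers) {
  stopifnot(nrow(tag) == 1, is_instant(tag$release_time))
  array_end <- max(receivers$deployed_to)
  if (tag$release_time >= array_end)
    stop_ct("no overlap: tag %s released after all array retrievals",
            tag$tag_id)
  end <- min(tag$release_time + tag$battery_days * 86400, array_end)
  days <- max(1L, as.integer(floor(
    as.numeric(difftime(end, tag$release_time, units = "days")))))
  structure(list(tag_id = tag$tag_id, start = tag$release_time, end = end,
                 potential_days = days), class = "monitoring_window")
}

#' @export
print.monitoring_window <- function(x, ...) {
  cat(sprintf("monitoring window for %s: %s to %s (%d potential days)\n",
              x$tag_id, format_utc(x$start), format_utc(x$end),
              x$potential_days))
  invisible(x)
}

#' Daily detection table
#'
#' Collapses raw detections to one row per (tag, array, calendar day) with
#' a detection count; the atom for RI and behaviour classification. Days
#' are taken in local time under a fixed UTC offset.
#'
#' @param detections detections data.frame.
#' @param receivers receiver table (maps receiver to array). Detections at
#'   unknown receivers are dropped.
#' @param window optional [monitoring_window()]; when supplied, days
#'   outside the window are dropped.
#' @param utc_offset_hours fixed offset used to assign calendar days.
#' @return data.frame (`tag_id`, `array_name`, `day`, `n_detections`)
#'   sorted by day.
#' @export
daily_detections <- function(detections, receivers, window = NULL,
                             utc_offset_hours = 0) {
  i <- match(detections$receiver_id, receivers$receiver_id)
  df <- detections[!is.na(i), , drop = FALSE]
  arr <- receivers$array_name[i[!is.na(i)]]
  if (!is.null(window)) {
    keep <- df$timestamp >= window$start & df$timestamp <= window$end
    df <- df[keep, , drop = FALSE]; arr <- arr[keep]
  }
  if (!nrow(df))
    return(data.frame(tag_id = character(), array_name = character(),
                      day = as.Date(character()), n_detections = integer(),
                      stringsAsFactors = FALSE))
  day <- local_date(df$timestamp, utc_offset_hours)
  agg <- aggregate(list(n_detections = rep(1L, nrow(df))),
                   by = list(tag_id = df$tag_id, array_name = arr, day = day),
                   FUN = sum)
  agg <- agg[order(agg$tag_id, agg$array_name, agg$day), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Residency Index
#'
#' Distinct detected days divided by the potential monitoring days of the
#' window (battery life capped by array service). Monotone non-decreasing
#' in the set of detected days and always in \[0, 1\].
#'
#' @param daily a [daily_detections()] table (one tag).
#' @param window the tag's [monitoring_window()].
#' @return fraction in \[0, 1\].
#' @export
residency_index <- function(daily, window) {
  stopifnot(inherits(window, "monitoring_window"))
  n_days <- length(unique(daily$day))
  ri <- n_days / window$potential_days
  min(ri, 1)
}

# distinct calendar months ("YYYY-MM") intersecting [from, to]
months_spanned <- function(from, to) {
  length(unique(format(seq(from, to, by = "day"), "%Y-%m")))
}

#' Classify occurrence behaviour
#'
#' Applies the four-category rules in precedence order resident ->
#' pseudo-resident -> transient -> passer-by. Year-blocks for the resident
#' rule are consecutive 365-day blocks from release; a final partial block
#' is held to the ten-month standard only if it spans at least ten calendar
#' months. The pseudo-resident month rule is evaluated within calendar
#' years. A shark detected past day 31 that fits neither the resident nor
#' the pseudo-resident pattern and shows no >31-day gap is labelled
#' transient, so the classification is total.
#'
#' @param daily a [daily_detections()] table for one tag (and usually one
#'   array).
#' @param window the tag's [monitoring_window()].
#' @param ri Residency Index; recomputed from `daily` if omitted.
#' @return one of `"resident"`, `"pseudo_resident"`, `"transient"`,
#'   `"passer_by"`.
#' @export
classify_behaviour <- function(daily, window,
                               ri = residency_index(daily, window)) {
  stopifnot(inherits(window, "monitoring_window"))
  days <- sort(unique(daily$day))
  release_day <- local_date(window$start)
  end_day <- local_date(window$end)

  # resident: >=10 detected months in every year-block that spans >=10
  # months, and RI strictly > 0.30
  if (ri > 0.30 && length(days)) {
    block_starts <- seq(release_day, end_day, by = 365)
    ok <- TRUE
    for (bs in seq_along(block_starts)) {
      b0 <- block_starts[bs]
      b1 <- min(b0 + 364, end_day)
      if (months_spanned(b0, b1) < 10) next
      got <- length(unique(format(days[days >= b0 & days <= b1], "%Y-%m")))
      if (got < 10) { ok <- FALSE; break }
    }
    if (ok) return("resident")
  }

  # pseudo-resident: some calendar year with >=3 months each holding >=5
  # detected days, and RI strictly < 0.30
  if (ri < 0.30 && length(days)) {
    per_month <- table(format(days, "%Y-%m"))
    yrs <- substr(names(per_month), 1, 4)
    good_months <- tapply(per_month >= 5, yrs, sum)
    if (any(good_months >= 3)) return("pseudo_resident")
  }

  # transient: any re-detection after a gap > 31 days (from the previous
  # detected day or from release)
  if (length(days)) {
    gaps <- diff(as.integer(c(release_day, days)))
    if (any(gaps > 31)) return("transient")
  }

  # passer-by: nothing detected after day 31 post-release
  if (!length(days) || max(days) <= release_day + 31) return("passer_by")

  "transient"
}

#' Per-tag, per-array residency summary
#'
#' Computes the standard acoustic-monitoring summary: days monitored
#' (release to last detection), distinct detected days, detection count,
#' mean gap between successive detected days, Residency Index and the
#' behaviour label.
#'
#' @param detections detections data.frame (any number of tags).
#' @param tags tag table (as from [read_tags()]).
#' @param receivers receiver table.
#' @param utc_offset_hours fixed offset used to assign calendar days.
#' @return data.frame with one row per (tag, array) with detections, plus
#'   one row (`array_name` `NA`) per tag never detected.
#' @export
residency_summary <- function(detections, tags, receivers,
                              utc_offset_hours = 0) {
  out <- list()
  for (k in seq_len(nrow(tags))) {
    tag <- tags[k, , drop = FALSE]
    win <- monitoring_window(tag, receivers)
    det_k <- detections[detections$tag_id == tag$tag_id, , drop = FALSE]
    daily_all <- daily_detections(det_k, receivers, win, utc_offset_hours)
    arrays <- unique(daily_all$array_name)
    if (!length(arrays)) {
      out[[length(out) + 1L]] <- data.frame(
        tag_id = tag$tag_id, array_name = NA_character_,
        days_monitored = 0L, days_detected = 0L, n_detections = 0L,
        mean_gap_days = NA_real_, residency_index = 0,
        behaviour = "passer_by", stringsAsFactors = FALSE)
      next
    }
    for (a in arrays) {
      daily <- daily_all[daily_all$array_name == a, , drop = FALSE]
      days <- sort(unique(daily$day))
      ri <- residency_index(daily, win)
      recs <- receivers$receiver_id[receivers$array_name == a]
      det_a <- det_k[det_k$receiver_id %in% recs, , drop = FALSE]
      last <- max(det_a$timestamp)
      out[[length(out) + 1L]] <- data.frame(
        tag_id = tag$tag_id, array_name = a,
        days_monitored = as.integer(round(as.numeric(
          difftime(last, win$start, units = "days")))),
        days_detected = length(days),
        n_detections = nrow(det_a),
        mean_gap_days = if (length(days) > 1)
          mean(diff(as.integer(days))) else NA_real_,
        residency_index = ri,
        behaviour = classify_behaviour(daily, win, ri),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
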