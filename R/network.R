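# Station-level movement summaries: visits (bouts of detections at one
# receiver), directed transitions between receivers, per-receiver detection
# proportions, and maximum linear distances between detection sites.

#' Group detections into station visits
#'
#' Consecutive detections of a tag at the same receiver separated by no
#' more than `gap_threshold_min` minutes merge into one visit; a receiver
#' change or a longer gap starts a new visit. A single-detection visit gets
#' a floor duration of 1 minute.
#'
#' @param detections time-sorted detections data.frame.
#' @param gap_threshold_min gap (minutes) above which a visit is broken.
#' @return data.frame (`tag_id`, `receiver_id`, `start`, `end`,
#'   `n_detections`, `duration_min`), in time order within tag.
#' @export
build_visits <- function(detections, gap_threshold_min = 30) {
  if (!nrow(detections))
    return(data.frame(tag_id = character(), receiver_id = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      n_detections = integer(), duration_min = numeric(),
                      stringsAsFactors = FALSE))
  df <- detections[order(detections$tag_id, detections$timestamp), ,
                   drop = FALSE]
  gap_s <- c(Inf, diff(as.numeric(df$timestamp)))
  new_visit <- c(TRUE, df$tag_id[-1] != df$tag_id[-nrow(df)] |
                   df$receiver_id[-1] != df$receiver_id[-nrow(df)]) |
    gap_s > gap_threshold_min * 60
  vid <- cumsum(new_visit)
  first <- !duplicated(vid)
  out <- data.frame(
    tag_id = df$tag_id[first], receiver_id = df$receiver_id[first],
    start = df$timestamp[first],
    end = as.POSIXct(tapply(as.numeric(df$timestamp), vid, max),
                     origin = "1970-01-01", tz = "UTC"),
    n_detections = as.integer(tapply(vid, vid, length)),
    stringsAsFactors = FALSE, row.names = NULL)
  out$duration_min <- pmax(1, as.numeric(out$end - out$start, units = "mins"))
  out
}

#' Directed transitions and detection proportions
#'
#' Counts a directed edge for every ordered pair of successive visits at
#' different receivers (within tag), and computes per-receiver detection
#' proportions (detection counts over the tag's total; a probability
#' vector).
#'
#' @param visits a [build_visits()] table (typically one tag).
#' @return list of class `transition_summary` with `edges` (data.frame
#'   `from`, `to`, `count`) and `proportions` (named numeric vector
#'   summing to 1).
#' @export
transitions <- function(visits) {
  edges <- data.frame(from = character(), to = character(),
                      count = integer(), stringsAsFactors = FALSE)
  if (nrow(visits) >= 2) {
    same_tag <- visits$tag_id[-1] == visits$tag_id[-nrow(visits)]
    from <- visits$receiver_id[-nrow(visits)][same_tag]
    to <- visits$receiver_id[-1][same_tag]
    keep <- from != to
    if (any(keep)) {
      tab <- table(from = from[keep], to = to[keep])
      edges <- as.data.frame(tab, stringsAsFactors = FALSE)
      names(edges) <- c("from", "to", "count")
      edges <- edges[edges$count > 0, , drop = FALSE]
      edges$count <- as.integer(edges$count)
      rownames(edges) <- NULL
    }
  }
  props <- numeric(0)
  if (nrow(visits)) {
    tot <- tapply(visits$n_detections, visits$receiver_id, sum)
    props <- as.numeric(tot) / sum(visits$n_detections)
    names(props) <- names(tot)
  }
  structure(list(edges = edges, proportions = props),
            class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("transition summary: %d directed edge(s), %d receiver(s)\n",
              nrow(x$edges), length(x$proportions)))
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

#' Maximum linear distance between detection sites
#'
#' Maximum pairwise great-circle distance over the set of receivers with at
#' least one detection, optionally including the release point. Invariant
#' to detection multiplicity: only the set of stations matters.
#'
#' @param detections detections data.frame (one tag).
#' @param receivers receiver table; every detected receiver must be known.
#' @param release_point optional c(lon, lat) of the release location.
#' @return distance in km (0 for a single co-located site; `NA` if there
#'   are no detections and no release point pair).
#' @export
max_linear_distance <- function(detections, receivers, release_point = NULL) {
  ids <- unique(detections$receiver_id)
  i <- match(ids, receivers$receiver_id)
  if (anyNA(i))
    stop_ct("unknown receiver id(s): %s", paste(ids[is.na(i)], collapse = ", "))
  pts <- cbind(receivers$lon[i], receivers$lat[i])
  if (!is.null(release_point)) pts <- rbind(pts, release_point)
  if (nrow(pts) < 2) return(0)
  dmax <- 0
  for (a in seq_len(nrow(pts) - 1)) {
    d <- haversine_km(pts[a, 1], pts[a, 2],
                      pts[(a + 1):nrow(pts), 1], pts[(a + 1):nrow(pts), 2])
    dmax <- max(dmax, d)
  }
  dmax
}
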