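# Post-geolocation track utilities: simplified bathymetric correction,
# displacement metrics, and archival depth-temperature summaries.

locate_cell <- function(grid, lon, lat) {
  i <- findInterval(lon, grid$lon, all.inside = TRUE)
  j <- findInterval(lat, grid$lat, all.inside = TRUE)
  # snap to the nearer axis value
  i <- ifelse(i < length(grid$lon) &
                abs(grid$lon[i + 1] - lon) < abs(grid$lon[i] - lon), i + 1L, i)
  j <- ifelse(j < length(grid$lat) &
                abs(grid$lat[j + 1] - lat) < abs(grid$lat[j] - lat), j + 1L, j)
  cbind(i, j)
}

#' Bathymetric track correction
#'
#' Geolocated positions are implausible where the charted seafloor is
#' shallower than the shark's maximum daily dive depth. Each such point is
#' relocated to the nearest grid cell (great-circle) whose seafloor depth
#' accommodates the dive, searching within `search_radius_km` (capped by
#' the point's confidence radius `ci_radius_km` when present). Points
#' already consistent are unchanged; points with no feasible cell in range
#' are flagged and left in place. The operation is idempotent.
#'
#' @param track data.frame with `lon`, `lat`, `max_daily_depth_m` (and
#'   optionally `ci_radius_km`).
#' @param bathy a `bathymetry_grid`.
#' @param search_radius_km maximum relocation distance in km.
#' @return the track with corrected `lon`/`lat` plus `corrected` and
#'   `infeasible` logical columns and `displacement_km` (relocation
#'   distance).
#' @export
bathymetric_correct <- function(track, bathy, search_radius_km = 50) {
  stopifnot(inherits(bathy, "bathymetry_grid"))
  if (any(track$lon < min(bathy$lon) | track$lon > max(bathy$lon) |
            track$lat < min(bathy$lat) | track$lat > max(bathy$lat)))
    stop_ct("track extends outside the bathymetry grid")
  cells <- expand.grid(lon = bathy$lon, lat = bathy$lat,
                       KEEP.OUT.ATTRS = FALSE)
  cell_depth <- as.vector(bathy$depth_m)
  out <- track
  out$corrected <- FALSE
  out$infeasible <- FALSE
  out$displacement_km <- 0
  for (k in seq_len(nrow(track))) {
    need <- track$max_daily_depth_m[k]
    if (is.na(need) || need <= 0) next
    ij <- locate_cell(bathy, track$lon[k], track$lat[k])
    if (bathy$depth_m[ij[1], ij[2]] >= need) next
    radius <- search_radius_km
    if (!is.null(track$ci_radius_km) && !is.na(track$ci_radius_km[k]))
      radius <- min(radius, track$ci_radius_km[k])
    ok <- which(cell_depth >= need)
    if (length(ok)) {
      d <- haversine_km(track$lon[k], track$lat[k], cells$lon[ok], cells$lat[ok])
      feasible <- ok[d <= radius]
      if (length(feasible)) {
        best <- feasible[which.min(d[d <= radius])]
        out$lon[k] <- cells$lon[best]
        out$lat[k] <- cells$lat[best]
        out$corrected[k] <- TRUE
        out$displacement_km[k] <- min(d[d <= radius])
        next
      }
    }
    out$infeasible[k] <- TRUE
  }
  out
}

#' Maximum displacement from the release point
#'
#' @param track data.frame with `lon`, `lat`.
#' @param release_point c(lon, lat).
#' @return maximum great-circle distance (km) from release over all track
#'   points.
#' @export
displacement_from_release <- function(track, release_point) {
  if (!nrow(track)) stop_ct("track must be non-empty")
  max(haversine_km(release_point[1], release_point[2], track$lon, track$lat))
}

modal_bin <- function(x, width) {
  centers <- round(x / width) * width
  tab <- table(centers)
  best <- as.numeric(names(tab)[tab == max(tab)])
  min(best)  # ties resolve to the shallowest / coolest bin
}

#' Depth-temperature archive summary
#'
#' Max/min/mean statistics plus modal values, where the mode is the centre
#' of the most-populated bin (default half-metre depth bins and 0.1 degree
#' temperature bins; ties go to the shallowest/coolest bin).
#'
#' @param series data.frame with `depth_m` and `temp_c`.
#' @param depth_bin_m depth bin width (m).
#' @param temp_bin_c temperature bin width (degrees C).
#' @return one-row data.frame of summary statistics.
#' @export
depth_temp_summary <- function(series, depth_bin_m = 0.5, temp_bin_c = 0.1) {
  if (!nrow(series)) stop_ct("series must be non-empty")
  data.frame(
    max_depth_m = max(series$depth_m),
    modal_depth_m = modal_bin(series$depth_m, depth_bin_m),
    mean_depth_m = mean(series$depth_m),
    max_temp_c = max(series$temp_c),
    min_temp_c = min(series$temp_c),
    modal_temp_c = modal_bin(series$temp_c, temp_bin_c),
    mean_temp_c = mean(series$temp_c),
    depth_bin_m = depth_bin_m, temp_bin_c = temp_bin_c)
}
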