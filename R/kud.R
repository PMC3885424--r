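# Three-dimensional kernel utilisation distributions over (easting,
# northing, depth) in km, with highest-density-region volume contours.
#
# The estimator is a product-Gaussian KDE on a regular 3D grid with a
# diagonal bandwidth matrix: each axis gets its own univariate plug-in
# (Sheather-Jones) bandwidth, or the d = 3 normal-scale rule. A separate
# depth bandwidth matters because depth spans ~1 km while horizontal
# movements span hundreds.

#' Project lon/lat/depth points to local azimuthal-equidistant km
#'
#' Spherical azimuthal-equidistant projection about an origin (radius
#' 6371 km): distances and bearings from the origin are preserved exactly
#' and the map is exactly invertible, so round-trip error is limited only
#' by floating point. Depth converts from metres to km, positive down.
#'
#' @param points data.frame or matrix with columns `lon`, `lat`,
#'   `depth_m`.
#' @param origin c(lon, lat) projection origin.
#' @return matrix with columns `x` (km east), `y` (km north), `z` (km
#'   down).
#' @export
project_points <- function(points, origin) {
  pts <- as.data.frame(points)
  rad <- pi / 180
  p0 <- origin * rad
  lam <- pts$lon * rad; phi <- pts$lat * rad
  dlam <- lam - p0[1]
  # angular distance and initial bearing from the origin
  cc <- acos(pmin(pmax(sin(p0[2]) * sin(phi) +
                         cos(p0[2]) * cos(phi) * cos(dlam), -1), 1))
  az <- atan2(sin(dlam) * cos(phi),
              cos(p0[2]) * sin(phi) - sin(p0[2]) * cos(phi) * cos(dlam))
  r <- 6371 * cc
  cbind(x = r * sin(az), y = r * cos(az), z = pts$depth_m / 1000)
}

#' Inverse of [project_points()]
#'
#' @param xyz matrix with columns `x`, `y`, `z` (km).
#' @param origin c(lon, lat) projection origin.
#' @return data.frame with `lon`, `lat`, `depth_m`.
#' @export
unproject_points <- function(xyz, origin) {
  rad <- pi / 180
  p0 <- origin * rad
  r <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  cc <- r / 6371
  az <- atan2(xyz[, 1], xyz[, 2])
  phi <- asin(pmin(pmax(sin(p0[2]) * cos(cc) +
                          cos(p0[2]) * sin(cc) * cos(az), -1), 1))
  lam <- p0[1] + atan2(sin(az) * sin(cc) * cos(p0[2]),
                       cos(cc) - sin(p0[2]) * sin(phi))
  out <- data.frame(lon = lam / rad, lat = phi / rad,
                    depth_m = xyz[, 3] * 1000)
  out$lon[r < 1e-12] <- origin[1]
  out$lat[r < 1e-12] <- origin[2]
  out
}

axis_bandwidth <- function(v, method) {
  s <- sd(v)
  if (!is.finite(s) || s < 1e-8) return(1e-3)  # degenerate axis floor (km)
  if (method == "plugin_diagonal") {
    h <- tryCatch(bw.SJ(v, method = "dpi"), error = function(e) NA_real_)
    if (is.finite(h) && h > 0) return(h)
  }
  s * (4 / (5 * length(v)))^(1 / 7)  # normal-scale, d = 3
}

#' Fit a 3D kernel utilisation distribution
#'
#' Product-Gaussian kernel density estimate of space use on a regular
#' `grid_n`^3 grid padded by `pad_sd` bandwidths beyond the data extent on
#' every axis, normalised so density times cell volume sums to one.
#'
#' @param points_km numeric matrix (or data.frame) of n x 3 coordinates in
#'   km (see [project_points()]); n must be at least 10 and at least one
#'   axis must have positive spread.
#' @param bandwidth_method `"plugin_diagonal"` (univariate Sheather-Jones
#'   plug-in per axis; the default) or `"normal_scale"` (Silverman-type
#'   rule for d = 3).
#' @param grid_n grid points per axis.
#' @param pad_sd grid padding in bandwidth SDs per axis.
#' @param h optional fixed per-axis bandwidth vector (km), overriding the
#'   selector.
#' @return object of class `kud3d`: list with `density` (3D array), axis
#'   vectors `x`, `y`, `z`, `h` (per-axis bandwidths, km), `cell_km3`,
#'   `n`, `bandwidth_method`.
#' @export
fit_kud <- function(points_km,
                    bandwidth_method = c("plugin_diagonal", "normal_scale"),
                    grid_n = 64, pad_sd = 3, h = NULL) {
  bandwidth_method <- match.arg(bandwidth_method)
  pts <- as.matrix(points_km)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3) stop_ct("points_km must have 3 columns")
  if (nrow(pts) < 10) stop_ct("need at least 10 points to fit a 3D KUD")
  if (all(apply(pts, 2, sd) < 1e-8))
    stop_ct("zero variance on all axes; no density to estimate")
  if (is.null(h))
    h <- vapply(seq_len(3), function(j) axis_bandwidth(pts[, j],
                                                       bandwidth_method),
                numeric(1))
  stopifnot(length(h) == 3, all(h > 0))
  axes <- lapply(seq_len(3), function(j)
    seq(min(pts[, j]) - pad_sd * h[j], max(pts[, j]) + pad_sd * h[j],
        length.out = grid_n))
  # separable kernel: contract the n-point kernel matrices axis by axis
  Kx <- outer(axes[[1]], pts[, 1], function(g, p) dnorm(g, p, h[1]))
  Ky <- outer(axes[[2]], pts[, 2], function(g, p) dnorm(g, p, h[2]))
  Kz <- outer(axes[[3]], pts[, 3], function(g, p) dnorm(g, p, h[3]))
  dens <- array(0, dim = c(grid_n, grid_n, grid_n))
  for (k in seq_len(grid_n)) {
    dens[, , k] <- (Kx * rep(Kz[k, ], each = grid_n)) %*% t(Ky)
  }
  dens <- dens / nrow(pts)
  cell <- prod(vapply(axes, function(a) a[2] - a[1], numeric(1)))
  dens <- dens / (sum(dens) * cell)  # renormalise on the finite grid
  structure(list(density = dens, x = axes[[1]], y = axes[[2]], z = axes[[3]],
                 h = h, cell_km3 = cell, n = nrow(pts),
                 bandwidth_method = bandwidth_method), class = "kud3d")
}

#' Highest-density-region volume contour
#'
#' Finds the iso-density threshold `t` such that cells with density >= `t`
#' hold the smallest probability mass at least `mass`, and reports their
#' total volume. This is the kernel-home-range convention for the
#' `mass`x100% utilisation contour.
#'
#' @param kud a fitted [fit_kud()] object.
#' @param mass probability-mass level(s) in (0, 1), e.g. `c(0.5, 0.95)`.
#' @return data.frame (`mass`, `threshold`, `volume_km3`), one row per
#'   level.
#' @export
volume_contour <- function(kud, mass = c(0.5, 0.95)) {
  stopifnot(inherits(kud, "kud3d"))
  if (any(mass <= 0 | mass >= 1)) stop_ct("mass must lie in (0, 1)")
  d <- sort(as.vector(kud$density), decreasing = TRUE)
  cum <- cumsum(d) * kud$cell_km3
  out <- lapply(mass, function(m) {
    k <- which(cum >= m)[1]
    if (is.na(k)) k <- length(d)
    data.frame(mass = m, threshold = d[k], volume_km3 = k * kud$cell_km3)
  })
  do.call(rbind, out)
}

#' Convenience: fit and extract 50/95% volumes
#'
#' @inheritParams fit_kud
#' @param mass probability-mass levels.
#' @return [volume_contour()] table.
#' @export
kud_volumes <- function(points_km, mass = c(0.5, 0.95), ...) {
  volume_contour(fit_kud(points_km, ...), mass)
}

#' @export
print.kud3d <- function(x, ...) {
  cat(sprintf("3D kernel utilisation distribution (%s bandwidth)\n",
              x$bandwidth_method))
  cat(sprintf("  n = %d points, grid %d^3, bandwidths (km): %.3g %.3g %.3g\n",
              x$n, length(x$x), x$h[1], x$h[2], x$h[3]))
  invisible(x)
}

#' @export
summary.kud3d <- function(object, mass = c(0.5, 0.95), ...) {
  vols <- volume_contour(object, mass)
  total <- sum(object$density) * object$cell_km3
  structure(list(kud = object, volumes = vols, total_mass = total),
            class = "summary.kud3d")
}

#' @export
print.summary.kud3d <- function(x, ...) {
  print(x$kud)
  cat(sprintf("  grid mass: %.6f\n", x$total_mass))
  for (i in seq_len(nrow(x$volumes)))
    cat(sprintf("  %2.0f%% volume: %.3g km^3\n", 100 * x$volumes$mass[i],
                x$volumes$volume_km3[i]))
  invisible(x)
}

#' Evaluate the fitted density at new points
#'
#' Trilinear interpolation on the fitted grid; points outside the grid get
#' density 0.
#'
#' @param object a `kud3d` fit.
#' @param newdata n x 3 matrix of km coordinates.
#' @param ... unused.
#' @return numeric density values.
#' @export
predict.kud3d <- function(object, newdata, ...) {
  p <- as.matrix(newdata)
  ax <- list(object$x, object$y, object$z)
  n <- nrow(p)
  out <- numeric(n)
  idx <- frac <- matrix(0, n, 3)
  inside <- rep(TRUE, n)
  for (j in 1:3) {
    a <- ax[[j]]
    inside <- inside & p[, j] >= a[1] & p[, j] <= a[length(a)]
    i <- pmin(pmax(findInterval(p[, j], a), 1L), length(a) - 1L)
    idx[, j] <- i
    frac[, j] <- (p[, j] - a[i]) / (a[i + 1] - a[i])
  }
  for (k in which(inside)) {
    i <- idx[k, ]; f <- frac[k, ]
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
        (if (dz) f[3] else 1 - f[3])
      acc <- acc + w * object$density[i[1] + dx, i[2] + dy, i[3] + dz]
    }
    out[k] <- acc
  }
  out
}

#' Plot marginal horizontal density of a 3D KUD
#'
#' Integrates the density over depth and draws an image with contour
#' overlay in km coordinates.
#'
#' @param x a `kud3d` fit.
#' @param ... passed to [graphics::image()].
#' @export
plot.kud3d <- function(x, ...) {
  dz <- x$z[2] - x$z[1]
  xy <- apply(x$density, c(1, 2), sum) * dz
  image(x$x, x$y, xy, col = hcl.colors(64, "YlGnBu", rev = TRUE),
        xlab = "east (km)", ylab = "north (km)", ...)
  contour(x$x, x$y, xy, add = TRUE, drawlabels = FALSE)
  invisible(x)
}
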