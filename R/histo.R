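#' Serial-section area series for Cavalieri estimation
#'
#' @param positions_mm Ordered anteroposterior section positions in mm
#'   (Bregma-referenced, negative = posterior), strictly monotone.
#' @param areas_mm2 Measured cross-section areas in mm^2 (>= 0).
#' @param thickness_um Physical section thickness in micrometres.
#' @param k Sampling interval: every k-th section analyzed (default 1).
#' @return An object of class `section_series`.
#' @export
section_series <- function(positions_mm, areas_mm2, thickness_um, k = 1) {
  if (length(positions_mm) != length(areas_mm2))
    stop("positions and areas must have equal length")
  if (length(positions_mm) == 0) stop("empty series")
  d <- diff(positions_mm)
  if (length(d) > 0 && !(all(d > 0) || all(d < 0)))
    stop("positions must be strictly monotone")
  if (any(areas_mm2 < 0)) stop("areas must be >= 0")
  if (k < 1) stop("k must be >= 1")
  structure(list(positions_mm = as.numeric(positions_mm),
                 areas_mm2 = as.numeric(areas_mm2),
                 thickness_um = thickness_um, k = as.integer(k)),
            class = "section_series")
}

#' Cavalieri volume estimate
#'
#' `V = sum(areas) * thickness * k`, i.e. each analyzed section stands for
#' `k` physical sections. When more than one section is present, the implied
#' spacing `|diff(positions)|` must be consistent with `thickness * k`.
#'
#' @param series A [section_series()].
#' @param tol Relative tolerance for the spacing consistency check.
#' @return Volume in mm^3.
#' @examples
#' s <- section_series(seq(-2.5, -1, by = 0.15), rep(1.2, 11), 50, k = 3)
#' cavalieri_volume(s)  # 1.2 * 0.15 * 11
#' @export
cavalieri_volume <- function(series, tol = 1e-6) {
  t_mm <- series$thickness_um / 1000
  spacing <- t_mm * series$k
  d <- abs(diff(series$positions_mm))
  if (length(d) > 0 && any(abs(d - spacing) > tol * max(spacing, 1e-12)))
    stop("inconsistent sampling: section spacing does not match thickness * k")
  sum(series$areas_mm2) * spacing
}

#' Heterotopia midpoint and anteroposterior extension
#'
#' The midpoint is halfway between the first and last sections containing
#' the cluster; the AP extension is the span plus one section spacing, so a
#' single-section cluster has extension equal to the spacing. Multiple
#' clusters in one animal are merged into a single heterotopic complex
#' before measuring.
#'
#' @param clusters A list of `c(first_mm, last_mm)` pairs (one per cluster),
#'   or a single such pair.
#' @param section_spacing_mm Spacing between analyzed sections in mm.
#' @return List with `midpoint_mm` and `extension_mm`.
#' @export
heterotopia_geometry <- function(clusters, section_spacing_mm) {
  if (!is.list(clusters)) clusters <- list(clusters)
  firsts <- vapply(clusters, function(cl) min(cl), numeric(1))
  lasts <- vapply(clusters, function(cl) max(cl), numeric(1))
  first <- min(firsts); last <- max(lasts)
  list(midpoint_mm = (first + last) / 2,
       extension_mm = abs(last - first) + section_spacing_mm)
}

#' Interlayer distance, total thickness, and centroid-to-layer distance
#'
#' For dyslaminated CA3 with a double pyramidal layer: the interlayer
#' distance is the mean point-wise separation of the two layer midlines over
#' their common mediolateral support; the total thickness is the mean span
#' between the outer boundaries (including both layers); the
#' centroid-to-layer distance is the minimum (perpendicular) distance from a
#' heterotopia centroid to the layer midline polyline.
#'
#' Polylines are data.frames with columns `x_um`, `y_um`.
#'
#' @param midlines List of two polylines (layer midlines), or NULL.
#' @param boundaries List of two polylines (outer boundaries), or NULL.
#' @param centroid_um `c(x, y)` heterotopia centroid, or NULL.
#' @param layer_polyline Polyline for the centroid distance (defaults to the
#'   first midline).
#' @return List with `interlayer_um`, `thickness_um`, `centroid_distance_um`
#'   (NA where the corresponding input is missing).
#' @export
interlayer_metrics <- function(midlines = NULL, boundaries = NULL,
                               centroid_um = NULL, layer_polyline = NULL) {
  inter <- NA_real_; thick <- NA_real_; cdist <- NA_real_
  if (!is.null(midlines)) inter <- mean_polyline_separation(midlines[[1]], midlines[[2]])
  if (!is.null(boundaries)) thick <- mean_polyline_separation(boundaries[[1]], boundaries[[2]])
  if (!is.null(centroid_um)) {
    if (is.null(layer_polyline)) {
      if (is.null(midlines)) stop("centroid distance requires a layer polyline")
      layer_polyline <- midlines[[1]]
    }
    cdist <- point_polyline_distance(centroid_um, layer_polyline)
  }
  list(interlayer_um = inter, thickness_um = thick, centroid_distance_um = cdist)
}

# mean |y1(x) - y2(x)| over the common x support (linear interpolation)
mean_polyline_separation <- function(p1, p2) {
  lo <- max(min(p1$x_um), min(p2$x_um))
  hi <- min(max(p1$x_um), max(p2$x_um))
  if (!(hi > lo)) stop("no common support")
  xs <- seq(lo, hi, length.out = 512)
  y1 <- stats::approx(p1$x_um, p1$y_um, xout = xs)$y
  y2 <- stats::approx(p2$x_um, p2$y_um, xout = xs)$y
  mean(abs(y1 - y2))
}

# exact minimum distance from a point to a polyline (segment projections)
point_polyline_distance <- function(pt, poly) {
  px <- pt[1]; py <- pt[2]
  x <- poly$x_um; y <- poly$y_um
  if (length(x) == 1) return(sqrt((px - x)^2 + (py - y)^2))
  dmin <- Inf
  for (i in seq_len(length(x) - 1)) {
    dx <- x[i + 1] - x[i]; dy <- y[i + 1] - y[i]
    L2 <- dx^2 + dy^2
    t <- if (L2 > 0) max(0, min(1, ((px - x[i]) * dx + (py - y[i]) * dy) / L2)) else 0
    qx <- x[i] + t * dx; qy <- y[i] + t * dy
    dmin <- min(dmin, sqrt((px - qx)^2 + (py - qy)^2))
  }
  dmin
}
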