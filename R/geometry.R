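# Planar geometry helpers used throughout the pipeline. All coordinates are
# local ENU metres (x east, y north).

#' Test whether points lie inside a closed polygon
#'
#' @param x,y Numeric vectors of point coordinates (m).
#' @param polygon A data frame or matrix with columns `x` and `y` giving the
#'   polygon vertices in order. The polygon is treated as closed; the last
#'   vertex need not repeat the first.
#' @return Logical vector, `TRUE` for points inside the polygon.
#' @export
point_in_polygon <- function(x, y, polygon) {
  polygon <- as_polygon_matrix(polygon)
  pts <- cbind(as.numeric(x), as.numeric(y))
  as.logical(mgcv::in.out(polygon, pts))
}

# Accepts tibble/data.frame with x,y columns or a 2-column matrix.
as_polygon_matrix <- function(polygon) {
  if (is.matrix(polygon)) {
    m <- polygon[, 1:2, drop = FALSE]
  } else {
    m <- cbind(polygon$x, polygon$y)
  }
  storage.mode(m) <- "double"
  # drop a duplicated closing vertex; mgcv::in.out expects an open ring
  n <- nrow(m)
  if (n > 1 && all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  m
}

#' Area of a simple polygon
#'
#' @inheritParams point_in_polygon
#' @return Area in m^2 (non-negative).
#' @export
polygon_area <- function(polygon) {
  m <- as_polygon_matrix(polygon)
  abs(pracma::polyarea(m[, 1], m[, 2]))
}

#' Total length of a polyline
#'
#' @param x,y Numeric vectors of ordered vertex coordinates (m).
#' @return Length in m; 0 for fewer than two vertices.
#' @export
polyline_length <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# Minimum distance from point (px,py) to segment (x1,y1)-(x2,y2); vectorized
# over segments.
dist_point_segments <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 > 0, ((px - x1) * dx + (py - y1) * dy) / len2, 0)
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Minimum distance from points to a polyline
#'
#' Exact point-to-segment minimisation over every segment of the polyline
#' (not nearest-vertex).
#'
#' @param px,py Numeric vectors of query point coordinates (m).
#' @param vx,vy Ordered polyline vertex coordinates (m), at least 2 vertices.
#' @return Numeric vector of minimum distances (m), one per query point.
#' @export
dist_to_polyline <- function(px, py, vx, vy) {
  stopifnot(length(vx) >= 2, length(vx) == length(vy))
  n <- length(vx)
  vapply(seq_along(px), function(i) {
    min(dist_point_segments(px[i], py[i],
                            vx[-n], vy[-n], vx[-1], vy[-1]))
  }, numeric(1))
}

# Resample a piecewise-linear path (waypoints) at arc-length positions s.
interp_along_path <- function(wx, wy, s) {
  seg <- sqrt(diff(wx)^2 + diff(wy)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- pmin(pmax(s, 0), total)
  x <- approx(cum, wx, xout = s, ties = "ordered")$y
  y <- approx(cum, wy, xout = s, ties = "ordered")$y
  tibble(s = s, x = x, y = y)
}
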