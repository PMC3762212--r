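# Planar geometry helpers for membrane polylines and dense-projection
# polygons. All coordinates are nm in the section plane.

#' Distance from points to a polyline
#'
#' Minimum Euclidean distance from one or more points to an open polyline,
#' together with the arc-length coordinate of the closest point (the
#' "foot point") along the polyline.
#'
#' @param x,y Numeric vectors of point coordinates (nm).
#' @param polyline Two-column numeric matrix of polyline vertices, in order.
#' @return A tibble with one row per point: `distance` (nm), `s` (arc-length
#'   coordinate of the foot point, nm from the first vertex), `foot_x`,
#'   `foot_y`.
#' @export
dist_to_polyline <- function(x, y, polyline) {
  stopifnot(is.matrix(polyline), ncol(polyline) == 2)
  if (nrow(polyline) < 2) {
    stop("polyline must have at least 2 points", call. = FALSE)
  }
  ax <- polyline[-nrow(polyline), 1]; ay <- polyline[-nrow(polyline), 2]
  bx <- polyline[-1, 1];              by <- polyline[-1, 2]
  seg_len <- sqrt((bx - ax)^2 + (by - ay)^2)
  cum_s <- c(0, cumsum(seg_len))[seq_along(seg_len)]
  n <- length(x)
  dx <- bx - ax; dy <- by - ay
  denom <- pmax(dx^2 + dy^2, .Machine$double.xmin)
  # points x segments matrices; rows are points (column recycling of x, y)
  px <- outer(x, ax, "-"); py <- outer(y, ay, "-")
  tpar <- (sweep(px, 2, dx, "*") + sweep(py, 2, dy, "*"))
  tpar <- sweep(tpar, 2, denom, "/")
  tpar[tpar < 0] <- 0; tpar[tpar > 1] <- 1
  fx <- sweep(sweep(tpar, 2, dx, "*"), 2, ax, "+")
  fy <- sweep(sweep(tpar, 2, dy, "*"), 2, ay, "+")
  d2 <- (x - fx)^2 + (y - fy)^2
  j <- max.col(-d2, ties.method = "first")
  pick <- cbind(seq_len(n), j)
  tibble::tibble(
    distance = sqrt(d2[pick]),
    s = cum_s[j] + tpar[pick] * seg_len[j],
    foot_x = fx[pick], foot_y = fy[pick]
  )
}

#' Distance from points to the edge of a closed polygon
#'
#' The polygon is closed implicitly (last vertex connects back to the
#' first). Distance is to the boundary, not the interior: points inside the
#' polygon get distance 0.
#'
#' @param x,y Numeric vectors of point coordinates (nm).
#' @param polygon Two-column numeric matrix of polygon vertices.
#' @return Numeric vector of distances (nm), 0 for interior points.
#' @export
dist_to_polygon_edge <- function(x, y, polygon) {
  stopifnot(is.matrix(polygon), ncol(polygon) == 2)
  closed <- rbind(polygon, polygon[1, , drop = FALSE])
  d <- dist_to_polyline(x, y, closed)$distance
  inside <- point_in_polygon(x, y, polygon)
  d[inside] <- 0
  d
}

# Even-odd ray-casting point-in-polygon test, vectorized over points.
point_in_polygon <- function(x, y, polygon) {
  px <- polygon[, 1]; py <- polygon[, 2]
  n <- nrow(polygon)
  inside <- logical(length(x))
  j <- n
  for (k in seq_len(n)) {
    dyk <- py[j] - py[k]
    crosses <- (py[k] > y) != (py[j] > y)
    if (any(crosses)) {
      xint <- (px[j] - px[k]) * (y - py[k]) / dyk + px[k]
      hit <- crosses & (x < xint)
      inside <- xor(inside, hit)
    }
    j <- k
  }
  inside
}

# Total arc length of a polyline.
polyline_length <- function(polyline) {
  sum(sqrt(diff(polyline[, 1])^2 + diff(polyline[, 2])^2))
}
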