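# Planar geometric primitives shared by all estimators. Everything is
# Cartesian: unitless coordinates in simulations, metres for field data.
# Bearings are geographic throughout: 0 deg = north, increasing clockwise.

#' Construct a polygon
#'
#' A simple polygon with an optional set of interior holes. Rings are stored
#' as two-column matrices (x, y), unclosed (first vertex not repeated). The
#' exterior ring is normalised to counter-clockwise orientation, holes to
#' clockwise.
#'
#' @param exterior Two-column matrix or data frame of exterior-ring vertices.
#' @param holes Optional list of hole rings in the same format.
#' @param validate Check rings for self-intersection (O(n^2); skip for
#'   trusted internal constructions).
#' @return An object of class `polygon2`.
#' @export
polygon2 <- function(exterior, holes = list(), validate = TRUE) {
  exterior <- as_ring(exterior)
  holes <- lapply(holes, as_ring)
  if (validate) {
    if (!is_simple_ring(exterior)) {
      abort("exterior ring is self-intersecting", class = "territr_invalid_geometry")
    }
    for (h in holes) {
      if (!is_simple_ring(h)) {
        abort("hole ring is self-intersecting", class = "territr_invalid_geometry")
      }
    }
  }
  if (ring_signed_area(exterior) < 0) exterior <- exterior[rev(seq_len(nrow(exterior))), , drop = FALSE]
  holes <- lapply(holes, function(h) {
    if (ring_signed_area(h) > 0) h[rev(seq_len(nrow(h))), , drop = FALSE] else h
  })
  structure(list(exterior = exterior, holes = holes), class = "polygon2")
}

as_ring <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y")])
  x <- unname(as.matrix(x))
  stopifnot(ncol(x) == 2, nrow(x) >= 3)
  if (!all(is.finite(x))) abort("ring coordinates must be finite",
                                class = "territr_invalid_geometry")
  # drop a closing vertex if present
  if (all(abs(x[1, ] - x[nrow(x), ]) < 1e-12)) x <- x[-nrow(x), , drop = FALSE]
  x
}

ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Segment-pair simplicity check; adjacent segments share an endpoint.
is_simple_ring <- function(ring) {
  if (nrow(ring) < 3) return(FALSE)
  length(ring_first_self_intersection_cpp(ring)) == 0
}

segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- crossp(p4 - p3, p1 - p3)
  d2 <- crossp(p4 - p3, p2 - p3)
  d3 <- crossp(p2 - p1, p3 - p1)
  d4 <- crossp(p2 - p1, p4 - p1)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  FALSE
}

crossp <- function(u, v) u[1] * v[2] - u[2] * v[1]

#' @export
print.polygon2 <- function(x, ...) {
  cat(sprintf("<polygon2> %d exterior vertices, %d hole(s), area %.6g\n",
              nrow(x$exterior), length(x$holes), polygon_area(x)))
  invisible(x)
}

#' @export
tidy.polygon2 <- function(x, ...) {
  rings <- c(list(x$exterior), x$holes)
  purrr::map_dfr(seq_along(rings), function(i) {
    tibble(ring = if (i == 1) "exterior" else paste0("hole", i - 1),
           x = rings[[i]][, 1], y = rings[[i]][, 2])
  })
}

#' Polygon area
#'
#' Shoelace area of the exterior ring minus the area of any holes.
#'
#' @param poly A [polygon2] object (or a bare ring matrix).
#' @return Non-negative scalar area.
#' @export
polygon_area <- function(poly) {
  if (!inherits(poly, "polygon2")) poly <- polygon2(poly, validate = FALSE)
  a <- abs(ring_signed_area(poly$exterior))
  if (length(poly$holes)) {
    a <- a - sum(vapply(poly$holes, function(h) abs(ring_signed_area(h)), 0))
  }
  a
}

#' Area-weighted polygon centroid
#'
#' @param poly A [polygon2] (holes are accounted for).
#' @return Length-2 numeric vector (x, y).
#' @export
polygon_centroid <- function(poly) {
  if (!inherits(poly, "polygon2")) poly <- polygon2(poly, validate = FALSE)
  ring_cent <- function(r) {
    x <- r[, 1]; y <- r[, 2]
    j <- c(seq_len(nrow(r))[-1], 1L)
    cr <- x * y[j] - x[j] * y
    a <- sum(cr) / 2
    c(sum((x + x[j]) * cr) / 6, sum((y + y[j]) * cr) / 6, a)
  }
  parts <- lapply(c(list(poly$exterior), poly$holes), ring_cent)
  sx <- sum(vapply(parts, `[`, 0, 1))
  sy <- sum(vapply(parts, `[`, 0, 2))
  sa <- sum(vapply(parts, `[`, 0, 3))
  c(x = sx / sa, y = sy / sa)
}

#' Point-in-polygon test
#'
#' Even-odd rule; points on any ring boundary count as inside.
#'
#' @param poly A [polygon2].
#' @param x,y Numeric vectors of point coordinates (recycled as a pair), or
#'   `x` may be a two-column matrix / data frame of points.
#' @param tol Boundary tolerance.
#' @return Logical vector.
#' @export
contains <- function(poly, x, y = NULL, tol = 1e-9) {
  if (!inherits(poly, "polygon2")) poly <- polygon2(poly, validate = FALSE)
  if (is.null(y)) {
    if (is.data.frame(x)) { y <- x$y; x <- x$x } else { y <- x[, 2]; x <- x[, 1] }
  }
  res <- points_in_ring_cpp(x, y, poly$exterior, tol)
  inside <- res >= 1L
  on_bnd <- res == 2L
  for (h in poly$holes) {
    hr <- points_in_ring_cpp(x, y, h, tol)
    on_bnd <- on_bnd | hr == 2L
    inside <- inside & !(hr == 1L)
  }
  inside | on_bnd
}

#' Convert a geographic bearing to a unit direction vector
#'
#' Bearings are geographic: 0 deg = north (+y), increasing clockwise, so
#' 90 deg = east (+x).
#'
#' @param bearing_deg Bearing in degrees.
#' @return Two-column matrix of unit vectors (dx, dy).
#' @export
bearing_to_vec <- function(bearing_deg) {
  th <- bearing_deg * pi / 180
  cbind(dx = sin(th), dy = cos(th))
}

#' Outermost ray-boundary intersection
#'
#' Casts a ray from an interior origin along a geographic bearing and returns
#' its intersection with the exterior ring. For boundaries a ray crosses more
#' than once (concave shapes) the outermost crossing is returned by default,
#' matching trial endpoints placed along the outer edge of a territory; set
#' `crossing = "first"` for the nearest one.
#'
#' @param poly A [polygon2].
#' @param origin Length-2 numeric (x, y), strictly inside `poly`.
#' @param bearing_deg Geographic bearing of the ray, degrees.
#' @param crossing `"outermost"` (default) or `"first"`.
#' @return Named numeric vector (x, y) on the exterior ring.
#' @export
ray_outermost_intersection <- function(poly, origin, bearing_deg,
                                       crossing = c("outermost", "first")) {
  crossing <- match.arg(crossing)
  if (!inherits(poly, "polygon2")) poly <- polygon2(poly, validate = FALSE)
  if (!contains(poly, origin[1], origin[2])) {
    abort("ray origin must lie inside the polygon", class = "territr_domain_error")
  }
  d <- drop(bearing_to_vec(bearing_deg))
  t <- ray_ring_params(poly$exterior, origin, d)
  if (!length(t)) abort("ray does not intersect the exterior ring",
                        class = "territr_internal_error")
  tt <- if (crossing == "outermost") max(t) else min(t)
  c(x = origin[1] + tt * d[1], y = origin[2] + tt * d[2])
}

# All positive ray parameters t where origin + t*d meets ring segments.
ray_ring_params <- function(ring, origin, d) {
  n <- nrow(ring)
  a <- ring
  b <- ring[c(2:n, 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  denom <- d[1] * ey - d[2] * ex
  wx <- a[, 1] - origin[1]; wy <- a[, 2] - origin[2]
  t <- (wx * ey - wy * ex) / denom
  s <- (wx * d[2] - wy * d[1]) / denom
  ok <- is.finite(t) & is.finite(s) & t > 1e-12 & s >= -1e-12 & s <= 1 + 1e-12
  t[ok]
}

# Affine helpers used by the shape constructors.
scale_ring <- function(ring, factor, about) {
  sweep(sweep(ring, 2, about, `-`) * factor, 2, about, `+`)
}

translate_ring <- function(ring, by) sweep(ring, 2, by, `+`)

#' Delaunay triangulation of a planar point set
#'
#' Bowyer-Watson construction. A deterministic relative jitter (~1e-9 of the
#' data span) enforces general position for near-cocircular inputs such as
#' equiangular boundary points; it is far below every tolerance used
#' downstream.
#'
#' @param points Data frame or matrix with columns x, y.
#' @return Integer matrix, one counter-clockwise triangle (vertex indices)
#'   per row.
#' @export
delaunay <- function(points) {
  xy <- as_xy(points)
  if (nrow(xy) < 3) abort("need at least 3 points", class = "territr_degenerate_input")
  delaunay_cpp(xy[, 1], xy[, 2])
}

as_xy <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "y") %in% names(points)))
    cbind(points$x, points$y)
  } else {
    m <- unname(as.matrix(points))
    stopifnot(ncol(m) == 2)
    m
  }
}
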