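# Polygon estimators that connect points: the minimum convex polygon and the
# detailed (characteristic/concave) hull obtained by peeling long boundary
# edges off the Delaunay triangulation.

new_hull_estimate <- function(polygon, method, params, n_points) {
  structure(list(polygon = polygon, area = polygon_area(polygon),
                 method = method, params = params, n_points = n_points),
            class = "hull_estimate")
}

#' Minimum convex polygon
#'
#' @param points Data frame (columns `x`, `y`) or two-column matrix of at
#'   least 3 non-collinear points.
#' @return A `hull_estimate` with the hull polygon and its area.
#' @export
mcp <- function(points) {
  xy <- as_xy(points)
  check_noncollinear(xy)
  idx <- chull(xy[, 1], xy[, 2])        # clockwise
  ring <- xy[rev(idx), , drop = FALSE]  # counter-clockwise
  new_hull_estimate(polygon2(ring, validate = FALSE), "MCP", list(),
                    nrow(xy))
}

check_noncollinear <- function(xy) {
  if (nrow(xy) < 3) {
    abort("need at least 3 points", class = "territr_degenerate_input")
  }
  d <- sweep(xy, 2, xy[1, ], `-`)
  cr <- d[, 1] * d[2, 2] - d[, 2] * d[2, 1]
  span <- max(apply(xy, 2, function(v) diff(range(v))), 0)
  if (all(abs(cr) <= 1e-12 * max(span^2, 1))) {
    abort("all points are collinear", class = "territr_degenerate_input")
  }
  invisible(TRUE)
}

#' Detailed (characteristic) hull
#'
#' A concave hull that follows the outline of a point pattern more tightly
#' than the convex polygon. Starting from the union of the Delaunay
#' triangulation, the longest exterior boundary edge is removed iteratively
#' while (a) it is longer than the threshold `lambda` and (b) its removal
#' keeps the boundary a simple polygon with every point on or inside it
#' (the apex of the peeled triangle must not already lie on the boundary).
#' `lambda = "auto"` uses mean + 1 SD of all Delaunay edge lengths;
#' `lambda = Inf` reproduces [mcp()].
#'
#' Ties between equally long boundary edges are broken by the smaller
#' (x, y) lexicographic order of the edge midpoint, for determinism.
#'
#' @param points Data frame or matrix of at least 3 non-collinear points.
#' @param lambda Edge-length threshold, or `"auto"`.
#' @return A `hull_estimate`; `params$lambda` records the resolved
#'   threshold.
#' @export
detailed_hull <- function(points, lambda = "auto") {
  xy <- as_xy(points)
  xy <- unique(xy)
  check_noncollinear(xy)
  tri <- delaunay(xy)
  # edge table: for each undirected edge, the triangles using it
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  elen_all <- sqrt(rowSums((xy[edges[, 1], , drop = FALSE] -
                            xy[edges[, 2], , drop = FALSE])^2))
  if (identical(lambda, "auto") || identical(lambda, "AUTO")) {
    ulen <- elen_all[!duplicated(ekey)]
    lambda <- mean(ulen) + sd(ulen)
  }
  stopifnot(is.numeric(lambda), lambda >= 0)

  ntri <- nrow(tri)
  alive <- rep(TRUE, ntri)
  tri_of_edge <- split(rep(seq_len(ntri), 3), ekey)
  repeat {
    live_tri <- which(alive)
    if (length(live_tri) <= 1) break
    e_live <- rbind(tri[live_tri, c(1, 2), drop = FALSE],
                    tri[live_tri, c(2, 3), drop = FALSE],
                    tri[live_tri, c(3, 1), drop = FALSE])
    k_live <- paste(pmin(e_live[, 1], e_live[, 2]),
                    pmax(e_live[, 1], e_live[, 2]))
    tab <- table(k_live)
    bkeys <- names(tab)[tab == 1]
    bverts <- unique(as.integer(unlist(strsplit(bkeys, " "))))
    binfo <- do.call(rbind, strsplit(bkeys, " "))
    bi <- as.integer(binfo[, 1]); bj <- as.integer(binfo[, 2])
    blen <- sqrt(rowSums((xy[bi, , drop = FALSE] - xy[bj, , drop = FALSE])^2))
    # candidate edges: longer than lambda and regular (apex off-boundary)
    cand <- which(blen > lambda)
    if (!length(cand)) break
    midx <- (xy[bi[cand], 1] + xy[bj[cand], 1]) / 2
    midy <- (xy[bi[cand], 2] + xy[bj[cand], 2]) / 2
    ord <- cand[order(-blen[cand], midx, midy)]
    removed <- FALSE
    for (ci in ord) {
      key <- bkeys[ci]
      tl <- tri_of_edge[[key]]
      tl <- tl[alive[tl]]
      if (length(tl) != 1) next
      apex <- setdiff(tri[tl, ], c(bi[ci], bj[ci]))
      if (apex %in% bverts) next  # removal would pinch the boundary
      alive[tl] <- FALSE
      removed <- TRUE
      break
    }
    if (!removed) break
  }

  ring <- boundary_ring(tri[alive, , drop = FALSE], xy)
  new_hull_estimate(polygon2(ring, validate = FALSE), "DH",
                    list(lambda = lambda), nrow(xy))
}

# Trace the outer boundary ring of a triangle set (counter-clockwise).
# Collinear field layouts can pinch the triangulated region at a vertex
# (two boundary fans meeting), so the trace is a face walk: at a vertex
# with several outgoing boundary edges the sharpest left turn continues
# the same face. The largest loop by |area| is the outline.
boundary_ring <- function(tri, xy) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bnd <- e[key %in% names(tab)[tab == 1], , drop = FALSE]
  m <- nrow(bnd)
  used <- rep(FALSE, m)
  out_by_from <- split(seq_len(m), bnd[, 1])
  best_path <- NULL
  best_area <- -Inf
  for (i0 in seq_len(m)) {
    if (used[i0]) next
    path <- integer(0)
    cur <- i0
    closed <- FALSE
    for (guard in seq_len(m + 1)) {
      used[cur] <- TRUE
      path <- c(path, cur)
      v <- bnd[cur, 2]
      if (v == bnd[path[1], 1]) { closed <- TRUE; break }
      cand <- out_by_from[[as.character(v)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1) {
        inx <- xy[bnd[cur, 2], 1] - xy[bnd[cur, 1], 1]
        iny <- xy[bnd[cur, 2], 2] - xy[bnd[cur, 1], 2]
        ang_in <- atan2(-iny, -inx)
        cw <- vapply(cand, function(j) {
          ox <- xy[bnd[j, 2], 1] - xy[bnd[j, 1], 1]
          oy <- xy[bnd[j, 2], 2] - xy[bnd[j, 1], 2]
          d <- ang_in - atan2(oy, ox)
          while (d <= 1e-12) d <- d + 2 * pi
          d
        }, 0)
        cand <- cand[which.min(cw)]
      }
      cur <- cand
    }
    if (!closed || length(path) < 3) next
    ring <- xy[bnd[path, 1], , drop = FALSE]
    a <- abs(ring_signed_area(ring))
    if (a > best_area) { best_area <- a; best_path <- path }
  }
  if (is.null(best_path)) {
    abort("could not trace the hull boundary", class = "territr_internal_error")
  }
  xy[bnd[best_path, 1], , drop = FALSE]
}

#' @export
print.hull_estimate <- function(x, ...) {
  p <- if (length(x$params)) {
    paste0(" (", paste(names(x$params),
                       signif(unlist(x$params), 4), sep = "=", collapse = ", "), ")")
  } else ""
  cat(sprintf("<hull_estimate %s%s> %d points, area %.6g\n",
              x$method, p, x$n_points, x$area))
  invisible(x)
}

#' @export
tidy.hull_estimate <- function(x, ...) {
  method <- x$method
  dplyr::mutate(tidy(x$polygon), method = .env$method)
}

#' @export
glance.hull_estimate <- function(x, ...) {
  tibble(method = x$method, area = x$area, n_points = x$n_points,
         lambda = if (!is.null(x$params$lambda)) x$params$lambda else NA_real_)
}

#' Plot a hull estimate over its point pattern
#'
#' @param object A `hull_estimate`.
#' @param points Optional point tibble to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hull_estimate <- function(object, points = NULL, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_polygon(fill = "steelblue", alpha = 0.3, colour = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::labs(subtitle = sprintf("%s, area %.4g", object$method, object$area)) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points, size = 0.6)
  }
  p
}
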