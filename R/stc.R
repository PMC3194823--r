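# The stretch-the-centre (STC) estimator: a parametric kernel of the calling
# positions is reshaped to the outline of the defended area by a
# piecewise-linear "rubbersheet" spatial adjustment. Correction links pull
# the 99% isocline of the central kernel onto the trial endpoints along each
# trial axis; identity links pin every calling position in place. The
# transformation is applied to the isocline polylines, not to the density
# raster (raster warping is known to produce severe artefacts).

#' Build rubbersheet links from trials and a 99% isocline
#'
#' One correction link per trial: the source is the (outermost) intersection
#' of the ray from the trial start along the trial bearing with the 99%
#' isocline; the target is the trial endpoint for responded trials, and the
#' calling (start) position itself for non-responses, so that the boundary
#' is pulled inwards along directions in which the animal claimed no
#' territory. One identity link is added at every calling position
#' (duplicates removed).
#'
#' @param isocline99 A ring matrix or [polygon2]: the 99% isocline of the
#'   central kernel.
#' @param trials Trial-set tibble (see [pair_trials()]); starts must lie
#'   inside the isocline.
#' @param calling_points Optional tibble of calling positions for identity
#'   links; defaults to the trial start points.
#' @return A `link_set` tibble: columns `kind` (`"correction"`/`"identity"`),
#'   `source_x`, `source_y`, `target_x`, `target_y`, `direction_deg`.
#' @export
build_stc_links <- function(isocline99, trials, calling_points = NULL) {
  poly <- if (inherits(isocline99, "polygon2")) isocline99 else
    polygon2(isocline99, validate = FALSE)
  links <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    start <- c(trials$start_x[i], trials$start_y[i])
    if (!contains(poly, start[1], start[2])) {
      abort(sprintf("start of trial %d (individual %s, direction %g) lies outside the 99%% isocline",
                    i, trials$individual[i], trials$direction_deg[i]),
            class = "territr_domain_error")
    }
    src <- ray_outermost_intersection(poly, start, trials$direction_deg[i])
    if (isTRUE(trials$responded[i])) {
      tgt <- c(trials$end_x[i], trials$end_y[i])
    } else {
      tgt <- start
    }
    tibble(kind = "correction", source_x = src[1], source_y = src[2],
           target_x = tgt[1], target_y = tgt[2],
           direction_deg = trials$direction_deg[i])
  })
  if (is.null(calling_points)) {
    calling_points <- tibble(x = trials$start_x, y = trials$start_y)
  }
  cp <- dplyr::distinct(tibble(x = calling_points$x, y = calling_points$y))
  ident <- tibble(kind = "identity", source_x = cp$x, source_y = cp$y,
                  target_x = cp$x, target_y = cp$y, direction_deg = NA_real_)
  out <- dplyr::bind_rows(links, ident)
  class(out) <- c("link_set", class(out))
  out
}

#' Piecewise-linear rubbersheet transformation
#'
#' A TIN (Delaunay) is built over all link source points; the displacement
#' at each node is target - source (zero at identity nodes). Query points
#' inside the triangulation are displaced by barycentric interpolation;
#' points outside by the affine extension of the nearest triangle. Every
#' link source maps exactly onto its target.
#'
#' @param geometry A two-column matrix / data frame of points, a [polygon2],
#'   an `isopleth_set`, or a list of ring matrices.
#' @param links A `link_set` from [build_stc_links()] (>= 3 non-collinear
#'   sources).
#' @return The transformed geometry, same shape as the input.
#' @export
rubbersheet_transform <- function(geometry, links) {
  src <- cbind(links$source_x, links$source_y)
  dsp <- cbind(links$target_x - links$source_x,
               links$target_y - links$source_y)
  dup <- duplicated(round(src, 12))
  src <- src[!dup, , drop = FALSE]
  dsp <- dsp[!dup, , drop = FALSE]
  if (nrow(src) < 3) abort("need at least 3 link sources",
                           class = "territr_ill_posed")
  ok <- tryCatch({ check_noncollinear(src); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort("link sources are collinear: transformation is ill-posed",
                 class = "territr_ill_posed")
  tri <- delaunay(src)

  transform_pts <- function(m) {
    m + tin_interp(m, src, dsp, tri)
  }
  if (inherits(geometry, "polygon2")) {
    polygon2(transform_pts(geometry$exterior),
             holes = lapply(geometry$holes, transform_pts), validate = FALSE)
  } else if (inherits(geometry, "isopleth_set")) {
    geometry$polygons <- lapply(geometry$polygons, function(rings) {
      lapply(rings, transform_pts)
    })
    geometry$areas <- vapply(geometry$polygons, rings_area, 0)
    geometry
  } else if (is.list(geometry) && !is.data.frame(geometry)) {
    lapply(geometry, transform_pts)
  } else {
    xy <- as_xy(geometry)
    out <- transform_pts(xy)
    tibble(x = out[, 1], y = out[, 2])
  }
}

# Insert points lying on (or near) a ring's boundary as ring vertices, each
# on its closest edge, ordered by position along the edge.
insert_ring_vertices <- function(ring, pts) {
  for (i in seq_len(nrow(pts))) {
    n <- nrow(ring)
    nxt <- ring[c(2:n, 1), , drop = FALSE]
    ex <- nxt[, 1] - ring[, 1]; ey <- nxt[, 2] - ring[, 2]
    L2 <- ex^2 + ey^2
    t <- pmin(1, pmax(0, ((pts[i, 1] - ring[, 1]) * ex +
                            (pts[i, 2] - ring[, 2]) * ey) / L2))
    dx <- ring[, 1] + t * ex - pts[i, 1]
    dy <- ring[, 2] + t * ey - pts[i, 2]
    e <- which.min(dx^2 + dy^2)
    if (t[e] > 1e-9 && t[e] < 1 - 1e-9) {
      ring <- rbind(ring[seq_len(e), , drop = FALSE], pts[i, ],
                    if (e < n) ring[(e + 1):n, , drop = FALSE])
    }
  }
  ring
}

# Barycentric interpolation of node displacements over a TIN. Points outside
# the triangulation take the displacement at the nearest point of the
# triangulation (linear interpolation along the nearest edge): a continuous
# extension that is bounded by the node displacements, so no extrapolation
# artefact can exceed the links themselves.
tin_interp <- function(pts, nodes, disp, tri) {
  pts <- as_xy(pts)
  out <- matrix(0, nrow(pts), 2)
  A <- nodes[tri[, 1], , drop = FALSE]
  B <- nodes[tri[, 2], , drop = FALSE]
  C <- nodes[tri[, 3], , drop = FALSE]
  det <- (B[, 1] - A[, 1]) * (C[, 2] - A[, 2]) -
         (C[, 1] - A[, 1]) * (B[, 2] - A[, 2])
  seg_proj <- function(px, py, P, Q) {
    dx <- Q[, 1] - P[, 1]; dy <- Q[, 2] - P[, 2]
    L2 <- pmax(dx^2 + dy^2, 1e-300)
    t <- pmin(1, pmax(0, ((px - P[, 1]) * dx + (py - P[, 2]) * dy) / L2))
    d2 <- (P[, 1] + t * dx - px)^2 + (P[, 2] + t * dy - py)^2
    list(t = t, d2 = d2)
  }
  ev <- cbind(tri[, 1], tri[, 2], tri[, 2], tri[, 3], tri[, 3], tri[, 1])
  for (i in seq_len(nrow(pts))) {
    px <- pts[i, 1]; py <- pts[i, 2]
    w1 <- ((B[, 1] - px) * (C[, 2] - py) - (C[, 1] - px) * (B[, 2] - py)) / det
    w2 <- ((C[, 1] - px) * (A[, 2] - py) - (A[, 1] - px) * (C[, 2] - py)) / det
    w3 <- 1 - w1 - w2
    inside <- which(w1 >= -1e-12 & w2 >= -1e-12 & w3 >= -1e-12)
    if (length(inside)) {
      t <- inside[1]
      out[i, ] <- w1[t] * disp[tri[t, 1], ] + w2[t] * disp[tri[t, 2], ] +
                  w3[t] * disp[tri[t, 3], ]
    } else {
      pAB <- seg_proj(px, py, A, B)
      pBC <- seg_proj(px, py, B, C)
      pCA <- seg_proj(px, py, C, A)
      d2 <- cbind(pAB$d2, pBC$d2, pCA$d2)
      j <- arrayInd(which.min(d2), dim(d2))
      tt <- list(pAB$t, pBC$t, pCA$t)[[j[2]]][j[1]]
      u <- ev[j[1], 2 * j[2] - 1]; v <- ev[j[1], 2 * j[2]]
      out[i, ] <- (1 - tt) * disp[u, ] + tt * disp[v, ]
    }
  }
  out
}

#' Stretch-the-centre territory estimate
#'
#' Fits a fixed bivariate normal kernel at the href bandwidth to the calling
#' positions, extracts its isoclines at the requested levels, builds
#' correction/identity links from the 99% isocline and the trials, and
#' rubbersheets all isoclines with that single link set. The 95% level is
#' the conventional headline territory estimate.
#'
#' @param calling_points Tibble of calling positions (`x`, `y`; n >= 5).
#' @param trials Trial-set tibble; at least 3 responded trials.
#' @param levels Isocline percentages (default 1, 5, ..., 95, 99).
#' @param grid A [grid_spec()].
#' @return An `stc_estimate`: the transformed `isopleth_set` plus the link
#'   set, the central (untransformed) isopleths, the kernel fit, the 95%
#'   area, and a nesting report (violations of isocline nesting after
#'   transformation are detected and reported, not silently accepted).
#' @export
stc_estimate <- function(calling_points, trials,
                         levels = c(1, seq(5, 95, by = 5), 99),
                         grid = grid_spec()) {
  stopifnot(nrow(calling_points) >= 5)
  if (sum(trials$responded) < 3) {
    abort("need at least 3 responded trials", class = "territr_degenerate_input")
  }
  levels <- sort(unique(c(levels, 99)))
  ud <- kde_density(calling_points, selector = "href", grid = grid)
  central <- kde_isopleth(ud, levels)
  i99 <- central$polygons[[match(99, central$levels)]]
  if (!length(i99)) abort("empty 99% isocline", class = "territr_internal_error")
  # use the largest ring as the linking isocline
  main <- i99[[which.max(vapply(i99, function(r) abs(ring_signed_area(r)), 0))]]
  links <- build_stc_links(main, trials, calling_points)
  # insert the exact link sources as vertices of the 99% ring so the
  # transformed polyline interpolates every endpoint, not just passes near it
  src <- cbind(links$source_x, links$source_y)[links$kind == "correction", ,
                                               drop = FALSE]
  main2 <- insert_ring_vertices(main, src)
  central$polygons[[match(99, central$levels)]][[
    which.max(vapply(i99, function(r) abs(ring_signed_area(r)), 0))]] <- main2
  stretched <- rubbersheet_transform(central, links)
  stretched <- repair_isopleths(stretched)
  nest <- check_nesting(stretched)
  structure(list(isopleths = stretched, links = links, central = central,
                 ud = ud, area_95 = isopleth_area_at(stretched, 95),
                 nesting_ok = nest$ok, nesting_report = nest$report),
            class = "stc_estimate")
}

# Self-intersecting transformed rings are repaired by dropping the smaller
# loop (buffer(0)-style cleaning) with a warning.
repair_isopleths <- function(iso) {
  for (i in seq_along(iso$polygons)) {
    iso$polygons[[i]] <- lapply(iso$polygons[[i]], function(r) {
      if (is_simple_ring(r)) r else {
        warn(sprintf("self-intersecting %g%% isocline repaired", iso$levels[i]))
        repair_ring(r)
      }
    })
  }
  iso$areas <- vapply(iso$polygons, rings_area, 0)
  iso
}

# Remove the smaller lobe at each self-intersection by keeping the longest
# simple sub-ring.
repair_ring <- function(r) {
  n <- nrow(r)
  ij <- ring_first_self_intersection_cpp(r)
  if (!length(ij)) return(r)
  i <- ij[1]; j <- ij[2]
  inner <- r[(i + 1):j, , drop = FALSE]
  outer <- r[c(if (j < n) (j + 1):n else integer(0), 1:i), , drop = FALSE]
  keep <- if (nrow(inner) >= nrow(outer)) inner else outer
  if (nrow(keep) >= 3) repair_ring(keep) else r
}

check_nesting <- function(iso) {
  lv <- iso$levels
  ok <- TRUE
  msgs <- character(0)
  for (i in seq_along(lv)[-1]) {
    small <- iso$polygons[[i - 1]]
    big <- iso$polygons[[i]]
    if (!length(small) || !length(big)) next
    for (r in small) {
      inside <- vapply(big, function(bb) {
        all(points_in_ring_cpp(r[, 1], r[, 2], bb, 1e-9) >= 1L)
      }, TRUE)
      if (!any(inside)) {
        ok <- FALSE
        msgs <- c(msgs, sprintf("level %g not nested inside level %g",
                                lv[i - 1], lv[i]))
        break
      }
    }
  }
  list(ok = ok, report = msgs)
}

#' @export
print.stc_estimate <- function(x, ...) {
  cat(sprintf("<stc_estimate> 95%% area %.6g, %d correction link(s), nesting %s\n",
              x$area_95, sum(x$links$kind == "correction"),
              if (x$nesting_ok) "ok" else "VIOLATED"))
  invisible(x)
}

#' @export
tidy.stc_estimate <- function(x, ...) tidy(x$isopleths)

#' @export
glance.stc_estimate <- function(x, ...) {
  tibble(area_95 = x$area_95,
         area_99 = isopleth_area_at(x$isopleths, 99),
         h = x$ud$h, n_correction = sum(x$links$kind == "correction"),
         n_identity = sum(x$links$kind == "identity"),
         nesting_ok = x$nesting_ok)
}

#' @export
autoplot.stc_estimate <- function(object, ...) {
  autoplot(object$isopleths) +
    ggplot2::geom_segment(
      data = dplyr::filter(object$links, .data$kind == "correction"),
      ggplot2::aes(x = .data$source_x, y = .data$source_y,
                   xend = .data$target_x, yend = .data$target_y),
      inherit.aes = FALSE, colour = "grey40",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::labs(subtitle = "stretch-the-centre isoclines with correction vectors")
}
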