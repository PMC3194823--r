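# k-nearest-neighbour local convex hulls (k-LoCoH): a nonparametric
# utilization distribution built from the union of each point's convex hull
# with its k-1 nearest neighbours, ordered by ascending hull area, plus the
# automated minimum-spurious-hole-covering (MSHC) selection of k.

#' k-LoCoH utilization distribution
#'
#' For every point, the convex hull of the point and its k-1 nearest
#' Euclidean neighbours (distance ties broken by point index) is formed;
#' hulls are sorted by ascending area and the p% isopleth is the union of
#' the smallest hulls needed to cover at least `ceiling(p*n/100)` distinct
#' points (a point counts as covered when inside or on any included hull).
#'
#' @param points Data frame or matrix with columns `x`, `y`.
#' @param k Neighbour count, `3 <= k <= n`.
#' @param levels Isopleth percentages; level 100 is always included.
#' @return A `locoh_model` with the per-point hulls, the selected `k` and an
#'   `isopleth_set` (each level carrying union rings, area, hole count).
#' @export
k_locoh <- function(points, k, levels = c(1, seq(5, 95, by = 5), 99, 100)) {
  xy <- as_xy(points)
  n <- nrow(xy)
  if (k < 3) abort("k must be at least 3 (smaller hulls have zero area)",
                   class = "territr_bad_k")
  if (k > n) abort("k cannot exceed the number of points", class = "territr_bad_k")
  levels <- sort(unique(c(levels, 100)))

  D <- as.matrix(dist(xy))
  hulls <- vector("list", n)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))  # ties by point index
    nb <- ord[seq_len(k)]
    sub <- xy[nb, , drop = FALSE]
    idx <- chull(sub[, 1], sub[, 2])
    ring <- sub[rev(idx), , drop = FALSE]
    hulls[[i]] <- ring
    areas[i] <- if (nrow(ring) >= 3) abs(ring_signed_area(ring)) else 0
  }
  ord <- order(areas, seq_len(n))
  hulls_sorted <- hulls[ord]
  nondeg <- vapply(hulls_sorted, nrow, 0L) >= 3

  # coverage incidence of points in the sorted hulls
  cov <- points_in_hulls_cpp(hulls_sorted[nondeg], xy[, 1], xy[, 2],
                             1e-9 * max(diff(range(xy[, 1])),
                                        diff(range(xy[, 2]))))
  # map back to sorted positions (degenerate hulls cover only their members)
  first_cover <- rep(NA_integer_, n)
  pos <- which(nondeg)
  for (j in seq_along(pos)) {
    newly <- is.na(first_cover) & cov[, j]
    first_cover[newly] <- pos[j]
  }
  # points never covered by a non-degenerate hull: covered by their own
  # (degenerate) hull at its sorted position
  if (anyNA(first_cover)) {
    own_pos <- match(seq_len(n), ord)
    first_cover[is.na(first_cover)] <- own_pos[is.na(first_cover)]
  }

  polys <- vector("list", length(levels))
  iso_areas <- numeric(length(levels))
  holes <- integer(length(levels))
  comps <- integer(length(levels))
  areas_sorted <- areas[ord]
  for (li in seq_along(levels)) {
    need <- ceiling(levels[li] * n / 100)
    m <- sort(first_cover)[need]          # hulls 1..m cover `need` points
    # the area ordering is only defined up to ties: when the stop index lands
    # inside a group of (numerically) equal-area hulls, include the whole
    # group so the isopleth does not depend on an arbitrary tie order
    while (m < n && areas_sorted[m + 1] <= areas_sorted[m] *
             (1 + 1e-9) + 1e-12) {
      m <- m + 1
    }
    use <- hulls_sorted[seq_len(m)]
    use <- use[vapply(use, nrow, 0L) >= 3]
    if (!length(use)) { polys[[li]] <- list(); next }
    u <- convex_union_cpp(use)
    polys[[li]] <- u$rings
    iso_areas[li] <- u$area
    holes[li] <- u$n_holes
    comps[li] <- u$n_components
  }
  iso <- structure(list(levels = levels, polygons = polys, areas = iso_areas,
                        n_holes = holes, n_components = comps,
                        source = "locoh"),
                   class = "isopleth_set")
  structure(list(k = k, n = n, hulls = hulls, hull_areas = areas,
                 isopleths = iso),
            class = "locoh_model")
}

#' @export
print.locoh_model <- function(x, ...) {
  cat(sprintf("<locoh_model> k = %d, n = %d, 100%% area %.6g (%d hole(s))\n",
              x$k, x$n, locoh_area(x), x$isopleths$n_holes[length(x$isopleths$levels)]))
  invisible(x)
}

#' Area of the 100% LoCoH isopleth
#'
#' @param model A `locoh_model`.
#' @export
locoh_area <- function(model) {
  isopleth_area_at(model$isopleths, 100)
}

#' @export
tidy.locoh_model <- function(x, ...) tidy(x$isopleths)

#' @export
glance.locoh_model <- function(x, ...) {
  tibble(k = x$k, n = x$n, area_100 = locoh_area(x),
         n_holes_100 = x$isopleths$n_holes[length(x$isopleths$levels)])
}

#' @export
autoplot.locoh_model <- function(object, ...) {
  autoplot(object$isopleths) +
    ggplot2::labs(subtitle = sprintf("k-LoCoH, k = %d", object$k))
}

#' Minimum-spurious-hole-covering selection of k
#'
#' Scans `k_range` in ascending order and returns the smallest k whose
#' 100%-LoCoH isopleth is free of spurious topology: no interior holes and
#' a single connected component. This is an automated, topological reading
#' of the rule that the tuning parameter should avoid unjustified holes or
#' cutaways in the 100% isopleth -- a union fragmented into disconnected
#' crumbs is the extreme cutaway, so connectedness is required alongside
#' hole-freeness. Biologically motivated exceptions are a judgement call
#' left to the analyst. If no k in the range qualifies the largest is
#' returned with a warning.
#'
#' @param points Data frame or matrix with columns `x`, `y`.
#' @param k_range Candidate k values (default `3:n`).
#' @return List with `k`, `hole_free` (TRUE when the selected isopleth has
#'   no holes and is connected) and `scanned` (tibble of k, holes,
#'   components, area for every k examined).
#' @export
mshc_select_k <- function(points, k_range = NULL) {
  xy <- as_xy(points)
  n <- nrow(xy)
  if (is.null(k_range)) k_range <- 3:n
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) abort("empty k range", class = "territr_bad_k")
  if (k_range[1] < 3 || k_range[length(k_range)] > n) {
    abort("k_range must lie within [3, n]", class = "territr_bad_k")
  }
  scanned <- list()
  chosen <- NULL
  for (k in k_range) {
    m <- k_locoh(xy, k, levels = 100)
    nh <- m$isopleths$n_holes[1]
    nc <- m$isopleths$n_components[1]
    scanned[[length(scanned) + 1]] <- tibble(k = k, holes = nh,
                                             components = nc,
                                             area = m$isopleths$areas[1])
    if (nh == 0 && nc == 1) { chosen <- k; break }
  }
  hole_free <- !is.null(chosen)
  if (!hole_free) {
    chosen <- k_range[length(k_range)]
    warn("no k in range produced a connected, hole-free 100% isopleth; returning the largest")
  }
  list(k = chosen, hole_free = hole_free, scanned = dplyr::bind_rows(scanned))
}
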