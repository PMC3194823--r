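# Simulated intrusion trials in virtual territories: uniform random start
# points in the central area, endpoints placed at 1-degree intervals along
# the outer edge (bearings taken about the central centroid), random
# central-edge pairing, and exhaustive enumeration of equiangular subsets.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample uniform random points in the central area
#'
#' Rejection sampling from the central polygon's bounding box.
#'
#' @param territory A [make_virtual_territory()] object.
#' @param n Number of points.
#' @param seed Optional integer seed (recorded in the result's attributes);
#'   `NULL` uses the current RNG stream.
#' @return Tibble with columns `x`, `y`.
#' @export
sample_central_points <- function(territory, n, seed = NULL) {
  stopifnot(inherits(territory, "territory"), n >= 0)
  poly <- territory$central
  bb <- apply(poly$exterior, 2, range)
  pts <- with_seed(seed, {
    out <- matrix(numeric(0), ncol = 2)
    while (nrow(out) < n) {
      m <- max(2 * (n - nrow(out)), 16)
      cand <- cbind(runif(m, bb[1, 1], bb[2, 1]), runif(m, bb[1, 2], bb[2, 2]))
      keep <- contains(poly, cand[, 1], cand[, 2])
      out <- rbind(out, cand[keep, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  })
  res <- tibble(x = pts[, 1], y = pts[, 2])
  attr(res, "seed") <- seed
  res
}

#' Place equiangular edge points on the outer boundary
#'
#' Places `n` points on the exterior ring of the outer region at equal
#' angular intervals of geographic bearing about the centroid of the central
#' area (the full simulation design: 360 points at 1-degree intervals). For
#' concave outlines the outermost ray crossing is used.
#'
#' @param territory A territory.
#' @param n Number of points; must divide 360 for equiangular-subset
#'   semantics.
#' @return Tibble with columns `direction_deg`, `x`, `y`.
#' @export
place_edge_points <- function(territory, n = 360) {
  stopifnot(inherits(territory, "territory"), n >= 1)
  if (360 %% n != 0) abort("n must divide 360", class = "territr_bad_subset")
  cen <- polygon_centroid(territory$central)
  if (!contains(territory$outer, cen[1], cen[2])) {
    abort("central centroid lies outside the outer polygon",
          class = "territr_domain_error")
  }
  dirs <- (0:(n - 1)) * (360 / n)
  pts <- vapply(dirs, function(b) {
    ray_outermost_intersection(territory$outer, cen, b)
  }, numeric(2))
  tibble(direction_deg = dirs, x = pts[1, ], y = pts[2, ])
}

#' Pair central and edge points into simulated intrusion trials
#'
#' A uniform random bijection between start points (central) and endpoints
#' (edge); each trial's direction is the bearing of its edge point.
#'
#' @param centrals Tibble of start points (`x`, `y`).
#' @param edges Tibble of edge points (`direction_deg`, `x`, `y`).
#' @param seed Optional integer seed.
#' @param individual Individual id to tag the trials with.
#' @return A trial set: tibble with columns `individual`, `direction_deg`,
#'   `start_x`, `start_y`, `end_x`, `end_y`, `responded`.
#' @export
pair_trials <- function(centrals, edges, seed = NULL, individual = "sim") {
  if (nrow(centrals) != nrow(edges)) {
    abort("centrals and edges must have equal length", class = "territr_length_mismatch")
  }
  perm <- with_seed(seed, sample.int(nrow(centrals)))
  res <- tibble(
    individual = individual,
    direction_deg = edges$direction_deg,
    start_x = centrals$x[perm], start_y = centrals$y[perm],
    end_x = edges$x, end_y = edges$y,
    responded = TRUE
  )
  attr(res, "seed") <- seed
  attr(res, "n_directions") <- nrow(edges)
  res
}

#' Simulate the full trial set for one territory
#'
#' Convenience wrapper: `n` random central points, `n` equiangular edge
#' points, random pairing.
#'
#' @inheritParams sample_central_points
#' @param n Number of trials (default 360).
#' @return A trial-set tibble (see [pair_trials()]).
#' @export
simulate_trials <- function(territory, n = 360, seed = NULL) {
  centrals <- sample_central_points(territory, n, seed = seed)
  edges <- place_edge_points(territory, n)
  pair_trials(centrals, edges, seed = if (is.null(seed)) NULL else seed + 1L)
}

#' Divisors of 360 used as equiangular trial counts
#'
#' @param min_k Smallest trial count to keep (default 2).
#' @return Integer vector of divisors of 360 that are >= `min_k`.
#' @export
divisors_360 <- function(min_k = 2) {
  d <- (1:360)[360 %% (1:360) == 0]
  d[d >= min_k]
}

#' Enumerate equiangular trial subsets
#'
#' For a trial count `k` dividing the number of directions there are
#' `360 / k` distinct equiangular subsets, one per angular offset; over the
#' full divisor list (2 ... 360) there are exactly 810.
#'
#' @param k Number of trials; must divide `n_directions`.
#' @param n_directions Total directions (360 for the simulation design).
#' @return List of integer vectors of directions (degrees), one per offset.
#' @export
enumerate_equiangular_subsets <- function(k, n_directions = 360) {
  if (n_directions %% k != 0) {
    abort("k must divide the number of directions", class = "territr_bad_subset")
  }
  step <- n_directions / k
  lapply(0:(step - 1), function(o) o + step * (0:(k - 1)))
}

#' Synthetic cohort of territorial individuals
#'
#' Generates a field-like fixture: `n_individuals` non-overlapping
#' territories placed in an arena, each probed with twelve trials at every
#' 30 degrees (scheduled semi-randomly), with a configurable probability of
#' non-response. Trial starts are calling positions drawn in the central
#' area; responded trials end on the outer boundary along the trial bearing
#' from the calling position. Purely geometric: no behavioural movement
#' model.
#'
#' @param n_individuals Number of individuals (>= 1).
#' @param arena A [polygon2] (or vertex matrix) the outer polygons must fit
#'   in; default a 60 x 60 square.
#' @param seed Optional integer seed.
#' @param area_range Range of true territory areas to draw from (uniform).
#' @param shapes Shape labels sampled for the outlines.
#' @param central_scale Linear central-area scale.
#' @param non_response_prob Per-trial probability of no response.
#' @param max_tries Placement retries before giving up.
#' @return List with elements `territories` (list of `territory`), `trials`
#'   (one trial-set tibble for the whole cohort) and `calling_points`
#'   (tibble of per-individual calling positions == trial starts).
#' @export
generate_fixture_individuals <- function(n_individuals, arena = NULL,
                                         seed = NULL,
                                         area_range = c(65, 420),
                                         shapes = c("circle", "ellipse",
                                                    "triangle", "angle",
                                                    "star", "irregular"),
                                         central_scale = 0.3,
                                         non_response_prob = 0.04,
                                         max_tries = 200) {
  stopifnot(n_individuals >= 1)
  if (is.null(arena)) {
    # ~25% packing fraction leaves room for rejection-free placement
    side <- ceiling(sqrt(n_individuals * mean(area_range) / 0.25))
    arena <- polygon2(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)),
                      validate = FALSE)
  } else if (!inherits(arena, "polygon2")) arena <- polygon2(arena)
  with_seed(seed, {
    bb <- apply(arena$exterior, 2, range)
    territories <- list()
    for (i in seq_len(n_individuals)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        shp <- sample(shapes, 1)
        a <- runif(1, area_range[1], area_range[2])
        ctr <- c(runif(1, bb[1, 1], bb[2, 1]), runif(1, bb[1, 2], bb[2, 2]))
        tr <- make_virtual_territory(shp, a, central_scale, centre = ctr)
        ring <- tr$outer$exterior
        if (!all(contains(arena, ring[, 1], ring[, 2]))) next
        clash <- FALSE
        for (other in territories) {
          if (polygons_overlap(tr$outer, other$outer)) { clash <- TRUE; break }
        }
        if (!clash) { territories[[i]] <- tr; placed <- TRUE; break }
      }
      if (!placed) {
        abort("arena too small to place non-overlapping territories",
              class = "territr_placement_error")
      }
    }
    trials <- purrr::map_dfr(seq_len(n_individuals), function(i) {
      tr <- territories[[i]]
      dirs <- schedule_directions()
      starts <- sample_central_points(tr, 12)
      ends <- t(vapply(seq_along(dirs), function(j) {
        ray_outermost_intersection(tr$outer,
                                   c(starts$x[j], starts$y[j]), dirs[j])
      }, numeric(2)))
      responded <- runif(12) >= non_response_prob
      tibble(individual = sprintf("ind%02d", i),
             direction_deg = dirs,
             start_x = starts$x, start_y = starts$y,
             end_x = ifelse(responded, ends[, 1], NA_real_),
             end_y = ifelse(responded, ends[, 2], NA_real_),
             responded = responded)
    })
    calling <- dplyr::transmute(trials, individual = .data$individual,
                                x = .data$start_x, y = .data$start_y)
    list(territories = territories, trials = trials, calling_points = calling)
  })
}

# Conservative polygon overlap test: bounding boxes, vertex containment
# either way, then any edge crossing.
polygons_overlap <- function(p1, p2) {
  r1 <- p1$exterior; r2 <- p2$exterior
  b1 <- apply(r1, 2, range); b2 <- apply(r2, 2, range)
  if (b1[2, 1] < b2[1, 1] || b1[1, 1] > b2[2, 1] ||
      b1[2, 2] < b2[1, 2] || b1[1, 2] > b2[2, 2]) return(FALSE)
  if (any(contains(p2, r1[, 1], r1[, 2]))) return(TRUE)
  if (any(contains(p1, r2[, 1], r2[, 2]))) return(TRUE)
  rings_cross_cpp(r1, r2)
}

#' Gather the point pattern of a trial subset
#'
#' Start and responded end points of the trials whose direction is in
#' `directions` (or all trials when `NULL`).
#'
#' @param trials A trial-set tibble.
#' @param directions Optional vector of directions to keep.
#' @return Tibble with columns `x`, `y`, `role` (`"start"`/`"end"`).
#' @export
trial_points <- function(trials, directions = NULL) {
  if (!is.null(directions)) {
    trials <- dplyr::filter(trials, .data$direction_deg %in% directions)
  }
  dplyr::bind_rows(
    tibble(x = trials$start_x, y = trials$start_y, role = "start"),
    tibble(x = trials$end_x[trials$responded],
           y = trials$end_y[trials$responded], role = "end")
  )
}
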