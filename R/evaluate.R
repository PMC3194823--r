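# Estimator benchmarking: percent-of-true area, area-accumulation tables
# over all equiangular subsets, rank-order stability, stepwise-change
# tables and isopleth coverage statistics.

#' Percent of true territory area
#'
#' @param estimate_area Estimated area(s).
#' @param territory A `territory` (or a positive true area).
#' @param rounded Round to integer percent, as benchmark tables print it.
#' @return Percentage(s).
#' @export
percent_of_true <- function(estimate_area, territory, rounded = FALSE) {
  true_area <- if (inherits(territory, "territory")) territory$true_area else territory
  stopifnot(true_area > 0)
  p <- 100 * estimate_area / true_area
  if (rounded) round(p) else p
}

# Resolve an estimator label to a function point-pattern -> area.
estimator_fun <- function(estimator, locoh_k = "mshc", kde_level = 95,
                          grid = grid_spec()) {
  switch(
    estimator,
    mcp = function(pts) mcp(pts)$area,
    dh = function(pts) detailed_hull(pts)$area,
    locoh = function(pts) {
      k <- if (identical(locoh_k, "mshc")) {
        mshc_select_k(pts)$k
      } else min(locoh_k, nrow(pts))
      locoh_area(k_locoh(pts, k, levels = 100))
    },
    kde_href = function(pts) {
      isopleth_area_at(kde_isopleth(kde_density(pts, selector = "href",
                                                grid = grid), kde_level),
                       kde_level)
    },
    kde_href_adaptive = function(pts) {
      isopleth_area_at(kde_isopleth(kde_density(pts, selector = "href",
                                                mode = "adaptive", grid = grid),
                                    kde_level), kde_level)
    },
    kde_lscv = function(pts) {
      isopleth_area_at(kde_isopleth(kde_density(pts, selector = "lscv",
                                                grid = grid), kde_level),
                       kde_level)
    },
    abort(sprintf("unknown estimator '%s'", estimator),
          class = "territr_bad_estimator")
  )
}

#' Area-accumulation table over equiangular subsets
#'
#' Simulates one full 360-trial set on a territory, then evaluates an
#' estimator on every equiangular subset for each trial count `k` (all
#' 360/k offsets, enumerated exhaustively) and summarises mean and SD of
#' the estimated area. Polygon estimators are evaluated at their full
#' extension; parametric kernels at the 95% isocline.
#'
#' @param territory A `territory`.
#' @param estimator One of `"mcp"`, `"dh"`, `"locoh"`, `"kde_href"`,
#'   `"kde_href_adaptive"`, `"kde_lscv"`.
#' @param ks Trial counts (divisors of 360).
#' @param seed Seed for the random central points and pairing.
#' @param trials Optional precomputed trial set (overrides `seed`).
#' @param offsets Optional restriction of the angular offsets evaluated at
#'   each k (e.g. `0` for the subset chain through direction 0); default all.
#' @param ... Passed to the estimator resolver (e.g. `locoh_k`).
#' @return Tibble with one row per k: `shape`, `estimator`, `k`,
#'   `n_offsets`, `mean_area`, `sd_area`, `percent_of_true`, and the raw
#'   per-offset areas in the list-column `areas`.
#' @export
accumulation_table <- function(territory, estimator, ks = divisors_360(),
                               seed = NULL, trials = NULL, offsets = NULL,
                               ...) {
  stopifnot(inherits(territory, "territory"))
  f <- estimator_fun(estimator, ...)
  if (is.null(trials)) trials <- simulate_trials(territory, 360, seed = seed)
  purrr::map_dfr(ks, function(k) {
    subs <- enumerate_equiangular_subsets(k)
    if (!is.null(offsets)) {
      subs <- subs[vapply(subs, function(s) any(offsets %in% s), TRUE)]
    }
    areas <- vapply(subs, function(dirs) f(trial_points(trials, dirs)), 0)
    tibble(shape = territory$shape_name, estimator = estimator, k = k,
           n_offsets = length(areas),
           mean_area = mean(areas),
           sd_area = if (length(areas) > 1) sd(areas) else 0,
           percent_of_true = percent_of_true(mean(areas), territory),
           areas = list(areas))
  })
}

#' Smallest trial count with invariant rank order
#'
#' Given per-unit area series over increasing trial counts, returns the
#' smallest k* such that the ordering of units at every k >= k* equals the
#' ordering at the maximum k. Exact area ties are broken by unit id.
#'
#' @param areas Tibble with columns `unit`, `k`, `area` (>= 2 units).
#' @return The trial count k*.
#' @export
rank_stability <- function(areas) {
  stopifnot(all(c("unit", "k", "area") %in% names(areas)))
  ks <- sort(unique(areas$k))
  units <- sort(unique(areas$unit))
  if (length(units) < 2) abort("need at least 2 units")
  ordering <- function(k) {
    d <- areas[areas$k == k, ]
    d <- d[order(d$area, d$unit), ]
    d$unit
  }
  ref <- ordering(ks[length(ks)])
  stable_from <- ks[length(ks)]
  for (i in rev(seq_along(ks))) {
    if (identical(ordering(ks[i]), ref)) stable_from <- ks[i] else break
  }
  stable_from
}

#' Stepwise relative change of an area series
#'
#' Change at step i is `100 * (mean_i - mean_{i-1}) / mean_{i-1}`. Reports
#' the changes and the last step whose absolute change exceeds the
#' threshold (the "no more than 2% stepwise" stopping rule).
#'
#' @param means Positive mean areas over increasing trial counts.
#' @param ks Optional trial counts labelling the series.
#' @param threshold Percent threshold (default 2).
#' @return List with `changes` (tibble: `k`, `change_pct`, `exceeds`) and
#'   `last_exceeding` (the k, or `NA` when no step exceeds).
#' @export
stepwise_change <- function(means, ks = seq_along(means), threshold = 2) {
  stopifnot(all(means > 0), length(means) == length(ks))
  ch <- 100 * diff(means) / head(means, -1)
  tbl <- tibble(k = ks[-1], change_pct = ch, exceeds = abs(ch) > threshold)
  last <- if (any(tbl$exceeds)) tbl$k[max(which(tbl$exceeds))] else NA
  list(changes = tbl, last_exceeding = last)
}

#' Isopleth coverage of a reference territory
#'
#' For an ordered isopleth set and a reference polygon (typically the
#' detailed hull of the calling territory) returns the smallest level whose
#' area reaches the reference area, and the smallest level whose polygons
#' fully contain the reference (containment is checked on the reference
#' boundary, densified to `n_probe` points). Containment is stricter than
#' area equality, so `full_overlap_level >= area_equality_level`.
#'
#' @param isopleths An `isopleth_set`.
#' @param reference A `hull_estimate` or [polygon2].
#' @param n_probe Number of boundary probe points.
#' @return Tibble with `area_equality_level` and `full_overlap_level`
#'   (`NA` when never reached).
#' @export
isopleth_coverage_stats <- function(isopleths, reference, n_probe = 200) {
  poly <- if (inherits(reference, "hull_estimate")) reference$polygon else
    if (inherits(reference, "polygon2")) reference else polygon2(reference)
  ref_area <- polygon_area(poly)
  lv <- isopleths$levels
  aeq <- lv[isopleths$areas >= ref_area][1]
  probe <- densify_ring(poly$exterior, n_probe)
  fol <- NA_real_
  for (i in seq_along(lv)) {
    rings <- isopleths$polygons[[i]]
    if (!length(rings)) next
    if (region_contains(rings, probe)) { fol <- lv[i]; break }
  }
  tibble(area_equality_level = if (is.na(aeq)) NA_real_ else aeq,
         full_overlap_level = fol)
}

# Even-odd containment of probe points in a multi-ring region.
region_contains <- function(rings, pts) {
  inside <- rep(FALSE, nrow(pts))
  on_bnd <- rep(FALSE, nrow(pts))
  for (r in rings) {
    res <- points_in_ring_cpp(pts[, 1], pts[, 2], r, 1e-9)
    inside <- xor(inside, res == 1L)
    on_bnd <- on_bnd | res == 2L
  }
  all(inside | on_bnd)
}

densify_ring <- function(ring, n) {
  m <- nrow(ring)
  nxt <- ring[c(2:m, 1), , drop = FALSE]
  seg_len <- sqrt(rowSums((nxt - ring)^2))
  total <- sum(seg_len)
  out <- ring
  per <- pmax(0, ceiling(n * seg_len / total) - 1)
  extra <- do.call(rbind, lapply(seq_len(m), function(i) {
    if (per[i] == 0) return(NULL)
    t <- seq_len(per[i]) / (per[i] + 1)
    cbind(ring[i, 1] + t * (nxt[i, 1] - ring[i, 1]),
          ring[i, 2] + t * (nxt[i, 2] - ring[i, 2]))
  }))
  rbind(out, extra)
}

#' Benchmark summary table at full trial count
#'
#' Convenience wrapper reproducing the benchmark layout: percent of true
#' area recovered by each estimator on each territory at 360 trials,
#' rounded to integer percent.
#'
#' @param territories List of `territory` objects.
#' @param estimators Estimator labels (see [accumulation_table()]).
#' @param seed Seed for the central points.
#' @param ... Passed to the estimator resolver.
#' @return Tibble: `shape`, `true_area`, one column per estimator.
#' @export
benchmark_table <- function(territories,
                            estimators = c("mcp", "dh", "locoh"),
                            seed = NULL, ...) {
  purrr::map_dfr(territories, function(tr) {
    trials <- simulate_trials(tr, 360, seed = seed)
    pts <- trial_points(trials)
    row <- tibble(shape = tr$shape_name, true_area = tr$true_area)
    for (est in estimators) {
      a <- estimator_fun(est, ...)(pts)
      row[[est]] <- percent_of_true(a, tr, rounded = TRUE)
    }
    row
  })
}
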