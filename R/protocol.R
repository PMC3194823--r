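# Field-protocol support: the 12-direction semi-random trial scheduler and
# trial-record validation. Twelve trials at every 30 degrees partition into
# three orthogonal "crosses"; within each cross the first direction is
# random, the second is its complement (+180), and the third and fourth are
# +90 and +270 in random order.

#' Semi-random schedule of twelve trial directions
#'
#' Draws the order in which the twelve 30-degree directions are probed:
#' d1 uniform on {0, 30, ..., 330}; d2 = d1 + 180; d3, d4 = d1 + 90 and
#' d1 + 270 in random order; d5 uniform over the eight remaining
#' directions, then the same pattern; d9-d12 likewise within the last
#' cross. All mod 360. The branch factor is 12 x 2 x 8 x 2 x 4 x 2 = 6144
#' distinct orderings.
#'
#' @param seed Optional integer seed.
#' @return Integer vector of 12 bearings (a permutation of
#'   seq(0, 330, 30)).
#' @export
schedule_directions <- function(seed = NULL) {
  with_seed(seed, {
    all_dirs <- seq(0, 330, by = 30)
    remaining <- all_dirs
    out <- integer(0)
    for (cross in 1:3) {
      d1 <- sample(remaining, 1)
      lr <- sample(c(90, 270))
      block <- (d1 + c(0, 180, lr)) %% 360
      out <- c(out, block)
      remaining <- setdiff(remaining, block)
    }
    out
  })
}

#' Build a trial plan
#'
#' @param individual Individual id.
#' @param setup One of the four intrusion-experiment setups:
#'   `"approach_fixed_intensity"` (stimulus approaches at fixed intensity),
#'   `"remove_fixed_intensity"`, `"increase_fixed_distance"`,
#'   `"decrease_fixed_distance"`. Fixed-distance setups yield intensity
#'   thresholds that require a separate calibration to a reaction horizon;
#'   they are representable but produce no endpoint geometry here.
#' @param seed Optional seed for the direction schedule.
#' @return Tibble: `individual`, `order`, `direction_deg`, `setup`.
#' @export
trial_plan <- function(individual, setup = c("approach_fixed_intensity",
                                             "remove_fixed_intensity",
                                             "increase_fixed_distance",
                                             "decrease_fixed_distance"),
                       seed = NULL) {
  setup <- match.arg(setup)
  dirs <- schedule_directions(seed)
  tibble(individual = individual, order = seq_along(dirs),
         direction_deg = dirs, setup = setup)
}

#' Validate a trial set against the 12-direction protocol
#'
#' Checks, per individual: duplicate directions (failure), directions
#' absent from the 30-degree grid (failure), missing endpoints on responded
#' trials (failure), non-responses (informational), and incomplete
#' direction coverage (warning -- analysis proceeds, as a territory holder
#' that was probed in only eleven directions is still usable). Timing
#' constraints (at most two trials per day, >= 4 h apart) are validated
#' only when a `timestamp` column is supplied; they are reported, never
#' silently enforced.
#'
#' @param trials Trial-set tibble.
#' @param plan Optional [trial_plan()] to compare directions against.
#' @return Tibble report: `individual`, `check`, `status`
#'   (`"pass"`/`"warn"`/`"fail"`), `detail`; attribute `ok` is TRUE when no
#'   check failed.
#' @export
validate_trialset <- function(trials, plan = NULL) {
  grid_dirs <- seq(0, 330, by = 30)
  rep_rows <- list()
  add <- function(ind, check, status, detail) {
    rep_rows[[length(rep_rows) + 1]] <<- tibble(individual = ind, check = check,
                                                status = status, detail = detail)
  }
  for (ind in unique(trials$individual)) {
    tr <- trials[trials$individual == ind, ]
    dups <- tr$direction_deg[duplicated(tr$direction_deg)]
    if (length(dups)) {
      add(ind, "unique_directions", "fail",
          paste("duplicate direction(s):", paste(unique(dups), collapse = ", ")))
    } else add(ind, "unique_directions", "pass", "")
    off <- setdiff(tr$direction_deg, grid_dirs)
    if (length(off)) {
      add(ind, "direction_grid", "fail",
          paste("off-grid direction(s):", paste(off, collapse = ", ")))
    } else add(ind, "direction_grid", "pass", "")
    missing <- setdiff(grid_dirs, tr$direction_deg)
    if (length(missing)) {
      add(ind, "coverage", "warn",
          paste("untested direction(s):", paste(missing, collapse = ", ")))
    } else add(ind, "coverage", "pass", "")
    bad_end <- tr$responded & (is.na(tr$end_x) | is.na(tr$end_y))
    if (any(bad_end)) {
      add(ind, "endpoints", "fail",
          paste("responded trials without endpoint at direction(s):",
                paste(tr$direction_deg[bad_end], collapse = ", ")))
    } else add(ind, "endpoints", "pass", "")
    nr <- sum(!tr$responded)
    add(ind, "non_response", if (nr) "warn" else "pass",
        if (nr) sprintf("%d non-response(s) at direction(s): %s", nr,
                        paste(tr$direction_deg[!tr$responded], collapse = ", "))
        else "")
    if ("timestamp" %in% names(tr)) {
      ts <- sort(as.POSIXct(tr$timestamp))
      per_day <- table(as.Date(ts))
      if (any(per_day > 2)) {
        add(ind, "timing", "fail", "more than two trials on one day")
      } else if (length(ts) > 1 &&
                 any(diff(as.numeric(ts)) < 4 * 3600)) {
        add(ind, "timing", "fail", "trials less than 4 h apart")
      } else add(ind, "timing", "pass", "")
    }
    if (!is.null(plan)) {
      pd <- plan$direction_deg[plan$individual == ind]
      if (length(pd) && !setequal(pd, tr$direction_deg)) {
        add(ind, "plan_match", "warn", "directions differ from plan")
      } else add(ind, "plan_match", "pass", "")
    }
  }
  out <- dplyr::bind_rows(rep_rows)
  attr(out, "ok") <- !any(out$status == "fail")
  out
}
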