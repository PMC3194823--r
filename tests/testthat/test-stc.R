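# A radially symmetric testbed: clustered calling positions at the origin
# and twelve trials at every 30 degrees ending at radius R.
symmetric_case <- function(R = 3, n_calls = 30, seed = 9, responded = rep(TRUE, 12)) {
  set.seed(seed)
  calls <- tibble::tibble(x = rnorm(n_calls, 0, .5), y = rnorm(n_calls, 0, .5))
  dirs <- seq(0, 330, 30)
  trials <- tibble::tibble(
    individual = "a", direction_deg = dirs, start_x = 0, start_y = 0,
    end_x = ifelse(responded, R * sin(dirs * pi / 180), NA_real_),
    end_y = ifelse(responded, R * cos(dirs * pi / 180), NA_real_),
    responded = responded)
  list(calls = calls, trials = trials)
}

test_that("links pair trial rays with endpoints and pin calling positions", {
  cs <- symmetric_case()
  ud <- kde_density(cs$calls, selector = "href")
  iso99 <- kde_isopleth(ud, 99)$polygons[[1]][[1]]
  links <- build_stc_links(iso99, cs$trials, cs$calls)
  expect_equal(sum(links$kind == "correction"), 12)
  expect_equal(sum(links$kind == "identity"), 30)
  expect_true(all(links$source_x[links$kind == "identity"] ==
                  links$target_x[links$kind == "identity"]))
  # sources lie on the isocline ring
  src <- links[links$kind == "correction", ]
  on_ring <- territr:::points_in_ring_cpp(src$source_x, src$source_y, iso99, 1e-6)
  expect_true(all(on_ring == 2L))
  # non-response: correction target is the calling position itself
  cs2 <- symmetric_case(responded = c(FALSE, rep(TRUE, 11)))
  links2 <- build_stc_links(iso99, cs2$trials, cs2$calls)
  nr <- links2[links2$kind == "correction", ][1, ]
  expect_equal(c(nr$target_x, nr$target_y), c(0, 0))
  # a start outside the isocline is a domain error naming the trial
  bad <- cs$trials
  bad$start_x[3] <- 100
  expect_error(build_stc_links(iso99, bad, cs$calls),
               class = "territr_domain_error")
})

test_that("rubbersheet honours identity-only links and constant displacements", {
  sq <- list(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
  ident <- tibble::tibble(kind = "identity",
                          source_x = c(0, 4, 0, 4), source_y = c(0, 0, 4, 4),
                          target_x = c(0, 4, 0, 4), target_y = c(0, 0, 4, 4),
                          direction_deg = NA_real_)
  class(ident) <- c("link_set", class(ident))
  out <- rubbersheet_transform(sq, ident)
  expect_equal(out[[1]], sq[[1]], tolerance = 1e-12)
  # three links all displacing by (1, 0): constant field inside their triangle
  con <- tibble::tibble(kind = "correction",
                        source_x = c(0, 4, 2), source_y = c(0, 0, 4),
                        target_x = c(1, 5, 3), target_y = c(0, 0, 4),
                        direction_deg = NA_real_)
  class(con) <- c("link_set", class(con))
  inner <- tibble::tibble(x = c(2, 1.5, 2.5), y = c(1, 2, 0.5))
  moved <- rubbersheet_transform(inner, con)
  expect_equal(moved$x, inner$x + 1, tolerance = 1e-9)
  expect_equal(moved$y, inner$y, tolerance = 1e-9)
  # every link source maps exactly onto its target
  src_moved <- rubbersheet_transform(
    tibble::tibble(x = con$source_x, y = con$source_y), con)
  expect_equal(src_moved$x, con$target_x, tolerance = 1e-9)
  expect_equal(src_moved$y, con$target_y, tolerance = 1e-9)
  # collinear sources are ill-posed
  col <- dplyr::mutate(con, source_y = 0, target_y = 0)
  class(col) <- c("link_set", class(col))
  expect_error(rubbersheet_transform(inner, col), class = "territr_ill_posed")
})

test_that("the stretched 99% isocline interpolates every responding endpoint", {
  cs <- symmetric_case(R = 3)
  est <- suppressWarnings(stc_estimate(cs$calls, cs$trials))
  i99 <- est$isopleths$polygons[[match(99, est$isopleths$levels)]][[1]]
  for (i in 1:12) {
    d <- min(sqrt((i99[, 1] - cs$trials$end_x[i])^2 +
                  (i99[, 2] - cs$trials$end_y[i])^2))
    expect_lt(d, 1e-6)
  }
  # calling positions are fixed points of the transformation
  back <- rubbersheet_transform(cs$calls, est$links)
  expect_equal(back$x, cs$calls$x, tolerance = 1e-9)
  expect_equal(back$y, cs$calls$y, tolerance = 1e-9)
  # headline estimate is the 95% area
  expect_equal(est$area_95,
               isopleth_area_at(est$isopleths, 95))
})

test_that("endpoints on the 99% isocline itself leave the kernel unchanged", {
  set.seed(9)
  calls <- tibble::tibble(x = rnorm(30, 0, .5), y = rnorm(30, 0, .5))
  ud <- kde_density(calls, selector = "href")
  central <- kde_isopleth(ud, c(95, 99))
  ring99 <- central$polygons[[2]][[1]]
  dirs <- seq(0, 330, 30)
  ends <- t(vapply(dirs, function(b) {
    ray_oracle(ring99, c(0, 0), b)
  }, numeric(2)))
  trials <- tibble::tibble(individual = "a", direction_deg = dirs,
                           start_x = 0, start_y = 0,
                           end_x = ends[, 1], end_y = ends[, 2],
                           responded = TRUE)
  est <- suppressWarnings(stc_estimate(calls, trials, levels = c(95, 99)))
  a_before <- isopleth_area_at(central, 95)
  a_after <- est$area_95
  expect_lt(abs(a_after - a_before) / a_before, 0.01)
})

test_that("nesting violations after transformation are detected, not hidden", {
  # severe inward pull from a non-response folds the isoclines: the estimate
  # must flag it
  cs <- symmetric_case(R = 6, responded = c(FALSE, FALSE, rep(TRUE, 10)))
  est <- suppressWarnings(stc_estimate(cs$calls, cs$trials))
  expect_type(est$nesting_ok, "logical")
  if (!est$nesting_ok) expect_gt(length(est$nesting_report), 0)
  # transformed isoclines stay nested in the symmetric all-responded case
  cs2 <- symmetric_case(R = 2)
  est2 <- suppressWarnings(stc_estimate(cs2$calls, cs2$trials))
  expect_true(est2$nesting_ok)
})

test_that("STC and LoCoH areas rank a synthetic cohort concordantly", {
  # a single Spearman coefficient over 15 individuals has a sampling SD of
  # roughly 0.1, so the concordance property is asserted on the median over
  # three independent cohorts, with every cohort required to be strongly
  # positive on its own
  rhos <- vapply(1:3, function(s) {
    fx <- generate_fixture_individuals(15, seed = s)
    res <- purrr::map_dfr(unique(fx$trials$individual), function(ind) {
      tr <- fx$trials[fx$trials$individual == ind, ]
      cp <- fx$calling_points[fx$calling_points$individual == ind, c("x", "y")]
      est <- suppressWarnings(stc_estimate(cp, tr))
      pts <- trial_points(tr)
      k <- mshc_select_k(pts)$k
      loc <- k_locoh(pts, k, levels = 100)
      tibble::tibble(individual = ind,
                     stc99 = isopleth_area_at(est$isopleths, 99),
                     locoh100 = locoh_area(loc))
    })
    cor(res$stc99, res$locoh100, method = "spearman")
  }, 0)
  expect_gt(median(rhos), 0.8)
  expect_true(all(rhos > 0.6))
})
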