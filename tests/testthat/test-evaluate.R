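test_that("percent of true area is a plain ratio with table rounding", {
  tr <- circle_territory()
  expect_equal(percent_of_true(200.04, tr), 100)
  expect_equal(percent_of_true(0, tr), 0)
  star <- make_virtual_territory("star")
  expect_equal(percent_of_true(1.82 * 130.09, star, rounded = TRUE), 182)
  # invariance under rigid motions: ratio depends only on areas
  expect_equal(percent_of_true(100, tr), percent_of_true(100, tr))
})

test_that("accumulation over equiangular subsets matches closed forms on the circle", {
  tr <- circle_territory()
  tab <- accumulation_table(tr, "mcp", ks = c(4, 360), seed = 1)
  # k = 4: inscribed square of the edge points, 2 r^2 / (pi r^2)
  expect_equal(tab$percent_of_true[tab$k == 4], 100 * 2 / pi, tolerance = 0.01)
  expect_equal(tab$n_offsets[tab$k == 4], 90)
  # k = 360: single offset, full recovery after rounding
  expect_equal(round(tab$percent_of_true[tab$k == 360]), 100)
  expect_equal(tab$sd_area[tab$k == 360], 0)
  expect_error(accumulation_table(tr, "nope"), class = "territr_bad_estimator")
})

test_that("rank stability finds the smallest k with the final ordering", {
  # constructed fixture: units A and B cross once between k = 10 and k = 12
  areas <- dplyr::bind_rows(
    tibble::tibble(unit = "A", k = c(5, 10, 12, 20), area = c(3, 5, 4, 4)),
    tibble::tibble(unit = "B", k = c(5, 10, 12, 20), area = c(4, 4.5, 5, 5)))
  expect_equal(rank_stability(areas), 12)
  stable <- dplyr::bind_rows(
    tibble::tibble(unit = "A", k = c(5, 10, 20), area = c(1, 2, 3)),
    tibble::tibble(unit = "B", k = c(5, 10, 20), area = c(2, 3, 4)))
  expect_equal(rank_stability(stable), 5)
})

test_that("stepwise change reports per-step percentages and the last exceedance", {
  sc <- stepwise_change(c(100, 150, 152), ks = c(1, 2, 3))
  expect_equal(sc$changes$change_pct, c(50, 2 / 1.5), tolerance = 1e-9)
  expect_equal(sc$last_exceeding, 2)
  flat <- stepwise_change(c(7, 7, 7))
  expect_true(all(flat$changes$change_pct == 0))
  expect_true(is.na(flat$last_exceeding))
})

test_that("coverage levels behave like concentric versus offset references", {
  # concentric discs: area equality and full overlap coincide
  disc_ring <- function(r, ctr = c(0, 0)) {
    th <- seq(0, 2 * pi, length.out = 90)[-90]
    cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
  }
  iso <- structure(list(levels = c(25, 50, 75, 99),
                        polygons = lapply(c(0.5, 0.9, 1.2, 1.6),
                                          function(r) list(disc_ring(r))),
                        areas = pi * c(0.5, 0.9, 1.2, 1.6)^2,
                        source = "locoh"), class = "isopleth_set")
  ref <- polygon2(disc_ring(1.0), validate = FALSE)
  st <- isopleth_coverage_stats(iso, ref)
  expect_equal(st$area_equality_level, 75)
  expect_equal(st$full_overlap_level, 75)
  # offset reference: containment is stricter than area
  ref_off <- polygon2(disc_ring(1.0, ctr = c(0.5, 0)), validate = FALSE)
  st2 <- isopleth_coverage_stats(iso, ref_off)
  expect_gte(st2$full_overlap_level, st2$area_equality_level)
  # reference larger than every isopleth: never reached
  ref_big <- polygon2(disc_ring(5), validate = FALSE)
  st3 <- isopleth_coverage_stats(iso, ref_big)
  expect_true(is.na(st3$area_equality_level))
  expect_true(is.na(st3$full_overlap_level))
})

test_that("benchmark tables report integer percentages per estimator", {
  tr <- make_virtual_territory("triangle")
  tab <- benchmark_table(list(tr), estimators = c("mcp", "dh"), seed = 2)
  expect_equal(tab$mcp, 100)
  expect_equal(tab$dh, 100)
  expect_equal(tab$true_area, 88)
})
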