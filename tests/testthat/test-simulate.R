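test_that("virtual territories are normalised to their true areas", {
  defaults <- c(ellipse = 243.58, star = 130.09, triangle = 88,
                circle = 200.04, angle = 155.63, irregular = 395.11)
  for (s in names(defaults)) {
    tr <- make_virtual_territory(s)
    expect_equal(polygon_area(tr$outer), defaults[[s]], tolerance = 1e-6)
    expect_equal(tr$true_area, defaults[[s]])
    # central area nested inside the outer region
    expect_true(all(contains(tr$outer, tr$central$exterior[, 1],
                             tr$central$exterior[, 2])))
  }
  # circle radius follows r = sqrt(A / pi)
  tr <- make_virtual_territory("circle", 200.04, 0.3)
  r <- sqrt(rowSums(tr$outer$exterior^2))
  expect_equal(mean(r), sqrt(200.04 / pi), tolerance = 1e-3)
  # equilateral triangle normalisation contract
  expect_equal(polygon_area(make_virtual_territory("triangle", 88)$outer), 88,
               tolerance = 1e-6)
  # concave star keeps its area contract too
  expect_equal(polygon_area(make_virtual_territory("star", 130.09)$outer),
               130.09, tolerance = 1e-6)
})

test_that("central points are uniform over the central area", {
  tr <- circle_territory()
  pts <- sample_central_points(tr, 360, seed = 1)
  expect_equal(nrow(pts), 360)
  expect_true(all(contains(tr$central, pts)))
  expect_equal(nrow(sample_central_points(tr, 0, seed = 1)), 0)
  # law of large numbers: empirical centroid near the true centroid
  big <- sample_central_points(tr, 10000, seed = 1)
  cen <- polygon_centroid(tr$central)
  r_central <- sqrt(polygon_area(tr$central) / pi)
  expect_lt(sqrt((mean(big$x) - cen[1])^2 + (mean(big$y) - cen[2])^2),
            0.05 * r_central)
  # reproducible under a fixed seed
  expect_identical(sample_central_points(tr, 50, seed = 7),
                   sample_central_points(tr, 50, seed = 7))
})

test_that("edge points sit on the outer ring at equal bearing intervals", {
  tr <- circle_territory()
  ep <- place_edge_points(tr, 360)
  expect_equal(ep$direction_deg, 0:359)
  r <- sqrt(ep$x^2 + ep$y^2)
  expect_equal(r, rep(sqrt(200.04 / pi), 360), tolerance = 1e-3)
  ep4 <- place_edge_points(tr, 4)
  expect_equal(ep4$direction_deg, c(0, 90, 180, 270))
  # on-boundary check against the segment oracle, for a concave shape
  star <- make_virtual_territory("star")
  eps <- place_edge_points(star, 360)
  cen <- polygon_centroid(star$central)
  for (i in seq(1, 360, by = 23)) {
    want <- ray_oracle(star$outer$exterior, cen, eps$direction_deg[i])
    expect_equal(c(eps$x[i], eps$y[i]), unname(want), tolerance = 1e-9)
  }
  expect_error(place_edge_points(tr, 7), class = "territr_bad_subset")
})

test_that("pairing is a uniform random bijection tagged with edge bearings", {
  tr <- circle_territory()
  cp <- sample_central_points(tr, 360, seed = 1)
  ep <- place_edge_points(tr, 360)
  ts <- pair_trials(cp, ep, seed = 7)
  expect_equal(nrow(ts), 360)
  expect_setequal(ts$direction_deg, 0:359)
  # each start used exactly once
  expect_equal(sort(ts$start_x), sort(cp$x))
  expect_false(any(duplicated(paste(ts$start_x, ts$start_y))))
  # different seeds give different pairings (360! permutations)
  ts2 <- pair_trials(cp, ep, seed = 8)
  expect_false(identical(ts$start_x, ts2$start_x))
  expect_error(pair_trials(cp[1:10, ], ep), class = "territr_length_mismatch")
  one <- pair_trials(cp[1, ], ep[1, ], seed = 1)
  expect_equal(c(one$start_x, one$end_x), c(cp$x[1], ep$x[1]))
})

test_that("equiangular subsets partition directions and total 810", {
  expect_equal(length(enumerate_equiangular_subsets(360)), 1)
  s12 <- enumerate_equiangular_subsets(12)
  expect_equal(length(s12), 30)
  expect_true(all(vapply(s12, function(s) all(diff(s) == 30), TRUE)))
  # subsets at fixed k partition the 360 directions
  expect_setequal(unlist(s12), 0:359)
  # nesting: k | k' implies subset at offset o contained in k'-subset at o
  s4 <- enumerate_equiangular_subsets(4)[[3]]
  s12_o3 <- enumerate_equiangular_subsets(12)[[3]]
  expect_true(all(s4 %in% s12_o3))
  expect_equal(sum(vapply(divisors_360(), function(k) 360 / k, 0)), 810)
  expect_error(enumerate_equiangular_subsets(7), class = "territr_bad_subset")
})

test_that("simulated trials start inside central and end on the outer ring", {
  for (s in c("circle", "star", "angle")) {
    tr <- make_virtual_territory(s)
    ts <- simulate_trials(tr, 90, seed = 3)
    expect_true(all(contains(tr$central, ts$start_x, ts$start_y)))
    on_ring <- territr:::points_in_ring_cpp(ts$end_x, ts$end_y,
                                            tr$outer$exterior, 1e-8)
    expect_true(all(on_ring == 2L))
  }
})

test_that("fixture cohorts have non-overlapping territories and 30-degree protocols", {
  fx <- generate_fixture_individuals(5, seed = 3)
  expect_length(fx$territories, 5)
  expect_equal(nrow(fx$trials), 60)
  for (ind in unique(fx$trials$individual)) {
    expect_setequal(fx$trials$direction_deg[fx$trials$individual == ind],
                    seq(0, 330, 30))
  }
  for (i in 1:4) for (j in (i + 1):5) {
    expect_false(territr:::polygons_overlap(fx$territories[[i]]$outer,
                                            fx$territories[[j]]$outer))
  }
  # forced non-response
  fx2 <- generate_fixture_individuals(1, seed = 3, non_response_prob = 1)
  expect_true(all(!fx2$trials$responded))
  expect_true(all(is.na(fx2$trials$end_x)))
})
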