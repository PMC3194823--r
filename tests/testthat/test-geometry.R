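test_that("polygon areas follow the shoelace rule, with holes subtracted", {
  sq <- polygon2(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(polygon_area(sq), 1)
  holed <- polygon2(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                    holes = list(rbind(c(0.25, 0.25), c(0.75, 0.25),
                                       c(0.75, 0.75), c(0.25, 0.75))))
  expect_equal(polygon_area(holed), 0.75)
  # inscribed regular 360-gon: closed form (360 / 2 pi) sin(2 pi / 360) * pi
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  gon <- polygon2(cbind(cos(th), sin(th)), validate = FALSE)
  expect_equal(polygon_area(gon), (360 / 2) * sin(2 * pi / 360),
               tolerance = 1e-12)
  # cross-check against an independent implementation
  skip_if_not_installed("pracma")
  expect_equal(polygon_area(sq), abs(pracma::polyarea(c(0, 1, 1, 0), c(0, 0, 1, 1))))
})

test_that("self-intersecting rings are rejected", {
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(polygon2(bowtie), class = "territr_invalid_geometry")
})

test_that("area is invariant under rigid motion and scales quadratically", {
  set.seed(11)
  ring <- cbind(runif(8, 0, 3), runif(8, 0, 3))
  ring <- ring[rev(chull(ring)), ]
  a0 <- polygon_area(polygon2(ring, validate = FALSE))
  th <- 0.7
  rot <- ring %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  expect_equal(polygon_area(polygon2(rot, validate = FALSE)), a0)
  expect_equal(polygon_area(polygon2(ring * 2.5 + 10, validate = FALSE)),
               a0 * 2.5^2)
})

test_that("containment uses the even-odd rule with inclusive boundary", {
  sq <- polygon2(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_true(contains(sq, 0.5, 0.5))
  expect_false(contains(sq, 2, 0))
  expect_true(contains(sq, 1, 0.5))   # boundary
  holed <- polygon2(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                    holes = list(rbind(c(0.25, 0.25), c(0.75, 0.25),
                                       c(0.75, 0.75), c(0.25, 0.75))))
  expect_false(contains(holed, 0.5, 0.5))      # in the hole
  expect_true(contains(holed, 0.1, 0.1))
  expect_true(contains(holed, 0.25, 0.5))      # hole boundary counts inside
})

test_that("geographic bearings map 0 to north and 90 to east", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  circ <- polygon2(cbind(cos(th), sin(th)), validate = FALSE)
  n <- ray_outermost_intersection(circ, c(0, 0), 0)
  e <- ray_outermost_intersection(circ, c(0, 0), 90)
  expect_equal(unname(n), c(0, 1), tolerance = 1e-6)
  expect_equal(unname(e), c(1, 0), tolerance = 1e-6)
})

test_that("rays through concave notches return the outermost crossing", {
  star <- make_virtual_territory("star")$outer
  cen <- polygon_centroid(star)
  for (b in seq(0, 350, by = 7)) {
    got <- ray_outermost_intersection(star, cen, b)
    want <- ray_oracle(star$exterior, cen, b)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
    # result must lie on the exterior ring and inside the polygon
    expect_true(contains(star, got[1], got[2]))
    res <- territr:::points_in_ring_cpp(got[1], got[2], star$exterior, 1e-9)
    expect_equal(as.integer(res), 2L)
  }
  # first-crossing option returns a nearer point for some bearing
  t_out <- vapply(seq(0, 359), function(b) {
    p <- ray_outermost_intersection(star, cen, b)
    sqrt(sum((p - cen)^2))
  }, 0)
  t_first <- vapply(seq(0, 359), function(b) {
    p <- ray_outermost_intersection(star, cen, b, crossing = "first")
    sqrt(sum((p - cen)^2))
  }, 0)
  expect_true(all(t_first <= t_out + 1e-9))
})

test_that("rays from outside the polygon are a domain error", {
  sq <- polygon2(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_error(ray_outermost_intersection(sq, c(5, 5), 0),
               class = "territr_domain_error")
})

test_that("delaunay triangulations are valid and cover the convex hull", {
  set.seed(21)
  for (case in list(cbind(runif(40), runif(40)),
                    trial_points(simulate_trials(circle_territory(), 60,
                                                 seed = 2)))) {
    xy <- territr:::as_xy(case)
    tri <- delaunay(xy)
    # every edge in at most two triangles, boundary edges form the hull
    e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    expect_true(all(table(key) <= 2))
    # total triangle area equals convex hull area
    ta <- sum(vapply(seq_len(nrow(tri)), function(i) {
      abs(territr:::ring_signed_area(xy[tri[i, ], ]))
    }, 0))
    expect_equal(ta, mcp(xy)$area, tolerance = 1e-4)
  }
})
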