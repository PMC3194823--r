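test_that("href follows the bivariate normal-reference formula", {
  # n = 64 with unit marginal SDs forces h = 64^(-1/6) = 0.5
  set.seed(2)
  xy <- cbind(rnorm(64), rnorm(64))
  xy <- scale(xy) # exactly unit SD
  expect_equal(href_bandwidth(xy), 64^(-1 / 6), tolerance = 1e-12)
  # scale equivariance
  pts <- tibble::tibble(x = runif(30), y = runif(30))
  expect_equal(href_bandwidth(dplyr::mutate(pts, x = 3 * x, y = 3 * y)),
               3 * href_bandwidth(pts), tolerance = 1e-12)
  # direct formula re-evaluation on a disc sample
  set.seed(11)
  th <- runif(360, 0, 2 * pi); r <- sqrt(runif(360))
  disc <- cbind(r * cos(th), r * sin(th))
  expect_equal(href_bandwidth(disc),
               sqrt((sd(disc[, 1])^2 + sd(disc[, 2])^2) / 2) * 360^(-1 / 6),
               tolerance = 1e-12)
  expect_error(href_bandwidth(cbind(rep(1, 5), rep(2, 5))),
               class = "territr_zero_variance")
})

test_that("closed-form LSCV score matches numeric quadrature", {
  set.seed(6)
  xy <- cbind(rnorm(20), rnorm(20))
  d2 <- as.numeric(dist(xy))^2
  d2 <- c(d2, d2)
  for (h in c(0.3, 0.5, 0.9)) {
    expect_equal(territr:::lscv_score(h, d2, 20), lscv_numeric(xy, h),
                 tolerance = 1e-3)
  }
})

test_that("LSCV finds a local minimum away from boundaries on smooth samples", {
  set.seed(5)
  xy <- cbind(rnorm(100), rnorm(100))
  fit <- lscv_bandwidth(xy)
  expect_true(fit$converged)
  d2 <- as.numeric(dist(xy))^2; d2 <- c(d2, d2)
  expect_lte(territr:::lscv_score(fit$h, d2, 100),
             territr:::lscv_score(fit$h * 1.05, d2, 100))
  expect_lte(territr:::lscv_score(fit$h, d2, 100),
             territr:::lscv_score(fit$h / 1.05, d2, 100))
})

test_that("LSCV flags boundary minimisers on clumped input instead of failing", {
  set.seed(8)
  c1 <- cbind(rnorm(20, 0, 1e-3), rnorm(20, 0, 1e-3))
  c2 <- cbind(rnorm(20, 10, 1e-3), rnorm(20, 10, 1e-3))
  fit <- lscv_bandwidth(rbind(c1, c2))
  expect_false(fit$converged)
})

test_that("a single-kernel density matches the bivariate normal closed form", {
  ud <- kde_density(matrix(c(0, 0), 1), h = 1)
  expect_equal(max(ud$z), 1 / (2 * pi), tolerance = 1e-3)
  expect_gte(ud$total_mass, 0.99)
  iso <- kde_isopleth(ud, c(50, 95))
  # area pi (h sqrt(-2 ln(1 - p))) ^ 2
  expect_equal(isopleth_area_at(iso, 50), pi * 2 * log(2), tolerance = 0.02)
  expect_equal(isopleth_area_at(iso, 95), pi * (-2 * log(0.05)),
               tolerance = 0.02)
})

test_that("kernel mass stays above 0.99 and isopleths are nested", {
  tr <- circle_territory()
  pts <- trial_points(simulate_trials(tr, 60, seed = 4))
  ud <- kde_density(pts, selector = "href")
  expect_gte(ud$total_mass, 0.99)
  iso <- kde_isopleth(ud, c(5, 25, 50, 75, 95, 99))
  expect_true(all(diff(iso$areas) >= 0))
  # nesting: vertices of the smaller level lie inside some larger-level ring
  for (i in seq_along(iso$levels)[-1]) {
    small <- iso$polygons[[i - 1]]
    big <- iso$polygons[[i]]
    for (r in small) {
      inside <- vapply(big, function(bb) {
        all(territr:::points_in_ring_cpp(r[, 1], r[, 2], bb, 1e-7) >= 1L)
      }, TRUE)
      expect_true(any(inside))
    }
  }
  expect_error(kde_isopleth(ud, 100), class = "territr_bad_level")
})

test_that("adaptive kernels equal fixed kernels when pilot densities are uniform", {
  # four corners of a square: pilot density identical at each point by symmetry
  sq <- tibble::tibble(x = c(-1, 1, 1, -1), y = c(-1, -1, 1, 1))
  fixed <- kde_density(sq, h = 0.8, mode = "fixed")
  adap <- kde_density(sq, h = 0.8, mode = "adaptive")
  expect_equal(adap$z, fixed$z, tolerance = 1e-10)
  # and differ when the pattern is asymmetric
  asym <- tibble::tibble(x = c(0, .1, .2, 5, 6), y = c(0, .1, -.1, 5, 4))
  expect_gt(max(abs(kde_density(asym, h = 1, mode = "adaptive")$z -
                    kde_density(asym, h = 1, mode = "fixed")$z)), 1e-6)
})

test_that("LSCV kernel areas fluctuate over trial counts while detailed hulls grow steadily", {
  tr <- circle_territory()
  trials <- simulate_trials(tr, 360, seed = 1)
  ks <- c(12, 18, 24, 36, 60, 90, 180, 360)
  areas <- vapply(ks, function(k) {
    dirs <- enumerate_equiangular_subsets(k)[[1]]
    pts <- trial_points(trials, dirs)
    c(lscv = isopleth_area_at(kde_isopleth(
        kde_density(pts, selector = "lscv"), 95), 95),
      dh = detailed_hull(pts)$area)
  }, c(lscv = 0, dh = 0))
  d_lscv <- diff(areas["lscv", ])
  d_dh <- diff(areas["dh", ])
  expect_gte(sum(diff(sign(d_lscv)) != 0), 1)  # at least one reversal
  expect_true(all(d_dh >= -1e-6))              # asymptotic growth
})
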