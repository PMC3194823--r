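# Independent oracles used across the suite. These deliberately use brute
# force (dense rasters, segment-by-segment intersection, numeric quadrature)
# so they share no code path with the implementation they check.

# Raster union area of a set of convex rings: fraction of pixel centres
# covered times bbox area.
pixel_union_area <- function(rings, n = 400) {
  allxy <- do.call(rbind, rings)
  xr <- range(allxy[, 1]); yr <- range(allxy[, 2])
  gx <- seq(xr[1], xr[2], length.out = n)
  gy <- seq(yr[1], yr[2], length.out = n)
  px <- rep(gx, times = n); py <- rep(gy, each = n)
  covered <- rep(FALSE, length(px))
  for (r in rings) {
    res <- territr:::points_in_ring_cpp(px, py, r, 1e-12)
    covered <- covered | res >= 1L
  }
  mean(covered) * diff(xr) * diff(yr)
}

# Hole count of a union of convex rings by flood fill on a raster:
# uncovered pixel components that do not touch the border are holes.
pixel_hole_count <- function(rings, n = 200, pad = 0.05) {
  allxy <- do.call(rbind, rings)
  xr <- range(allxy[, 1]); yr <- range(allxy[, 2])
  xr <- xr + c(-1, 1) * pad * diff(xr)
  yr <- yr + c(-1, 1) * pad * diff(yr)
  gx <- seq(xr[1], xr[2], length.out = n)
  gy <- seq(yr[1], yr[2], length.out = n)
  px <- rep(gx, times = n); py <- rep(gy, each = n)
  covered <- rep(FALSE, length(px))
  for (r in rings) {
    res <- territr:::points_in_ring_cpp(px, py, r, 1e-12)
    covered <- covered | res >= 1L
  }
  m <- matrix(covered, n, n)          # [ix, iy]
  lab <- matrix(0L, n, n)
  cur <- 0L
  holes <- 0L
  for (sx in seq_len(n)) for (sy in seq_len(n)) {
    if (m[sx, sy] || lab[sx, sy] != 0L) next
    cur <- cur + 1L
    touches_border <- FALSE
    stack <- list(c(sx, sy))
    lab[sx, sy] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (p[1] == 1 || p[1] == n || p[2] == 1 || p[2] == n) touches_border <- TRUE
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] < 1 || q[1] > n || q[2] < 1 || q[2] > n) next
        if (m[q[1], q[2]] || lab[q[1], q[2]] != 0L) next
        lab[q[1], q[2]] <- cur
        stack[[length(stack) + 1]] <- q
      }
    }
    if (!touches_border) holes <- holes + 1L
  }
  holes
}

# Brute-force outermost ray-ring intersection: test every segment.
ray_oracle <- function(ring, origin, bearing_deg) {
  th <- bearing_deg * pi / 180
  d <- c(sin(th), cos(th))
  n <- nrow(ring)
  best <- NULL; best_t <- -Inf
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[if (i == n) 1 else i + 1, ]
    e <- b - a
    den <- d[1] * e[2] - d[2] * e[1]
    if (abs(den) < 1e-14) next
    w <- a - origin
    t <- (w[1] * e[2] - w[2] * e[1]) / den
    s <- (w[1] * d[2] - w[2] * d[1]) / den
    if (t > 1e-12 && s >= -1e-12 && s <= 1 + 1e-12 && t > best_t) {
      best_t <- t
      best <- origin + t * d
    }
  }
  best
}

# Numeric-quadrature LSCV score: grid integration of the squared density
# plus direct leave-one-out evaluation.
lscv_numeric <- function(xy, h, ngrid = 160) {
  n <- nrow(xy)
  pad <- 4 * h
  gx <- seq(min(xy[, 1]) - pad, max(xy[, 1]) + pad, length.out = ngrid)
  gy <- seq(min(xy[, 2]) - pad, max(xy[, 2]) + pad, length.out = ngrid)
  f <- outer(gx, gy, Vectorize(function(x, y) {
    sum(exp(-((x - xy[, 1])^2 + (y - xy[, 2])^2) / (2 * h^2))) /
      (2 * pi * h^2 * n)
  }))
  int_f2 <- sum(f^2) * diff(gx[1:2]) * diff(gy[1:2])
  loo <- vapply(seq_len(n), function(i) {
    d2 <- (xy[-i, 1] - xy[i, 1])^2 + (xy[-i, 2] - xy[i, 2])^2
    sum(exp(-d2 / (2 * h^2))) / (2 * pi * h^2 * (n - 1))
  }, 0)
  int_f2 - 2 * mean(loo)
}

# A fixed 40-point sample over a plus/cross-shaped region (two overlapping
# bars), deterministic.
plus_points <- function() {
  set.seed(4242)
  horiz <- cbind(runif(20, -3, 3), runif(20, -0.7, 0.7))
  vert <- cbind(runif(20, -0.7, 0.7), runif(20, -3, 3))
  tibble::tibble(x = c(horiz[, 1], vert[, 1]), y = c(horiz[, 2], vert[, 2]))
}

circle_territory <- function() make_virtual_territory("circle")
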