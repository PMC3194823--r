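# Virtual territories: a central area (display/resting sites) nested inside
# a larger defended outer region, with known true area -- the ground truth
# for estimator benchmarking.

# Unit outlines for the six built-in shapes, before scaling to the target
# area. The circle/ellipse are fine 720-gons so the polygon area equals the
# target exactly after scaling. Star, angle and irregular reproduce the shape
# classes (convex / concave / highly concave), not any particular geometry.
shape_outline <- function(shape_name) {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  switch(
    shape_name,
    circle = cbind(cos(th), sin(th)),
    ellipse = cbind(2 * cos(th), sin(th)),
    triangle = {
      a <- c(90, 210, 330) * pi / 180
      cbind(cos(a), sin(a))
    },
    star = {
      a <- (90 + 36 * (0:9)) * pi / 180
      r <- rep(c(1, 0.5), 5)
      cbind(r * cos(a), r * sin(a))
    },
    angle = rbind( # L-shape; arm width 1/2 keeps the centroid (the bearing
      # origin for edge points) inside the polygon, which thinner arms do not
      c(0, 0), c(1, 0), c(1, 1 / 2), c(1 / 2, 1 / 2), c(1 / 2, 1), c(0, 1)),
    irregular = rbind( # fixed 12-vertex concave outline
      c(0.0, 0.0), c(1.6, -0.4), c(2.4, 0.7), c(1.5, 0.9), c(2.6, 1.8),
      c(1.9, 2.6), c(0.9, 1.7), c(0.6, 2.8), c(-0.6, 2.2), c(-0.2, 1.1),
      c(-1.3, 1.0), c(-0.9, 0.1)),
    abort(sprintf("unknown shape '%s'", shape_name), class = "territr_bad_shape")
  )
}

#' Construct a virtual territory
#'
#' Builds a nested pair of polygons: an outer defended region scaled so its
#' polygon area equals `true_area`, and a central area obtained by shrinking
#' the outer polygon about its centroid by `central_scale` (linear factor).
#' Six built-in outlines span convex to highly concave shapes; the default
#' true areas are the benchmark set
#' (ellipse 243.58, star 130.09, triangle 88, circle 200.04, angle 155.63,
#' irregular 395.11, arbitrary units).
#'
#' @param shape_name One of `"ellipse"`, `"star"`, `"triangle"`, `"angle"`,
#'   `"circle"`, `"irregular"`, or a custom [polygon2] / vertex matrix.
#' @param true_area Target outer area (> 0). Defaults to the benchmark value
#'   for built-in shapes.
#' @param central_scale Linear scale of the central area relative to the
#'   outer polygon (0 < s < 1).
#' @param centre Optional length-2 translation applied to the whole territory.
#' @return An object of class `territory` with elements `outer`, `central`
#'   (both [polygon2]), `true_area` and `shape_name`.
#' @examples
#' tr <- make_virtual_territory("circle")
#' polygon_area(tr$outer)
#' @export
make_virtual_territory <- function(shape_name, true_area = NULL,
                                   central_scale = 0.3, centre = c(0, 0)) {
  default_areas <- c(ellipse = 243.58, star = 130.09, triangle = 88,
                     circle = 200.04, angle = 155.63, irregular = 395.11)
  if (is.character(shape_name)) {
    label <- shape_name
    if (is.null(true_area)) {
      true_area <- unname(default_areas[shape_name])
      if (is.na(true_area)) abort("true_area required for unknown shape label")
    }
    ring <- shape_outline(shape_name)
    outer <- polygon2(ring, validate = FALSE)
  } else {
    label <- "custom"
    outer <- if (inherits(shape_name, "polygon2")) shape_name else polygon2(shape_name)
    if (is.null(true_area)) true_area <- polygon_area(outer)
  }
  stopifnot(true_area > 0, central_scale > 0, central_scale < 1)
  cen <- polygon_centroid(outer)
  f <- sqrt(true_area / polygon_area(outer))
  # scale about the centroid, then recentre the centroid at `centre`
  ring <- scale_ring(outer$exterior, f, cen)
  cen2 <- polygon_centroid(polygon2(ring, validate = FALSE))
  ring <- translate_ring(ring, centre - cen2)
  outer <- polygon2(ring, validate = FALSE)
  cen3 <- polygon_centroid(outer)
  central <- polygon2(scale_ring(outer$exterior, central_scale, cen3),
                      validate = FALSE)
  if (!all(contains(outer, central$exterior[, 1], central$exterior[, 2]))) {
    abort("central area is not contained in the outer region (outline not star-shaped enough about its centroid); supply a smaller central_scale or a different outline",
          class = "territr_invalid_geometry")
  }
  structure(list(outer = outer, central = central,
                 true_area = true_area, shape_name = label),
            class = "territory")
}

#' @export
print.territory <- function(x, ...) {
  cat(sprintf("<territory '%s'> true area %.4g, central area %.4g\n",
              x$shape_name, x$true_area, polygon_area(x$central)))
  invisible(x)
}

#' @export
tidy.territory <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$outer), part = "outer"),
    dplyr::mutate(tidy(x$central), part = "central")
  )
}

#' @export
glance.territory <- function(x, ...) {
  tibble(shape = x$shape_name, true_area = x$true_area,
         central_area = polygon_area(x$central),
         outer_vertices = nrow(x$outer$exterior))
}

#' @rdname autoplot.territory
#' @export
plot_territory <- function(object, ...) autoplot.territory(object, ...)

#' Plot a territory
#'
#' @param object A `territory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.territory <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, group = .data$part)) +
    ggplot2::geom_polygon(ggplot2::aes(fill = .data$part),
                          colour = "grey30", alpha = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$shape_name) +
    ggplot2::theme_minimal()
}
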