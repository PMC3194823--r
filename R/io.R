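# Formats: CSV is the canonical trial format (field teams use spreadsheets),
# RFC 7946 GeoJSON the canonical geometry format. Every written artifact
# embeds the package version and any supplied run parameters so a run is
# reproducible from its outputs.

trial_cols <- c("individual", "direction_deg", "start_x", "start_y",
                "end_x", "end_y", "responded")

#' Read a trial table from CSV
#'
#' Expected columns: `individual`, `direction_deg`, `start_x`, `start_y`,
#' `end_x`, `end_y`, `responded`. Blank end coordinates with
#' `responded = FALSE` parse as non-responses; a responded trial with a
#' blank endpoint is a row-level error.
#'
#' @param path CSV file path.
#' @return Trial-set tibble.
#' @export
read_trials_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          individual = readr::col_character(),
                          direction_deg = readr::col_double(),
                          start_x = readr::col_double(),
                          start_y = readr::col_double(),
                          end_x = readr::col_double(),
                          end_y = readr::col_double(),
                          responded = readr::col_logical()))
  missing <- setdiff(trial_cols, names(df))
  if (length(missing)) {
    abort(paste("missing column(s):", paste(missing, collapse = ", ")),
          class = "territr_schema_error")
  }
  bad <- which(!complete.cases(df[, c("direction_deg", "start_x", "start_y")]))
  if (length(bad)) {
    abort(sprintf("non-numeric or missing coordinate in row(s) %s (header is line 1)",
                  paste(bad + 1, collapse = ", ")),
          class = "territr_row_error")
  }
  bad_end <- which(df$responded & (is.na(df$end_x) | is.na(df$end_y)))
  if (length(bad_end)) {
    abort(sprintf("responded trial without endpoint in row(s) %s",
                  paste(bad_end + 1, collapse = ", ")),
          class = "territr_row_error")
  }
  df[trial_cols]
}

#' Write a trial table to CSV
#'
#' Round-trips losslessly with [read_trials_csv()].
#'
#' @param trials Trial-set tibble.
#' @param path Output path.
#' @export
write_trials_csv <- function(trials, path) {
  readr::write_csv(trials[trial_cols], path)
  invisible(path)
}

geojson_polygon_coords <- function(poly) {
  close_coords <- function(r) {
    r <- rbind(r, r[1, ])
    lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
  }
  c(list(close_coords(poly$exterior)), lapply(poly$holes, close_coords))
}

feature <- function(geometry, properties) {
  list(type = "Feature",
       geometry = geometry,
       properties = properties)
}

polygon_geometry <- function(poly) {
  list(type = "Polygon", coordinates = geojson_polygon_coords(poly))
}

#' Write geometries as GeoJSON
#'
#' Writes an RFC 7946 FeatureCollection. Supported inputs: `territory`
#' (outer + central polygon features), point tibbles (`x`, `y` plus any
#' extra columns as properties), `hull_estimate` (method and parameters as
#' properties), `isopleth_set` (one feature per level with a numeric
#' `level` property) and `link_set` (LineString features with a `kind`
#' property). Run metadata (package version plus anything in `config`) is
#' embedded under a top-level `"territr"` member.
#'
#' @param x Object to write.
#' @param path Output path.
#' @param config Optional named list of run parameters (seed, thresholds,
#'   ...) recorded in the file.
#' @export
write_geojson <- function(x, path, config = list()) {
  feats <- geojson_features(x)
  fc <- list(type = "FeatureCollection",
             territr = c(list(version = as.character(utils::packageVersion("territr"))),
                         config),
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

geojson_features <- function(x) UseMethod("geojson_features")

#' @export
geojson_features.territory <- function(x) {
  list(feature(polygon_geometry(x$outer),
               list(part = "outer", shape = x$shape_name,
                    true_area = x$true_area)),
       feature(polygon_geometry(x$central),
               list(part = "central", shape = x$shape_name)))
}

#' @export
geojson_features.polygon2 <- function(x) {
  list(feature(polygon_geometry(x), list()))
}

#' @export
geojson_features.hull_estimate <- function(x) {
  props <- c(list(method = x$method, area = x$area, n_points = x$n_points),
             x$params)
  list(feature(polygon_geometry(x$polygon), props))
}

#' @export
geojson_features.isopleth_set <- function(x) {
  unlist(lapply(seq_along(x$levels), function(i) {
    rings <- x$polygons[[i]]
    if (!length(rings)) return(list())
    lapply(seq_along(rings), function(r) {
      feature(polygon_geometry(polygon2(rings[[r]], validate = FALSE)),
              list(level = x$levels[i], ring = r, area_level = x$areas[i]))
    })
  }), recursive = FALSE)
}

#' @export
geojson_features.link_set <- function(x) {
  lapply(seq_len(nrow(x)), function(i) {
    feature(list(type = "LineString",
                 coordinates = list(c(x$source_x[i], x$source_y[i]),
                                    c(x$target_x[i], x$target_y[i]))),
            list(kind = x$kind[i], direction_deg = x$direction_deg[i]))
  })
}

#' @export
geojson_features.data.frame <- function(x) {
  stopifnot(all(c("x", "y") %in% names(x)))
  extra <- setdiff(names(x), c("x", "y"))
  lapply(seq_len(nrow(x)), function(i) {
    feature(list(type = "Point", coordinates = c(x$x[i], x$y[i])),
            as.list(x[i, extra, drop = FALSE]))
  })
}

#' Read points or polygons from GeoJSON
#'
#' Reads a FeatureCollection written by [write_geojson()] (or any RFC 7946
#' file with Point / Polygon features).
#'
#' @param path GeoJSON path.
#' @return For point features, a tibble (`x`, `y`, plus properties); for
#'   polygon features, a list of [polygon2] with a `properties` attribute
#'   per element.
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  types <- vapply(feats, function(f) f$geometry$type, "")
  if (all(types == "Point")) {
    purrr::map_dfr(feats, function(f) {
      co <- f$geometry$coordinates
      props <- f$properties
      c(tibble(x = co[[1]], y = co[[2]]),
        if (length(props)) tibble::as_tibble(props[lengths(props) == 1]))
    })
  } else {
    lapply(feats, function(f) {
      rings <- lapply(f$geometry$coordinates, function(ring) {
        do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      })
      p <- polygon2(rings[[1]], holes = rings[-1], validate = FALSE)
      attr(p, "properties") <- f$properties
      p
    })
  }
}
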