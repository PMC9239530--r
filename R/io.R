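#' Write cell records to GeoJSON
#'
#' One Feature per cell: a Polygon for cells with a contour (the centre kept
#' in `properties.center`), a Point otherwise. Properties carry `class`,
#' `grade` and `area` when present.
#'
#' @param cells A cells data frame (`cell_class`, `x`, `y`, optional `grade`,
#'   `area`, `contour` list-column).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cells_geojson <- function(cells, path) {
  features <- purrr::map(seq_len(nrow(cells)), function(i) {
    props <- list(class = cells$cell_class[i])
    if ("grade" %in% names(cells) && !is.na(cells$grade[i])) {
      props$grade <- cells$grade[i]
    }
    if ("area" %in% names(cells) && !is.na(cells$area[i])) {
      props$area <- cells$area[i]
    }
    contour <- if ("contour" %in% names(cells)) cells$contour[[i]] else NULL
    if (!is.null(contour)) {
      ring <- as_ring(contour)
      ring <- rbind(ring, ring[1, ]) # GeoJSON rings are closed
      props$center <- c(cells$x[i], cells$y[i])
      geometry <- list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(r) ring[r, ]))
      )
    } else {
      geometry <- list(type = "Point", coordinates = c(cells$x[i], cells$y[i]))
    }
    list(type = "Feature", geometry = geometry, properties = props)
  })
  obj <- list(type = "FeatureCollection", features = features)
  if (!is.null(magnification(cells))) {
    obj$properties <- list(magnification = magnification(cells))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read cell records from GeoJSON
#'
#' @param path A file written by [write_cells_geojson()] (or any
#'   FeatureCollection of Point/Polygon cell features with a `class`
#'   property).
#' @return A cells tibble.
#' @export
read_cells_geojson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(obj$type, "FeatureCollection"))
  rows <- purrr::map(obj$features, function(f) {
    geom <- f$geometry
    props <- f$properties
    if (identical(geom$type, "Polygon")) {
      ring <- do.call(rbind, lapply(geom$coordinates[[1]], unlist))
      ring <- as_ring(ring)
      center <- if (!is.null(props$center)) {
        unlist(props$center)
      } else {
        colMeans(ring)
      }
      contour <- list(ring)
      area <- props$area %||% polygon_area(ring)
    } else if (identical(geom$type, "Point")) {
      center <- unlist(geom$coordinates)
      contour <- list(NULL)
      area <- props$area %||% NA_real_
    } else {
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    }
    tibble::tibble(
      cell_class = props$class %||% NA_character_,
      x = center[1], y = center[2],
      grade = as.integer(props$grade %||% NA_integer_),
      area = as.numeric(area),
      contour = contour
    )
  })
  out <- dplyr::bind_rows(rows)
  mag <- obj$properties$magnification
  if (!is.null(mag)) out <- set_magnification(out, mag)
  out
}

#' Write cell records to CSV
#'
#' Flat export (`class,x,y,grade,area`); contours are not serialized — use
#' [write_cells_geojson()] to keep them.
#'
#' @param cells A cells data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cells_csv <- function(cells, path) {
  df <- data.frame(
    class = cells$cell_class, x = cells$x, y = cells$y,
    grade = if ("grade" %in% names(cells)) cells$grade else NA_integer_,
    area = if ("area" %in% names(cells)) cells$area else NA_real_
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read cell records from CSV
#'
#' @param path A CSV with columns `class,x,y` and optionally `grade,area`.
#' @return A cells tibble.
#' @export
read_cells_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(
    cell_class = df$class, x = df$x, y = df$y,
    grade = as.integer(df$grade %||% NA_integer_),
    area = as.numeric(df$area %||% NA_real_)
  )
}
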