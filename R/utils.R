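# Internal helpers shared across modules.

# Evaluate `code` with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so generators never perturb user code.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Shoelace area of a simple polygon given as a 2-column matrix (open ring).
polygon_area <- function(poly) {
  poly <- as_ring(poly)
  x <- poly[, 1]
  y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Coerce polygon input (matrix, data frame, or list(x=, y=)) to an open
# 2-column matrix ring.
as_ring <- function(poly) {
  if (is.list(poly) && !is.data.frame(poly) && all(c("x", "y") %in% names(poly))) {
    poly <- cbind(poly$x, poly$y)
  }
  poly <- as.matrix(poly)
  if (ncol(poly) != 2 || nrow(poly) < 3) {
    stop("a polygon needs at least 3 vertices with x and y columns", call. = FALSE)
  }
  storage.mode(poly) <- "double"
  # drop an explicitly closed last vertex
  n <- nrow(poly)
  if (isTRUE(all(poly[1, ] == poly[n, ])) && n > 3) poly <- poly[-n, , drop = FALSE]
  unname(poly)
}

# Regular polygon approximating an ellipse, rescaled so its shoelace area
# equals `area` exactly (so stored areas, contours, and grade bins agree).
ellipse_polygon <- function(area, axis_ratio = 1, angle = 0, cx = 0, cy = 0, n_vertices = 24) {
  stopifnot(area > 0, axis_ratio > 0)
  a <- sqrt(area / (pi * axis_ratio))
  b <- a * axis_ratio
  t <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  px <- a * cos(t)
  py <- b * sin(t)
  ring <- cbind(px * cos(angle) - py * sin(angle), px * sin(angle) + py * cos(angle))
  ring <- ring * sqrt(area / polygon_area(ring))
  cbind(ring[, 1] + cx, ring[, 2] + cy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Magnification tag plumbing: cells tibbles and rasters carry a "20x"/"40x" tag.
magnification <- function(x) attr(x, "magnification", exact = TRUE)

#' Tag an object with its scan magnification
#'
#' @param x A cells data frame or raster array.
#' @param tag Either `"20x"` or `"40x"`.
#' @return `x` with a `magnification` attribute set.
#' @export
set_magnification <- function(x, tag) {
  tag <- match.arg(tag, c("20x", "40x"))
  attr(x, "magnification") <- tag
  x
}
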