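#' Upscale a 20x-scanned input to the 40x frame
#'
#' Slides scanned at 20x are brought to the common 40x analysis frame by a
#' factor-of-two linear resize: rasters are bilinearly interpolated to twice
#' their width and height; cell records have coordinates and contour vertices
#' doubled and areas multiplied by four.
#'
#' @param x A cells data frame or a raster array (height x width x channels),
#'   tagged `"20x"` via [set_magnification()].
#' @return The rescaled object, tagged `"40x"`.
#' @export
upscale_to_40x <- function(x) {
  tag <- magnification(x)
  if (is.null(tag)) {
    stop("input has no magnification tag; use set_magnification()", call. = FALSE)
  }
  if (tag == "40x") {
    stop("input is already tagged 40x", call. = FALSE)
  }
  if (is.data.frame(x)) {
    x$x <- x$x * 2
    x$y <- x$y * 2
    if ("area" %in% names(x)) x$area <- x$area * 4
    if ("contour" %in% names(x)) {
      x$contour <- purrr::map(x$contour, function(p) if (is.null(p)) NULL else p * 2)
    }
    return(set_magnification(x, "40x"))
  }
  if (is.array(x)) {
    rlang::check_installed("EBImage", reason = "to resize rasters")
    d <- dim(x)
    # EBImage images are x-by-y; ours are row (y) by column (x)
    img <- EBImage::Image(aperm(x, c(2, 1, 3)[seq_along(d)]),
      colormode = if (length(d) == 3) "Color" else "Grayscale"
    )
    res <- EBImage::resize(img, w = d[2] * 2, h = d[1] * 2, filter = "bilinear")
    out <- aperm(EBImage::imageData(res), c(2, 1, 3)[seq_along(d)])
    return(set_magnification(out, "40x"))
  }
  stop("`x` must be a cells data frame or a raster array", call. = FALSE)
}

#' Tissue mask by HSV saturation threshold
#'
#' A pixel is called tissue when its HSV saturation, on the 8-bit 0-255 scale,
#' strictly exceeds `s_threshold`. Saturation is `(max - min) / max * 255`
#' over the RGB channels (0 where all channels are 0), so the mask is
#' invariant to whether the raster stores 0-1 or 0-255 intensities.
#'
#' @param raster A height x width x 3 RGB array.
#' @param s_threshold Saturation threshold on the 0-255 scale (default 30).
#' @return A logical height x width matrix, `TRUE` for tissue.
#' @export
tissue_mask <- function(raster, s_threshold = 30) {
  d <- dim(raster)
  if (length(d) != 3 || d[3] != 3) {
    stop("`raster` must be a height x width x 3 RGB array", call. = FALSE)
  }
  mx <- pmax(raster[, , 1], raster[, , 2], raster[, , 3])
  mn <- pmin(raster[, , 1], raster[, , 2], raster[, , 3])
  s <- ifelse(mx > 0, (mx - mn) / mx * 255, 0)
  mask <- s > s_threshold
  dim(mask) <- d[1:2]
  mask
}

#' Build a fixed tile grid over a slide canvas
#'
#' Partitions the canvas into half-open `tile_size`-px squares; partial
#' right/bottom remainders are dropped so all tiles have equal area (tile-wise
#' features compare absolute counts). A tile is flagged as tissue when at
#' least `tissue_fraction_min` of its pixels are tissue in `mask`; with no
#' mask every tile is tissue.
#'
#' @param width,height Canvas size in pixels; must each fit one full tile.
#' @param mask Optional logical height x width tissue mask (see
#'   [tissue_mask()]).
#' @param tile_size Tile side in pixels (default 1,024).
#' @param tissue_fraction_min Minimum tissue-pixel fraction for a tissue tile.
#' @return A `tile_grid` object with `n_rows`, `n_cols`, `tile_size` and a
#'   logical `tissue` matrix.
#' @export
build_tile_grid <- function(width, height, mask = NULL, tile_size = 1024,
                            tissue_fraction_min = 0.05) {
  stopifnot(tile_size > 0)
  if (width < tile_size || height < tile_size) {
    stop("canvas must be at least one full tile in each dimension", call. = FALSE)
  }
  n_rows <- floor(height / tile_size)
  n_cols <- floor(width / tile_size)
  tissue <- matrix(TRUE, n_rows, n_cols)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
    if (nrow(mask) < n_rows * tile_size || ncol(mask) < n_cols * tile_size) {
      stop("mask is smaller than the tiled canvas", call. = FALSE)
    }
    for (r in seq_len(n_rows)) {
      for (cc in seq_len(n_cols)) {
        block <- mask[
          ((r - 1) * tile_size + 1):(r * tile_size),
          ((cc - 1) * tile_size + 1):(cc * tile_size)
        ]
        tissue[r, cc] <- mean(block) >= tissue_fraction_min
      }
    }
  }
  structure(
    list(
      tile_size = tile_size, n_rows = n_rows, n_cols = n_cols,
      width = width, height = height, tissue = tissue
    ),
    class = "tile_grid"
  )
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf(
    "<tile_grid> %d x %d tiles of %d px (%d tissue)\n",
    x$n_rows, x$n_cols, x$tile_size, sum(x$tissue)
  ))
  invisible(x)
}

#' Count cells per tile
#'
#' Assigns each cell centre to the unique half-open tile containing it and
#' tallies tumor and TIL counts per tile. Cells falling in dropped remainder
#' regions (or off-canvas) are not assigned; their number is reported in the
#' `dropped` attribute and as a warning when non-zero.
#'
#' @param cells A cells data frame with `cell_class`, `x`, `y`.
#' @param grid A [build_tile_grid()] result.
#' @return A tibble with one row per tile: `row`, `col` (0-based),
#'   `tumor_count`, `til_count`, `tumor_pct` (`tumor / (tumor + til)`, 0 when
#'   the tile is empty) and `tissue`.
#' @export
assign_cells_to_tiles <- function(cells, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  ts <- grid$tile_size
  row <- floor(cells$y / ts)
  col <- floor(cells$x / ts)
  inside <- row >= 0 & row < grid$n_rows & col >= 0 & col < grid$n_cols &
    cells$x >= 0 & cells$y >= 0
  dropped <- sum(!inside)
  if (dropped > 0) {
    warning(sprintf("%d cell(s) fall outside the tiled area and were dropped", dropped))
  }

  all_tiles <- tidyr::expand_grid(
    row = seq_len(grid$n_rows) - 1L,
    col = seq_len(grid$n_cols) - 1L
  )
  counted <- tibble::tibble(
    row = as.integer(row[inside]),
    col = as.integer(col[inside]),
    cell_class = cells$cell_class[inside]
  ) |>
    dplyr::count(.data$row, .data$col, .data$cell_class) |>
    tidyr::pivot_wider(
      names_from = "cell_class", values_from = "n", values_fill = 0L
    )
  for (cls in c("tumor", "til")) {
    if (!cls %in% names(counted)) counted[[cls]] <- 0L
  }
  out <- all_tiles |>
    dplyr::left_join(counted, by = c("row", "col")) |>
    dplyr::mutate(
      tumor_count = dplyr::coalesce(.data$tumor, 0L),
      til_count = dplyr::coalesce(.data$til, 0L),
      total = .data$tumor_count + .data$til_count,
      tumor_pct = ifelse(.data$total > 0, .data$tumor_count / .data$total, 0),
      tissue = grid$tissue[cbind(.data$row + 1L, .data$col + 1L)]
    ) |>
    dplyr::select(
      "row", "col", "tumor_count", "til_count", "tumor_pct", "tissue"
    )
  attr(out, "dropped") <- dropped
  out
}

#' Per-class tile density map
#'
#' @param tile_stats Output of [assign_cells_to_tiles()].
#' @param grid The matching [build_tile_grid()].
#' @param cell_class `"tumor"` or `"til"`.
#' @return An `n_rows` x `n_cols` count matrix (class `density_map`); counts
#'   in non-tissue tiles are set to 0.
#' @export
density_map <- function(tile_stats, grid, cell_class = c("tumor", "til")) {
  cell_class <- match.arg(cell_class)
  stopifnot(inherits(grid, "tile_grid"))
  m <- matrix(0, grid$n_rows, grid$n_cols)
  if (nrow(tile_stats) > 0) {
    cnt <- if (cell_class == "tumor") tile_stats$tumor_count else tile_stats$til_count
    cnt[!tile_stats$tissue] <- 0
    m[cbind(tile_stats$row + 1L, tile_stats$col + 1L)] <- cnt
  }
  structure(m, class = c("density_map", class(m)), cell_class = cell_class)
}

#' Select the densest tumor tiles
#'
#' Orders tissue tiles by tumor count, descending, ties broken by row-major
#' tile index, and returns the first `k`. When a slide has fewer than `k`
#' tissue tiles all of them are returned, flagged short (attribute `short`),
#' with a warning.
#'
#' @param tile_stats Output of [assign_cells_to_tiles()].
#' @param k Number of tiles to keep (default 10).
#' @return The top-`k` rows of `tile_stats`, in feature order i = 1..k.
#' @export
select_top_tiles <- function(tile_stats, k = 10) {
  if (k <= 0) stop("`k` must be positive", call. = FALSE)
  tissue <- dplyr::filter(tile_stats, .data$tissue)
  ordered <- dplyr::arrange(
    tissue,
    dplyr::desc(.data$tumor_count), .data$row, .data$col
  )
  short <- nrow(ordered) < k
  if (short) {
    warning(sprintf(
      "only %d tissue tile(s) available for top-%d selection", nrow(ordered), k
    ))
  }
  out <- utils::head(ordered, k)
  attr(out, "short") <- short
  out
}
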