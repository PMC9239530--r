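#' Immunohistochemistry H-score
#'
#' H-score = staining percentage (0-100) x intensity (0-3), range 0-300.
#'
#' @param percentage Percent of stained cells, 0-100.
#' @param intensity Staining intensity, integer 0-3.
#' @return The H-score(s), 0-300. Vectorized.
#' @examples
#' compute_h_score(40, 2) # 80
#' @export
compute_h_score <- function(percentage, intensity) {
  if (any(percentage < 0 | percentage > 100, na.rm = TRUE)) {
    stop("`percentage` must be in [0, 100]", call. = FALSE)
  }
  if (any(!intensity %in% 0:3)) {
    stop("`intensity` must be one of 0, 1, 2, 3", call. = FALSE)
  }
  percentage * intensity
}

#' TIL number variance across selected tiles
#'
#' Sample variance of the per-tile TIL counts over the selected (normally ten)
#' tiles: squared deviations from the mean with divisor m - 1.
#'
#' @param counts TIL counts over the selected tiles; at least 2.
#' @return The variance, in cells^2.
#' @examples
#' til_number_variance(1:10) # 9.1667
#' @export
til_number_variance <- function(counts) {
  if (length(counts) < 2) {
    stop("TIL number variance needs at least 2 tile counts", call. = FALSE)
  }
  stats::var(as.numeric(counts))
}

#' Per-cell nuclear grade from nucleus area
#'
#' Grades a tumor nucleus by the ratio r of its area to the reference TIL
#' nucleus area: grade 1 for r < 2.5 (ratios below 1 are clamped to grade 1),
#' grade 2 for 2.5 <= r <= 3.5, grade 3 for r > 3.5.
#'
#' @param nucleus_area Tumor nucleus area(s), px^2, positive.
#' @param til_ref_area Reference TIL nucleus area, px^2 (default 304.7).
#' @return Integer grade(s) in 1-3. Vectorized.
#' @export
cell_nuclear_grade <- function(nucleus_area, til_ref_area = 304.7) {
  if (any(nucleus_area <= 0, na.rm = TRUE) || any(is.na(nucleus_area))) {
    stop("`nucleus_area` must be positive", call. = FALSE)
  }
  r <- nucleus_area / til_ref_area
  # small tolerance so areas constructed exactly at a bin edge grade stably
  eps <- 1e-9
  ifelse(r < 2.5 - eps, 1L, ifelse(r <= 3.5 + eps, 2L, 3L))
}

#' Aggregate per-cell nuclear grades to a slide grade
#'
#' Cascade over grade fractions f_g: grade 3 if f_3 >= 10%; else grade 2 if
#' f_2 >= 10%; else grade 1. With three grade levels the cascade always
#' terminates (some fraction is at least 1/3).
#'
#' @param grades Per-cell grades in 1-3; non-empty.
#' @return A single integer grade.
#' @export
aggregate_nuclear_grade <- function(grades) {
  if (length(grades) == 0) stop("`grades` must be non-empty", call. = FALSE)
  stopifnot(all(grades %in% 1:3))
  n <- length(grades)
  if (sum(grades == 3) / n >= 0.10) return(3L)
  if (sum(grades == 2) / n >= 0.10) return(2L)
  1L
}

#' Build the slide-level image feature vector
#'
#' Flattens the per-tile triplets (tumor count, TIL count, tumor percentage)
#' of the selected tiles, in selection order, and appends the TIL number
#' variance over those tiles and the aggregated nuclear grade of the tumor
#' cells pooled from them: 3 x 10 + 2 = 32 features for a full ten-tile slide.
#'
#' @param top_stats Ordered tile stats from [select_top_tiles()].
#' @param tumor_areas Nucleus areas (px^2) of tumor cells pooled from the
#'   selected tiles.
#' @param til_ref_area Reference TIL nucleus area, px^2.
#' @return A one-row tibble with columns `t01_tumor`, `t01_til`, `t01_pct`,
#'   ..., `til_var`, `nuc_grade`; attribute `short` is `TRUE` when fewer than
#'   ten tiles were available.
#' @export
build_image_feature_vector <- function(top_stats, tumor_areas, til_ref_area = 304.7) {
  m <- nrow(top_stats)
  if (m < 2) stop("need at least 2 selected tiles", call. = FALSE)
  if (length(tumor_areas) == 0) {
    stop("no tumor areas supplied for nuclear grading", call. = FALSE)
  }
  triplets <- purrr::map(seq_len(m), function(i) {
    v <- c(
      top_stats$tumor_count[i], top_stats$til_count[i], top_stats$tumor_pct[i]
    )
    names(v) <- sprintf("t%02d_%s", i, c("tumor", "til", "pct"))
    v
  })
  flat <- unlist(triplets)
  out <- tibble::as_tibble(as.list(flat))
  out$til_var <- til_number_variance(top_stats$til_count)
  out$nuc_grade <- as.integer(
    aggregate_nuclear_grade(cell_nuclear_grade(tumor_areas, til_ref_area))
  )
  attr(out, "short") <- isTRUE(attr(top_stats, "short")) || m < 10
  attr(out, "n_tiles") <- m
  out
}

#' Extract the image feature vector from a scene
#'
#' Convenience wrapper over the slide-level chain: tile grid, per-tile counts,
#' top-`k` selection, pooling of tumor nucleus areas from the selected tiles,
#' and [build_image_feature_vector()].
#'
#' @param scene A `wsi_scene` (or cells data frame with `width`/`height`).
#' @param mask Optional tissue mask.
#' @param tile_size Tile side in px.
#' @param k Number of top tumor-density tiles.
#' @param til_ref_area Reference TIL nucleus area, px^2.
#' @param width,height Canvas size when `scene` is a plain cells table.
#' @return As [build_image_feature_vector()], plus columns useful downstream:
#'   the densest-tile tumor count is `t01_tumor`.
#' @export
extract_slide_features <- function(scene, mask = NULL, tile_size = 1024, k = 10,
                                   til_ref_area = 304.7,
                                   width = NULL, height = NULL) {
  if (inherits(scene, "wsi_scene")) {
    cells <- scene$cells
    width <- scene$width
    height <- scene$height
  } else {
    cells <- scene
    if (is.null(width) || is.null(height)) {
      stop("`width` and `height` are required for a plain cells table", call. = FALSE)
    }
  }
  grid <- build_tile_grid(width, height, mask = mask, tile_size = tile_size)
  stats <- assign_cells_to_tiles(cells, grid)
  top <- select_top_tiles(stats, k = k)

  ts <- grid$tile_size
  cell_row <- floor(cells$y / ts)
  cell_col <- floor(cells$x / ts)
  in_top <- cells$cell_class == "tumor" &
    paste(cell_row, cell_col) %in% paste(top$row, top$col)
  tumor_areas <- cells$area[in_top]
  tumor_areas <- tumor_areas[!is.na(tumor_areas)]
  build_image_feature_vector(top, tumor_areas, til_ref_area = til_ref_area)
}

#' HER2 status to regression dummy
#'
#' @param status Character vector of `"Negative"` / `"Equivocal"` (case
#'   insensitive; `"Equivocal positive"` also accepted).
#' @return 0/1 numeric dummy, 1 for equivocal.
#' @export
her2_dummy <- function(status) {
  if (is.numeric(status)) {
    stopifnot(all(status %in% c(0, 1)))
    return(as.numeric(status))
  }
  s <- tolower(trimws(status))
  out <- dplyr::case_when(
    grepl("^equivocal", s) ~ 1,
    s %in% c("negative", "neg") ~ 0,
    TRUE ~ NA_real_
  )
  if (any(is.na(out))) {
    stop(
      "unrecognized HER2 status: ",
      paste(unique(status[is.na(out)]), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

# The eight regression variables, in canonical order: the five Magee
# equation-2 variables followed by the three image features.
model_variables <- function() {
  c(
    "nottingham", "er_h", "pr_h", "her2_equivocal", "tumor_size_cm",
    "densest_tile_tumor_count", "til_variance", "nuclear_grade"
  )
}

#' Assemble the eight-variable model feature table
#'
#' Selects, in canonical order, the five Magee-equation-2 variables
#' (Nottingham grade/score, ER and PR H-scores, HER2-equivocal dummy, tumor
#' size in cm) and the three image features (densest-tile tumor count, TIL
#' number variance, nuclear grade). A `her2` column holding status strings is
#' converted with [her2_dummy()] when `her2_equivocal` is absent.
#'
#' @param data A patient-level data frame.
#' @return A tibble with the eight model columns (plus `patient_id` and `rs`
#'   when present in `data`).
#' @export
assemble_model_features <- function(data) {
  if (!"her2_equivocal" %in% names(data) && "her2" %in% names(data)) {
    data$her2_equivocal <- her2_dummy(data$her2)
  }
  vars <- model_variables()
  missing <- setdiff(vars, names(data))
  if (length(missing) > 0) {
    stop(
      "missing model variable(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  keep <- c(intersect(c("patient_id"), names(data)), vars,
            intersect(c("rs"), names(data)))
  tibble::as_tibble(data[, keep])
}

#' Absolute Pearson correlation matrix between features
#'
#' @param data A patient-level data frame.
#' @param features Feature column names; all must be non-constant.
#' @return A symmetric matrix of |Pearson r| with unit diagonal.
#' @export
feature_correlation_matrix <- function(data, features = model_variables()) {
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    stop("unknown feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) < 3) stop("need at least 3 rows", call. = FALSE)
  X <- as.matrix(data[, features])
  storage.mode(X) <- "double"
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop(
      "constant feature(s): ", paste(features[sds == 0], collapse = ", "),
      call. = FALSE
    )
  }
  abs(stats::cor(X))
}
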