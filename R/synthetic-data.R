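#' Configure a synthetic cell scene
#'
#' Describes a synthetic whole-slide "scene" at the 40x pixel frame: spatially
#' clustered tumor cells with elliptical nucleus contours whose areas follow
#' the rule-based nuclear-grade bins, and tumor-infiltrating lymphocytes (TILs)
#' drawn from a background Poisson field with extra intensity in an annulus
#' just outside each tumor cluster (TILs concentrate near tumor fronts).
#'
#' @param canvas_width,canvas_height Canvas size in pixels; each must be at
#'   least one full 1,024-px tile.
#' @param n_tumor_clusters Number of tumor cell clusters.
#' @param tumor_cells_per_cluster_mean Mean cells per cluster (Poisson).
#' @param cluster_spread Isotropic standard deviation of cell positions around
#'   a cluster centre, in pixels.
#' @param til_density_background Background TIL intensity, cells per megapixel.
#' @param til_front_boost Multiplier on TIL intensity inside the tumor-front
#'   annulus (1 = no boost).
#' @param front_annulus_width Width in pixels of the boosted annulus outside a
#'   cluster's 2-SD radius.
#' @param grade_mix Probability triple over nuclear grades 1/2/3 for tumor
#'   cells; must sum to 1.
#' @param til_ref_area Reference TIL nucleus area in px^2 used to anchor the
#'   grade bins (default 304.7).
#' @param seed Integer seed; scenes are bitwise reproducible.
#' @return A `scene_config` list.
#' @seealso [gen_scene()]
#' @export
scene_config <- function(canvas_width = 2048,
                         canvas_height = 2048,
                         n_tumor_clusters = 3,
                         tumor_cells_per_cluster_mean = 150,
                         cluster_spread = 120,
                         til_density_background = 40,
                         til_front_boost = 4,
                         front_annulus_width = 100,
                         grade_mix = c(0.1, 0.6, 0.3),
                         til_ref_area = 304.7,
                         seed = 1L) {
  stopifnot(
    canvas_width >= 1024, canvas_height >= 1024,
    n_tumor_clusters >= 0, tumor_cells_per_cluster_mean >= 0,
    cluster_spread > 0, til_density_background >= 0,
    til_front_boost >= 0, front_annulus_width >= 0,
    length(grade_mix) == 3, all(grade_mix >= 0), til_ref_area > 0
  )
  if (abs(sum(grade_mix) - 1) > 1e-9) {
    stop("`grade_mix` must sum to 1", call. = FALSE)
  }
  structure(
    list(
      canvas_width = canvas_width, canvas_height = canvas_height,
      n_tumor_clusters = n_tumor_clusters,
      tumor_cells_per_cluster_mean = tumor_cells_per_cluster_mean,
      cluster_spread = cluster_spread,
      til_density_background = til_density_background,
      til_front_boost = til_front_boost,
      front_annulus_width = front_annulus_width,
      grade_mix = grade_mix, til_ref_area = til_ref_area,
      seed = as.integer(seed)
    ),
    class = "scene_config"
  )
}

# Nuclear-grade area-ratio bins: grade 1 below 2.5, grade 2 in [2.5, 3.5],
# grade 3 above 3.5. Sampling stays strictly inside each bin so that
# re-grading a generated area always returns the sampled grade.
sample_grade_ratio <- function(grade) {
  lo <- c(1.0, 2.5, 3.55)[grade]
  hi <- c(2.45, 3.5, 6.0)[grade]
  stats::runif(length(grade), lo, hi)
}

#' Generate a synthetic cell scene
#'
#' Draws tumor cell centres from a Gaussian cluster mixture, assigns each
#' tumor cell a nuclear grade and an elliptical contour whose area sits in the
#' grade's area-ratio bin relative to `til_ref_area`, and scatters TILs from a
#' background Poisson field plus a boosted annulus around each cluster.
#'
#' @param config A [scene_config()].
#' @return A `wsi_scene` object: a list with `cells` (a tibble with columns
#'   `cell_class`, `x`, `y`, `grade`, `area` and a `contour` list-column),
#'   `width`, `height` and `magnification` (always `"40x"`).
#' @examples
#' sc <- gen_scene(scene_config(seed = 7))
#' dplyr::count(sc$cells, cell_class)
#' @export
gen_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    w <- config$canvas_width
    h <- config$canvas_height
    margin <- min(2 * config$cluster_spread, w / 4, h / 4)

    centers <- if (config$n_tumor_clusters > 0) {
      cbind(
        stats::runif(config$n_tumor_clusters, margin, w - margin),
        stats::runif(config$n_tumor_clusters, margin, h - margin)
      )
    } else {
      matrix(numeric(0), ncol = 2)
    }

    tumor <- gen_tumor_cells(config, centers, w, h)
    til <- gen_til_cells(config, centers, w, h)

    cells <- dplyr::bind_rows(tumor, til)
    if (nrow(cells) == 0) {
      cells <- tibble::tibble(
        cell_class = character(), x = numeric(), y = numeric(),
        grade = integer(), area = numeric(), contour = list()
      )
    }
    structure(
      list(
        cells = set_magnification(cells, "40x"),
        width = w, height = h,
        magnification = "40x",
        config = config
      ),
      class = "wsi_scene"
    )
  })
}

gen_tumor_cells <- function(config, centers, w, h) {
  k <- nrow(centers)
  if (k == 0) return(NULL)
  n_per <- stats::rpois(k, config$tumor_cells_per_cluster_mean)
  n <- sum(n_per)
  if (n == 0) return(NULL)
  idx <- rep(seq_len(k), n_per)
  x <- pmin(pmax(stats::rnorm(n, centers[idx, 1], config$cluster_spread), 0), w - 1e-6)
  y <- pmin(pmax(stats::rnorm(n, centers[idx, 2], config$cluster_spread), 0), h - 1e-6)
  grade <- sample.int(3, n, replace = TRUE, prob = config$grade_mix)
  area <- sample_grade_ratio(grade) * config$til_ref_area
  axis_ratio <- stats::runif(n, 0.7, 1.0)
  angle <- stats::runif(n, 0, pi)
  contour <- purrr::pmap(
    list(area, axis_ratio, angle, x, y),
    function(a, r, th, cx, cy) ellipse_polygon(a, r, th, cx, cy)
  )
  tibble::tibble(
    cell_class = "tumor", x = x, y = y,
    grade = grade, area = area, contour = contour
  )
}

gen_til_cells <- function(config, centers, w, h) {
  mpx <- w * h / 1e6
  n_bg <- stats::rpois(1, config$til_density_background * mpx)
  x <- stats::runif(n_bg, 0, w)
  y <- stats::runif(n_bg, 0, h)

  # Tumor-front boost: extra Poisson intensity in the annulus between each
  # cluster's 2-SD radius and that radius + front_annulus_width.
  if (nrow(centers) > 0 && config$til_front_boost > 1 &&
      config$front_annulus_width > 0 && config$til_density_background > 0) {
    r1 <- 2 * config$cluster_spread
    r2 <- r1 + config$front_annulus_width
    ann_area <- pi * (r2^2 - r1^2)
    extra_rate <- (config$til_front_boost - 1) * config$til_density_background * ann_area / 1e6
    for (i in seq_len(nrow(centers))) {
      n_extra <- stats::rpois(1, extra_rate)
      if (n_extra > 0) {
        rr <- sqrt(stats::runif(n_extra, r1^2, r2^2))
        th <- stats::runif(n_extra, 0, 2 * pi)
        x <- c(x, centers[i, 1] + rr * cos(th))
        y <- c(y, centers[i, 2] + rr * sin(th))
      }
    }
  }
  keep <- x >= 0 & x < w & y >= 0 & y < h
  x <- x[keep]
  y <- y[keep]
  if (length(x) == 0) return(NULL)
  tibble::tibble(
    cell_class = "til", x = x, y = y,
    grade = NA_integer_, area = NA_real_,
    contour = vector("list", length(x))
  )
}

#' @export
print.wsi_scene <- function(x, ...) {
  cat(sprintf(
    "<wsi_scene> %d x %d px (%s), %d tumor cells, %d TILs\n",
    x$width, x$height, x$magnification,
    sum(x$cells$cell_class == "tumor"), sum(x$cells$cell_class == "til")
  ))
  invisible(x)
}

#' Perturb ground-truth detections
#'
#' Simulates an imperfect detector on a known scene: each ground-truth cell is
#' dropped independently with probability `fn_rate`, surviving centres are
#' jittered by an isotropic Gaussian, and spurious uniform detections are added
#' with expected count `fp_rate * n`. Class labels are preserved for survivors;
#' spurious cells draw their class from the ground-truth class mix.
#'
#' @param scene A `wsi_scene` from [gen_scene()], or a cells data frame (then
#'   `width`/`height` must be given).
#' @param fn_rate,fp_rate False-negative and false-positive rates in \[0, 1\].
#' @param jitter_sd Isotropic Gaussian jitter SD in pixels.
#' @param seed Integer seed.
#' @param width,height Canvas dimensions, taken from `scene` when it is a
#'   `wsi_scene`.
#' @return A tibble of detected cells (`cell_class`, `x`, `y`, `source` one of
#'   `"survivor"`/`"spurious"`, `gt_idx` index into the input for survivors).
#' @export
perturb_detections <- function(scene, fn_rate = 0, fp_rate = 0, jitter_sd = 0,
                               seed = 1L, width = NULL, height = NULL) {
  if (inherits(scene, "wsi_scene")) {
    cells <- scene$cells
    width <- scene$width
    height <- scene$height
  } else {
    cells <- scene
    if (is.null(width) || is.null(height)) {
      stop("`width` and `height` are required when `scene` is a plain cells table", call. = FALSE)
    }
  }
  stopifnot(
    fn_rate >= 0, fn_rate <= 1, fp_rate >= 0, fp_rate <= 1, jitter_sd >= 0
  )
  n <- nrow(cells)
  with_seed(seed, {
    keep <- if (n > 0) stats::runif(n) >= fn_rate else logical(0)
    surv <- cells[keep, c("cell_class", "x", "y")]
    n_surv <- nrow(surv)
    if (n_surv > 0 && jitter_sd > 0) {
      surv$x <- surv$x + stats::rnorm(n_surv, 0, jitter_sd)
      surv$y <- surv$y + stats::rnorm(n_surv, 0, jitter_sd)
    }
    surv$source <- rep("survivor", n_surv)
    surv$gt_idx <- which(keep)

    n_fp <- if (n > 0 && fp_rate > 0) stats::rpois(1, fp_rate * n) else 0L
    fp <- tibble::tibble(
      cell_class = if (n_fp > 0) {
        sample(cells$cell_class, n_fp, replace = TRUE)
      } else {
        character(0)
      },
      x = stats::runif(n_fp, 0, width),
      y = stats::runif(n_fp, 0, height),
      source = rep("spurious", n_fp),
      gt_idx = rep(NA_integer_, n_fp)
    )
    out <- dplyr::bind_rows(tibble::as_tibble(surv), fp)
    set_magnification(out, magnification(cells) %||% "40x")
  })
}

# Default marginal specs for the cohort generator: observed range and mean of
# each regression variable in an ER+/HER2- RS cohort. Continuous features are
# drawn from a Beta on [min, max] with matched mean (concentration 4);
# categorical features carry outcome probabilities.
default_feature_marginals <- function() {
  list(
    nottingham = list(type = "categorical", levels = 1:3, prob = c(33, 75, 17) / 125),
    er_h = list(type = "range", min = 80, max = 300, mean = 277.14),
    pr_h = list(type = "range", min = 0, max = 300, mean = 188.07),
    her2_equivocal = list(type = "categorical", levels = c(0, 1), prob = c(123, 2) / 125),
    tumor_size_cm = list(type = "range", min = 0.4, max = 7.8, mean = 2.19),
    densest_tile_tumor_count = list(
      type = "range", min = 140, max = 612, mean = 346.13, integer = TRUE
    ),
    til_variance = list(type = "range", min = 2.49, max = 8227.6, mean = 714.95),
    nuclear_grade = list(type = "categorical", levels = 1:3, prob = c(1, 81, 43) / 125)
  )
}

default_cohort_coefficients <- function() {
  c(
    intercept = 10, nottingham = 2.5, er_h = -0.025, pr_h = -0.02,
    her2_equivocal = 4, tumor_size_cm = 1.2,
    densest_tile_tumor_count = 0.01, til_variance = 5e-4, nuclear_grade = 2
  )
}

#' Configure a synthetic patient cohort
#'
#' @param n_patients Cohort size; must exceed the number of non-intercept
#'   coefficients by at least 2.
#' @param coefficients Named vector of true linear coefficients over
#'   `intercept` and the eight model variables.
#' @param noise_sd Gaussian noise SD on the recurrence score, in RS units.
#' @param feature_marginals Per-feature sampling specs; see
#'   `default_feature_marginals` in the package source for the shape.
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 125,
                          coefficients = default_cohort_coefficients(),
                          noise_sd = 5,
                          feature_marginals = default_feature_marginals(),
                          seed = 1L) {
  stopifnot(noise_sd >= 0, "intercept" %in% names(coefficients))
  p <- length(coefficients) - 1L
  if (n_patients < p + 2) {
    stop(sprintf("`n_patients` must be at least %d (p + 2)", p + 2), call. = FALSE)
  }
  missing_marg <- setdiff(setdiff(names(coefficients), "intercept"), names(feature_marginals))
  if (length(missing_marg) > 0) {
    stop("no marginal spec for feature(s): ", paste(missing_marg, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      n_patients = as.integer(n_patients), coefficients = coefficients,
      noise_sd = noise_sd, feature_marginals = feature_marginals,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

sample_marginal <- function(spec, n) {
  if (spec$type == "categorical") {
    sample(spec$levels, n, replace = TRUE, prob = spec$prob)
  } else {
    m <- (spec$mean - spec$min) / (spec$max - spec$min)
    conc <- 4
    x <- spec$min + (spec$max - spec$min) * stats::rbeta(n, conc * m, conc * (1 - m))
    if (isTRUE(spec$integer)) round(x) else x
  }
}

#' Generate a synthetic patient cohort
#'
#' Samples the eight regression variables from their marginal specs and builds
#' a recurrence score as a noisy linear function of them. The raw (real) RS is
#' kept alongside the reported integer RS (rounded half-up, clipped to
#' \[0, 100\]). The true coefficients are attached as the
#' `true_coefficients` attribute for recovery tests.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per patient: `patient_id`, the eight model
#'   variables, `rs_raw`, `rs`, `age`, `chemo_received`.
#' @examples
#' co <- gen_cohort(cohort_config(n_patients = 50, seed = 3))
#' range(co$rs)
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    feats <- names(config$coefficients)
    feats <- feats[feats != "intercept"]
    X <- purrr::map(feats, function(f) sample_marginal(config$feature_marginals[[f]], n))
    names(X) <- feats
    X <- tibble::as_tibble(X)

    constant <- vapply(X, function(v) length(unique(v)) == 1, logical(1))
    bad <- constant & config$coefficients[names(X)] != 0
    if (any(bad)) {
      stop(
        "singular design: constant feature(s) with non-zero coefficient: ",
        paste(names(X)[bad], collapse = ", "),
        call. = FALSE
      )
    }

    beta <- config$coefficients[feats]
    rs_raw <- config$coefficients[["intercept"]] +
      as.numeric(as.matrix(X) %*% beta) +
      stats::rnorm(n, 0, config$noise_sd)
    rs <- pmin(pmax(floor(rs_raw + 0.5), 0), 100)

    age <- sample(30:80, n, replace = TRUE)
    rec <- chemo_recommendation(rs, age)
    chemo_received <- stats::runif(n) < ifelse(rec == "yes", 0.7, 0.1)

    out <- dplyr::bind_cols(
      tibble::tibble(patient_id = sprintf("P%04d", seq_len(n))),
      X,
      tibble::tibble(
        rs_raw = rs_raw, rs = as.integer(rs),
        age = age, chemo_received = chemo_received
      )
    )
    attr(out, "true_coefficients") <- config$coefficients
    attr(out, "noise_sd") <- config$noise_sd
    out
  })
}
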