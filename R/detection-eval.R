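as_points <- function(x) {
  if (is.data.frame(x)) x <- cbind(x$x, x$y)
  x <- as.matrix(x)
  if (length(x) == 0) return(matrix(numeric(0), ncol = 2))
  stopifnot(ncol(x) == 2)
  storage.mode(x) <- "double"
  unname(x)
}

#' Greedy point matching of detections against ground truth
#'
#' Candidate ground-truth/prediction pairs within `radius` pixels are sorted
#' by ascending distance (ties by ground-truth then prediction index) and
#' accepted greedily when both endpoints are still unused. Remaining ground
#' truths are false negatives; remaining predictions are false positives.
#'
#' @param gt,pred Point sets: data frames with `x`,`y` or 2-column matrices.
#' @param radius Maximum match distance in pixels (default 12, about half a
#'   grade-1 nucleus equivalent diameter).
#' @return A `point_match` object: `tp`, `fp`, `fn` counts, a `pairs` tibble
#'   (`gt_idx`, `pred_idx`, `distance`), and unmatched index vectors.
#' @export
match_points <- function(gt, pred, radius = 12) {
  stopifnot(radius > 0)
  gt <- as_points(gt)
  pred <- as_points(pred)
  n_gt <- nrow(gt)
  n_pred <- nrow(pred)

  pairs <- tibble::tibble(
    gt_idx = integer(), pred_idx = integer(), distance = numeric()
  )
  if (n_gt > 0 && n_pred > 0) {
    d <- sqrt(
      outer(gt[, 1], pred[, 1], "-")^2 + outer(gt[, 2], pred[, 2], "-")^2
    )
    cand <- which(d <= radius, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(d[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      gt_used <- logical(n_gt)
      pred_used <- logical(n_pred)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        g <- cand[i, 1]
        p <- cand[i, 2]
        if (!gt_used[g] && !pred_used[p]) {
          gt_used[g] <- TRUE
          pred_used[p] <- TRUE
          keep[i] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      pairs <- tibble::tibble(
        gt_idx = as.integer(cand[, 1]),
        pred_idx = as.integer(cand[, 2]),
        distance = d[cand]
      )
    }
  }
  structure(
    list(
      tp = nrow(pairs),
      fp = n_pred - nrow(pairs),
      fn = n_gt - nrow(pairs),
      pairs = pairs,
      unmatched_gt = setdiff(seq_len(n_gt), pairs$gt_idx),
      unmatched_pred = setdiff(seq_len(n_pred), pairs$pred_idx),
      radius = radius
    ),
    class = "point_match"
  )
}

#' @export
print.point_match <- function(x, ...) {
  cat(sprintf(
    "<point_match> TP = %d, FP = %d, FN = %d (radius %g px)\n",
    x$tp, x$fp, x$fn, x$radius
  ))
  invisible(x)
}

#' Precision, recall and F1 from match counts
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2PR/(P+R) (0 when P + R = 0).
#'
#' @param tp,fp,fn True positive, false positive and false negative counts,
#'   or a `point_match` object as `tp`.
#' @return A one-row tibble: `precision`, `recall`, `f1`.
#' @examples
#' detection_scores(6101, 2003, 1508)
#' @export
detection_scores <- function(tp, fp = NULL, fn = NULL) {
  if (inherits(tp, "point_match")) {
    fp <- tp$fp
    fn <- tp$fn
    tp <- tp$tp
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp == 0) stop("precision undefined: TP + FP = 0", call. = FALSE)
  if (tp + fn == 0) stop("recall undefined: TP + FN = 0", call. = FALSE)
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(precision = precision, recall = recall, f1 = f1)
}

ring_to_polyclip <- function(poly) {
  p <- as_ring(poly)
  list(x = p[, 1], y = p[, 2])
}

clip_area <- function(paths) {
  if (length(paths) == 0) return(0)
  sum(vapply(paths, function(p) polygon_area(cbind(p$x, p$y)), numeric(1)))
}

#' Intersection over union of two polygons
#'
#' Exact polygon clipping (Vatti algorithm via polyclip) gives the
#' intersection and union areas of two simple polygons.
#'
#' @param a,b Simple polygons (2-column vertex matrices, data frames, or
#'   `list(x=, y=)`).
#' @return IOU in \[0, 1\].
#' @export
polygon_iou <- function(a, b) {
  pa <- ring_to_polyclip(a)
  pb <- ring_to_polyclip(b)
  if (polygon_area(cbind(pa$x, pa$y)) == 0 || polygon_area(cbind(pb$x, pb$y)) == 0) {
    stop("degenerate (zero-area) polygon", call. = FALSE)
  }
  inter <- clip_area(polyclip::polyclip(pa, pb, op = "intersection"))
  uni <- clip_area(polyclip::polyclip(pa, pb, op = "union"))
  if (uni == 0) return(0)
  inter / uni
}

iou_matrix <- function(gt, pred) {
  m <- matrix(0, length(gt), length(pred))
  for (i in seq_along(gt)) {
    for (j in seq_along(pred)) {
      m[i, j] <- polygon_iou(gt[[i]], pred[[j]])
    }
  }
  m
}

#' Match contours by IOU cutoff
#'
#' Ground truths are scanned in index order; each takes, among the not yet
#' assigned predictions with IOU at or above `K`, the one with the largest
#' IOU (ties to the lower prediction index). A prediction already assigned to
#' an earlier ground truth stays with it, so later ground truths fall through
#' to their next-best candidate or go unmatched.
#'
#' @param gt,pred Lists of simple polygons.
#' @param K IOU cutoff in \[0, 1\].
#' @param iou Optional precomputed IOU matrix (`length(gt)` x
#'   `length(pred)`), to avoid re-clipping when matching at several cutoffs.
#' @return A `contour_match` object: a `pairs` tibble (`gt_idx`, `pred_idx`,
#'   `iou`), `unmatched_gt`, `unmatched_pred`, and `K`.
#' @export
match_contours <- function(gt, pred, K, iou = NULL) {
  stopifnot(K >= 0, K <= 1)
  if (is.null(iou)) iou <- iou_matrix(gt, pred)
  stopifnot(nrow(iou) == length(gt), ncol(iou) == length(pred))
  assigned <- logical(length(pred))
  pairs <- vector("list", length(gt))
  for (i in seq_along(gt)) {
    if (length(pred) == 0) break
    ok <- which(!assigned & iou[i, ] >= K)
    if (length(ok) == 0) next
    best <- ok[order(-iou[i, ok], ok)][1]
    assigned[best] <- TRUE
    pairs[[i]] <- tibble::tibble(
      gt_idx = i, pred_idx = as.integer(best), iou = iou[i, best]
    )
  }
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0) {
    pairs <- tibble::tibble(gt_idx = integer(), pred_idx = integer(), iou = numeric())
  }
  structure(
    list(
      pairs = pairs,
      unmatched_gt = setdiff(seq_along(gt), pairs$gt_idx),
      unmatched_pred = setdiff(seq_along(pred), pairs$pred_idx),
      K = K
    ),
    class = "contour_match"
  )
}

#' @export
print.contour_match <- function(x, ...) {
  cat(sprintf(
    "<contour_match> K = %g: %d pair(s), %d unmatched GT, %d unmatched pred\n",
    x$K, nrow(x$pairs), length(x$unmatched_gt), length(x$unmatched_pred)
  ))
  invisible(x)
}

# Insert vertices along each edge so no segment exceeds `max_len` pixels.
densify_ring <- function(poly, max_len = 1) {
  p <- as_ring(poly)
  n <- nrow(p)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- p[i, ]
    b <- p[if (i == n) 1 else i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1, ceiling(len / max_len))
    t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

directed_max_min <- function(A, B) {
  # max over rows of A of the min distance to rows of B, chunked to keep the
  # distance matrix small
  worst <- 0
  step <- 512
  for (s in seq(1, nrow(A), by = step)) {
    idx <- s:min(s + step - 1, nrow(A))
    d2 <- outer(A[idx, 1], B[, 1], "-")^2 + outer(A[idx, 2], B[, 2], "-")^2
    worst <- max(worst, sqrt(max(apply(d2, 1, min))))
  }
  worst
}

#' Hausdorff distance between two contours
#'
#' Symmetric Hausdorff distance over the polygon boundaries, densified so no
#' boundary segment exceeds 1 px: max over each boundary of the distance to
#' the nearest point of the other.
#'
#' @param a,b Polygons (or, degenerately, point sets as 2-column matrices
#'   with fewer than 3 rows).
#' @param max_segment Densification limit in pixels.
#' @return Distance in pixels.
#' @export
hausdorff_distance <- function(a, b, max_segment = 1) {
  to_boundary <- function(x) {
    m <- if (is.list(x) && !is.data.frame(x) && all(c("x", "y") %in% names(x))) {
      cbind(x$x, x$y)
    } else {
      as.matrix(x)
    }
    storage.mode(m) <- "double"
    if (nrow(m) >= 3) densify_ring(m, max_segment) else m
  }
  A <- to_boundary(a)
  B <- to_boundary(b)
  if (nrow(A) == 0 || nrow(B) == 0) stop("degenerate empty contour", call. = FALSE)
  max(directed_max_min(A, B), directed_max_min(B, A))
}

#' Equivalent diameter of a nucleus
#'
#' Diameter of the circle with the same area: `sqrt(4 * area / pi)`.
#'
#' @param area Nucleus area(s) in px^2, positive.
#' @return Diameter(s) in pixels. Vectorized.
#' @export
equivalent_diameter <- function(area) {
  if (any(area <= 0, na.rm = TRUE)) stop("`area` must be positive", call. = FALSE)
  sqrt(4 * area / pi)
}

#' Grade-stratified segmentation evaluation summary
#'
#' For each IOU cutoff K and each nuclear grade: the mean Hausdorff distance
#' over matched ground-truth/prediction pairs whose ground truth has that
#' grade, the mean equivalent diameter over all ground truths of the grade,
#' and their ratio in percent.
#'
#' @param gt,pred Lists of simple polygons.
#' @param gt_grades Nuclear grade (1-3) per ground-truth polygon.
#' @param gt_areas Optional ground-truth areas in px^2 (defaults to the
#'   polygon areas).
#' @param cutoffs IOU cutoffs (default 0.1-0.9 by 0.1).
#' @return A tibble with `cutoff`, `grade`, `n_matched`, `mean_hd`,
#'   `mean_equiv_diameter`, `ratio_pct` (`NA` mean HD, with a warning, for
#'   strata with no matches).
#' @export
seg_summary <- function(gt, pred, gt_grades, gt_areas = NULL,
                        cutoffs = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(length(gt_grades) == length(gt), all(gt_grades %in% 1:3))
  if (is.null(gt_areas)) {
    gt_areas <- vapply(gt, function(p) polygon_area(as_ring(p)), numeric(1))
  }
  iou <- iou_matrix(gt, pred)
  hd_cache <- new.env(parent = emptyenv())
  pair_hd <- function(i, j) {
    key <- paste(i, j)
    if (is.null(hd_cache[[key]])) {
      hd_cache[[key]] <- hausdorff_distance(gt[[i]], pred[[j]])
    }
    hd_cache[[key]]
  }
  grades_present <- sort(unique(gt_grades))
  mean_ed <- vapply(
    grades_present,
    function(g) mean(equivalent_diameter(gt_areas[gt_grades == g])),
    numeric(1)
  )
  names(mean_ed) <- grades_present

  out <- purrr::map_dfr(cutoffs, function(K) {
    mt <- match_contours(gt, pred, K, iou = iou)
    purrr::map_dfr(grades_present, function(g) {
      rows <- mt$pairs[gt_grades[mt$pairs$gt_idx] == g, ]
      if (nrow(rows) == 0) {
        warning(sprintf("no matches for grade %d at K = %g", g, K), call. = FALSE)
        mean_hd <- NA_real_
      } else {
        mean_hd <- mean(purrr::map2_dbl(rows$gt_idx, rows$pred_idx, pair_hd))
      }
      ed <- mean_ed[[as.character(g)]]
      tibble::tibble(
        cutoff = K, grade = as.integer(g), n_matched = nrow(rows),
        mean_hd = mean_hd, mean_equiv_diameter = ed,
        ratio_pct = mean_hd / ed * 100
      )
    })
  })
  out
}
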