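test_that("point matching satisfies its count identities", {
  set.seed(1)
  gt <- separated_points(9)
  pm <- match_points(gt, gt, radius = 1)
  expect_identical(pm$tp, 9L)
  expect_identical(pm$fp, 0L)
  expect_identical(pm$fn, 0L)

  pm2 <- match_points(cbind(0, 0), cbind(100, 100), radius = 12)
  expect_identical(c(pm2$tp, pm2$fp, pm2$fn), c(0L, 1L, 1L))

  for (i in 1:10) {
    gt <- matrix(runif(20, 0, 200), ncol = 2)
    pred <- matrix(runif(24, 0, 200), ncol = 2)
    pm <- match_points(gt, pred, radius = 25)
    expect_identical(pm$tp + pm$fn, nrow(gt))
    expect_identical(pm$tp + pm$fp, nrow(pred))
    expect_true(all(pm$pairs$distance <= 25))
    expect_false(any(duplicated(pm$pairs$gt_idx)))
    expect_false(any(duplicated(pm$pairs$pred_idx)))
  }
})

test_that("greedy matching equals the exhaustive assignment oracle", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(3:6, 1)
    gt <- separated_points(n)
    pred <- gt + matrix(rnorm(2 * n, sd = 2), ncol = 2)
    # occasionally drop one and add a far spurious point
    if (seed %% 3 == 0) pred <- rbind(pred[-1, , drop = FALSE], c(500, 500))
    pm <- match_points(gt, pred, radius = 12)
    o <- oracle_match_points(gt, pred, radius = 12)
    expect_identical(pm$tp, o$tp)
    expect_identical(pm$fp, o$fp)
    expect_identical(pm$fn, o$fn)
  }
})

test_that("detection scores follow their definitions and bounds", {
  s <- detection_scores(6101, fp = 2003, fn = 1508)
  expect_equal(s$recall, 6101 / 7609)
  expect_equal(round(s$recall, 4), 0.8018)

  s2 <- detection_scores(3304, fp = 100, fn = 696)
  expect_equal(round(s2$recall, 3), 0.826)

  eq <- detection_scores(10, fp = 10, fn = 10)
  expect_equal(eq$f1, eq$precision) # harmonic mean of equals

  expect_error(detection_scores(0, fp = 0, fn = 3), "precision")
  expect_error(detection_scores(0, fp = 3, fn = 0), "recall")

  set.seed(2)
  for (i in 1:15) {
    s <- detection_scores(sample(0:50, 1) + 1, fp = sample(0:50, 1), fn = sample(0:50, 1))
    expect_gte(s$f1, min(s$precision, s$recall) - 1e-12)
    expect_lte(s$f1, max(s$precision, s$recall) + 1e-12)
  }
})

test_that("polygon IOU matches closed forms and a point-grid oracle", {
  expect_equal(polygon_iou(square(), square()), 1)
  expect_equal(polygon_iou(square(), square(5)), 0)
  expect_equal(polygon_iou(square(), square(0.5)), 1 / 3) # overlap 1/2, union 3/2
  expect_error(polygon_iou(square(), cbind(c(0, 1, 2), c(0, 0, 0))), "degenerate")

  # symmetry + bounds + grid oracle on random simple polygons
  skip_if_not_installed("mgcv")
  set.seed(8)
  for (i in 1:5) {
    a <- random_polygon(0, 0, 10)
    b <- random_polygon(3, 2, 9)
    v <- polygon_iou(a, b)
    expect_equal(v, polygon_iou(b, a))
    expect_true(v >= 0 && v <= 1)
    gx <- seq(-16, 20, by = 0.25)
    pts <- as.matrix(expand.grid(gx, gx))
    ina <- mgcv::in.out(rbind(a, a[1, ]), pts)
    inb <- mgcv::in.out(rbind(b, b[1, ]), pts)
    approx <- sum(ina & inb) / sum(ina | inb)
    expect_equal(v, approx, tolerance = 0.03)
  }
})

test_that("contour matching follows the sequential largest-IOU rule", {
  gt <- list(square(0, 0, 10))
  pred <- list(square(3, 0, 10), square(5, 0, 10)) # IOUs ~0.54 and ~0.33
  mt <- match_contours(gt, pred, K = 0.3)
  expect_identical(mt$pairs$pred_idx, 1L)

  # two ground truths fighting over the same best prediction: the first wins
  gt2 <- list(square(0, 0, 10), square(1, 0, 10))
  pred2 <- list(square(0.5, 0, 10))
  mt2 <- match_contours(gt2, pred2, K = 0.5)
  expect_identical(mt2$pairs$gt_idx, 1L)
  expect_identical(mt2$unmatched_gt, 2L)

  mt3 <- match_contours(gt2, pred2, K = 0.99)
  expect_identical(nrow(mt3$pairs), 0L)
  expect_identical(mt3$unmatched_pred, 1L)
})

test_that("contour matching equals the rule-simulation oracle on random sets", {
  for (seed in 1:60) {
    set.seed(seed)
    n_gt <- sample(1:4, 1)
    n_pred <- sample(1:4, 1)
    gt <- lapply(seq_len(n_gt), function(i) random_polygon(runif(1, 0, 30), runif(1, 0, 30), 8))
    pred <- lapply(seq_len(n_pred), function(i) random_polygon(runif(1, 0, 30), runif(1, 0, 30), 8))
    K <- sample(c(0.1, 0.3, 0.5), 1)
    mt <- match_contours(gt, pred, K)
    o <- oracle_match_contours(gt, pred, K)
    got <- as.matrix(mt$pairs[, c("gt_idx", "pred_idx")])
    dimnames(got) <- NULL
    if (is.null(o)) {
      expect_identical(nrow(mt$pairs), 0L)
    } else {
      expect_identical(got, o)
    }
    expect_true(all(mt$pairs$iou >= K))
  }
})

test_that("matches at a stricter cutoff are a subset of looser ones", {
  set.seed(3)
  gt <- lapply(1:4, function(i) random_polygon(i * 12, 10, 7))
  pred <- lapply(1:4, function(i) random_polygon(i * 12 + 2, 11, 7))
  loose <- match_contours(gt, pred, 0.2)
  strict <- match_contours(gt, pred, 0.6)
  expect_true(all(strict$pairs$iou >= 0.6))
  # every strictly-matched candidate pair is admissible at the looser cutoff
  expect_true(all(strict$pairs$iou >= 0.2))
  expect_lte(nrow(strict$pairs), nrow(loose$pairs))
})

test_that("Hausdorff distance matches closed forms and is metric-like", {
  sq <- square(0, 0, 10)
  expect_equal(hausdorff_distance(sq, sq), 0)
  expect_equal(hausdorff_distance(cbind(0, 0), cbind(3, 4)), 5)
  expect_equal(hausdorff_distance(sq, square(3, 0, 10)), 3, tolerance = 1e-9)

  skip_if_not_installed("pracma")
  set.seed(4)
  for (i in 1:4) {
    a <- random_polygon(0, 0, 8)
    b <- random_polygon(2, 1, 7)
    da <- wsirs:::densify_ring(a)
    db <- wsirs:::densify_ring(b)
    expect_equal(
      hausdorff_distance(a, b),
      pracma::hausdorff_dist(da, db),
      tolerance = 1e-9
    )
    expect_equal(hausdorff_distance(a, b), hausdorff_distance(b, a))
  }

  # triangle inequality within densification slack
  a <- random_polygon(0, 0, 8)
  b <- random_polygon(5, 0, 8)
  c <- random_polygon(2, 4, 8)
  expect_lte(
    hausdorff_distance(a, c),
    hausdorff_distance(a, b) + hausdorff_distance(b, c) + 2
  )
})

test_that("equivalent diameter inverts the circle area formula", {
  expect_equal(equivalent_diameter(pi), 2)
  expect_equal(equivalent_diameter(100), sqrt(400 / pi))
  expect_equal(round(equivalent_diameter(100), 4), 11.2838)
  expect_equal(equivalent_diameter(200) / equivalent_diameter(100), sqrt(2))
  expect_error(equivalent_diameter(-1), "positive")
})

test_that("segmentation summaries stratify by grade and cutoff", {
  set.seed(10)
  gt <- lapply(1:6, function(i) {
    wsirs:::ellipse_polygon(
      c(500, 1000, 1400)[(i - 1) %% 3 + 1],
      cx = i * 60, cy = 50
    )
  })
  grades <- c(1L, 2L, 3L, 1L, 2L, 3L)
  # perfect predictions: zero Hausdorff distance everywhere
  sm <- seg_summary(gt, gt, grades, cutoffs = c(0.3, 0.6))
  expect_identical(nrow(sm), 2L * 3L)
  expect_true(all(sm$mean_hd == 0))
  expect_true(all(sm$ratio_pct == 0))

  # jittered predictions: mean HD non-increasing as the cutoff rises is NOT
  # guaranteed, but the matched-pair count is non-increasing in K
  pred <- lapply(gt, function(p) p + 3)
  sm2 <- suppressWarnings(
    seg_summary(gt, pred, grades, cutoffs = seq(0.1, 0.9, 0.2))
  )
  counts <- tapply(sm2$n_matched, sm2$cutoff, sum)
  expect_true(all(diff(counts) <= 0))
  # single matched pair: summary equals that pair's HD
  one <- seg_summary(gt[1], list(gt[[1]] + 2), 1L, cutoffs = 0.5)
  expect_equal(one$mean_hd, hausdorff_distance(gt[[1]], gt[[1]] + 2))
})

test_that("perturbed scenes recover known precision and recall", {
  s <- gen_scene(scene_config(
    canvas_width = 2048, canvas_height = 2048,
    n_tumor_clusters = 4, tumor_cells_per_cluster_mean = 180,
    cluster_spread = 200, til_density_background = 60, seed = 50
  ))
  n <- nrow(s$cells)
  det <- perturb_detections(s, fn_rate = 0.2, fp_rate = 0.25, jitter_sd = 0.5, seed = 51)
  pm <- match_points(s$cells[, c("x", "y")], det[, c("x", "y")], radius = 3)
  sc <- detection_scores(pm)
  sd_rec <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(sc$recall - 0.8), 3 * sd_rec + 0.01)
  expected_prec <- 0.8 / (0.8 + 0.25)
  expect_lt(abs(sc$precision - expected_prec), 0.04)
})
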