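# Printed-table fixtures and independent oracles used across test files.

# 3x3 risk confusion matrices (rows: ground truth; order high/intermediate/low)
# for the two validation cohorts, as published.
table4_set1 <- matrix(
  c(
    11, 12, 4,
    0, 8, 7,
    0, 13, 27
  ),
  nrow = 3, byrow = TRUE,
  dimnames = list(gt = c("high", "intermediate", "low"),
                  pred = c("high", "intermediate", "low"))
)

table4_set2 <- matrix(
  c(
    7, 25, 5,
    1, 43, 26,
    0, 32, 36
  ),
  nrow = 3, byrow = TRUE,
  dimnames = list(gt = c("high", "intermediate", "low"),
                  pred = c("high", "intermediate", "low"))
)

# 2x2 chemotherapy recommendation matrix (rows: RS no/yes; cols predicted)
table6_matrix <- matrix(
  c(
    166, 14,
    40, 37
  ),
  nrow = 2, byrow = TRUE,
  dimnames = list(rs = c("no", "yes"), predicted = c("no", "yes"))
)

# axis-aligned unit square translated by (dx, dy), scaled by s
square <- function(dx = 0, dy = 0, s = 1) {
  cbind(c(0, 1, 1, 0) * s + dx, c(0, 0, 1, 1) * s + dy)
}

# star-shaped simple polygon around a centre (angularly monotone vertices)
random_polygon <- function(cx, cy, r0, n = 8) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, 0.5 * r0, 1.5 * r0)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Exhaustive point-matching oracle: over all injective partial assignments of
# ground truths to predictions within `radius`, maximize cardinality, then
# minimize total distance. Recursive enumeration, feasible for <= 6 points.
oracle_match_points <- function(gt, pred, radius) {
  gt <- as.matrix(gt)
  pred <- as.matrix(pred)
  n_gt <- nrow(gt)
  n_pred <- nrow(pred)
  d <- sqrt(outer(gt[, 1], pred[, 1], "-")^2 + outer(gt[, 2], pred[, 2], "-")^2)
  best <- list(card = -1L, dist = Inf)
  rec <- function(i, used, card, total) {
    if (i > n_gt) {
      if (card > best$card || (card == best$card && total < best$dist)) {
        best <<- list(card = card, dist = total)
      }
      return(invisible())
    }
    rec(i + 1L, used, card, total)
    for (j in seq_len(n_pred)) {
      if (!used[j] && d[i, j] <= radius) {
        used[j] <- TRUE
        rec(i + 1L, used, card + 1L, total + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(n_pred), 0L, 0)
  list(tp = best$card, fp = n_pred - best$card, fn = n_gt - best$card)
}

# Direct simulation of the sequential contour-matching rule: scan ground
# truths in index order; each takes the unassigned prediction with the
# largest IOU at or above K (ties to the lower index).
oracle_match_contours <- function(gt, pred, K) {
  taken <- logical(length(pred))
  pairs <- NULL
  for (i in seq_along(gt)) {
    best_j <- 0L
    best_iou <- -Inf
    for (j in seq_along(pred)) {
      if (taken[j]) next
      v <- polygon_iou(gt[[i]], pred[[j]])
      if (v >= K && v > best_iou) {
        best_iou <- v
        best_j <- j
      }
    }
    if (best_j > 0) {
      taken[best_j] <- TRUE
      pairs <- rbind(pairs, c(i, best_j))
    }
  }
  pairs
}

# Per-pair tally oracle for agreement statistics on raw category lists.
oracle_agreement <- function(gt, pred) {
  lev <- c("low", "intermediate", "high")
  gi <- match(as.character(gt), lev)
  pi <- match(as.character(pred), lev)
  steps <- abs(gi - pi)
  c(
    concordance = mean(steps == 0),
    one_step = mean(steps == 1),
    two_step = mean(steps == 2)
  )
}

# Cohort generation with a deterministic reseed rule: the generator rejects
# singular draws (e.g. an all-negative HER2 cohort, common at small n), so
# tests that need any valid cohort step the seed forward until one succeeds.
gen_cohort_ok <- function(n, noise_sd = 5, seed = 1) {
  repeat {
    co <- tryCatch(
      gen_cohort(cohort_config(n_patients = n, noise_sd = noise_sd, seed = seed)),
      error = function(e) NULL
    )
    if (!is.null(co)) return(co)
    seed <- seed + 10000
  }
}

# Well-separated ground-truth points on a jittered grid, so greedy and
# exhaustive matching coincide at a tight radius.
separated_points <- function(n, spacing = 60) {
  k <- ceiling(sqrt(n))
  g <- expand.grid(ix = seq_len(k), iy = seq_len(k))[seq_len(n), ]
  cbind(
    g$ix * spacing + stats::runif(n, -5, 5),
    g$iy * spacing + stats::runif(n, -5, 5)
  )
}
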