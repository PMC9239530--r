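test_that("OLS recovers a noiseless linear response exactly", {
  co <- gen_cohort_ok(60, noise_sd = 0, seed = 4)
  beta <- attr(co, "true_coefficients")
  fit <- fit_rs_ols(co, response = "rs_raw")
  expect_equal(
    unname(fit$coefficients),
    unname(beta[c("intercept", fit$feature_names)]),
    tolerance = 1e-9
  )
  # residual orthogonality to the design
  X <- as.matrix(co[, fit$feature_names])
  resid <- co$rs_raw - predict_rs(fit, co)
  expect_lt(max(abs(crossprod(X, resid))) / nrow(co), 1e-6)
})

test_that("a constant response gives zero slopes and mean intercept", {
  co <- gen_cohort_ok(40, seed = 8)
  co$flat <- 21
  fit <- fit_rs_ols(co, response = "flat")
  expect_equal(unname(fit$coefficients[-1]), rep(0, 8), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[1]), 21, tolerance = 1e-10)
})

test_that("rank-deficient designs error with the collinear column named", {
  co <- gen_cohort_ok(40, seed = 8)
  co$dup <- co$er_h
  expect_error(
    fit_rs_ols(co, features = c("er_h", "pr_h", "dup")),
    "dup"
  )
})

test_that("LASSO at lambda zero equals OLS; heavy shrinkage kills all slopes", {
  co <- gen_cohort(cohort_config(n_patients = 150, noise_sd = 3, seed = 10))
  ols <- fit_rs_ols(co)
  l0 <- fit_rs_lasso(co, lambda = 0)
  expect_equal(l0$coefficients, ols$coefficients, tolerance = 1e-6)

  lbig <- fit_rs_lasso(co, lambda = 1e6)
  expect_equal(unname(lbig$coefficients[-1]), rep(0, 8))
  expect_equal(unname(lbig$coefficients[1]), mean(co$rs), tolerance = 1e-8)

  expect_error(fit_rs_lasso(co, lambda = -1), "non-negative")
})

test_that("LASSO non-zero slope count is non-increasing along a lambda grid", {
  co <- gen_cohort(cohort_config(n_patients = 150, noise_sd = 3, seed = 20))
  grid <- c(0.01, 0.1, 0.5, 1, 5, 20)
  nz <- vapply(grid, function(l) {
    sum(fit_rs_lasso(co, lambda = l)$coefficients[-1] != 0)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("seeded cross-validated LASSO is reproducible", {
  co <- gen_cohort(cohort_config(n_patients = 120, noise_sd = 4, seed = 30))
  f1 <- fit_rs_lasso(co, lambda = "cv", seed = 7)
  f2 <- fit_rs_lasso(co, lambda = "cv", seed = 7)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$lambda, f2$lambda)
})

test_that("predictions are linear and match feature-name contracts", {
  co <- gen_cohort(cohort_config(n_patients = 50, seed = 2))
  fit <- fit_rs_ols(co)
  base <- predict_rs(fit, co)
  shifted <- co
  shifted$tumor_size_cm <- shifted$tumor_size_cm + 0.5
  expect_equal(
    predict_rs(fit, shifted) - base,
    rep(0.5 * fit$coefficients[["tumor_size_cm"]], nrow(co))
  )
  expect_error(predict_rs(fit, co[, 1:3]), "missing feature")

  zero <- fit
  zero$coefficients[-1] <- 0
  expect_equal(predict_rs(zero, co), rep(zero$coefficients[[1]], nrow(co)))
})

test_that("fit metrics match brute-force formulas on a hand example", {
  y <- c(10, 14, 9, 21, 30, 18)
  yhat <- c(12, 13, 10, 19, 27, 20)
  p <- 2
  m <- fit_metrics(y, yhat, p)
  n <- 6
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  expect_equal(m$r2, r2, tolerance = 1e-12)
  expect_equal(m$adj_r2, 1 - (1 - r2) * (n - 1) / (n - p - 1), tolerance = 1e-12)
  r <- sum((y - mean(y)) * (yhat - mean(yhat))) /
    sqrt(sum((y - mean(y))^2) * sum((yhat - mean(yhat))^2))
  expect_equal(m$pearson_r, r, tolerance = 1e-12)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(m$p_value, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)

  perfect <- fit_metrics(y, y, p)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$adj_r2, 1)
  expect_equal(perfect$pearson_r, 1)

  null <- fit_metrics(y, rep(mean(y), 6), 1)
  expect_equal(null$r2, 0)
  expect_error(fit_metrics(rep(3, 6), y, 1), "zero variance")
})

test_that("adjusted R-squared never exceeds R-squared", {
  set.seed(6)
  for (i in 1:15) {
    n <- sample(10:60, 1)
    p <- sample(1:5, 1)
    y <- rnorm(n)
    yhat <- y + rnorm(n, sd = runif(1, 0.1, 2))
    m <- fit_metrics(y, yhat, p)
    expect_lte(m$adj_r2, m$r2 + 1e-12)
  }
})

test_that("training R-squared is monotone over nested OLS feature sets", {
  co <- gen_cohort(cohort_config(n_patients = 100, noise_sd = 6, seed = 40))
  feats <- wsirs:::model_variables()
  r2 <- vapply(seq_along(feats), function(k) {
    fit <- fit_rs_ols(co, features = feats[1:k])
    fit_metrics(co$rs, predict_rs(fit, co), k)$r2
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

# synthetic slide-level feature table for the combination search
make_slide_cohort <- function(n = 70, seed = 99) {
  wsirs:::with_seed(seed, {
    df <- tibble::tibble(
      nottingham = sample(1:3, n, TRUE),
      er_h = runif(n, 80, 300),
      pr_h = runif(n, 0, 300),
      her2_equivocal = rbinom(n, 1, 0.1),
      tumor_size_cm = runif(n, 0.4, 7),
      til_var = runif(n, 0, 4000),
      nuc_grade = sample(1:3, n, TRUE)
    )
    for (i in 1:10) {
      df[[sprintf("t%02d_tumor", i)]] <- rpois(n, 300)
      df[[sprintf("t%02d_til", i)]] <- rpois(n, 40)
      df[[sprintf("t%02d_pct", i)]] <- runif(n, 0.3, 0.95)
    }
    df$rs <- 5 + 2 * df$nottingham - 0.02 * df$er_h + 0.01 * df$t01_tumor +
      0.002 * df$til_var + rnorm(n, sd = 3)
    df
  })
}

test_that("the combination search scores all depth/toggle combinations", {
  df <- make_slide_cohort()
  res <- search_feature_combinations(df, depths = 1:4)
  expect_identical(nrow(res), 4L * 2L * 2L)
  expect_true(all(diff(res$adj_r2) <= 1e-12))
  best <- attr(res, "best_features")
  expect_true(all(c("nottingham", "er_h", "pr_h") %in% best))
  expect_true(res$r2[which.max(res$adj_r2)] <= 1)
})

test_that("tidy and glance expose coefficients and fit quality", {
  co <- gen_cohort(cohort_config(n_patients = 80, seed = 3))
  fit <- fit_rs_ols(co)
  td <- tidy(fit)
  expect_identical(td$term[1], "(intercept)")
  expect_identical(nrow(td), 9L)
  expect_true(all(c("std.error", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(
    gl$r2,
    fit_metrics(co$rs, predict_rs(fit, co), 8)$r2
  )
})

test_that("models round-trip through JSON", {
  co <- gen_cohort(cohort_config(n_patients = 80, seed = 3))
  fit <- fit_rs_lasso(co, lambda = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_rs_model(fit, path)
  back <- read_rs_model(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_identical(back$feature_names, fit$feature_names)
  expect_identical(back$method, "LASSO")
  expect_equal(predict_rs(back, co), predict_rs(fit, co))
})
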