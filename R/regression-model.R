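new_rs_model <- function(feature_names, coefficients, method, lambda = NA_real_,
                         standardization = NULL, fit = NULL) {
  structure(
    list(
      feature_names = feature_names,
      coefficients = coefficients, # named: "(intercept)" then features
      method = method,
      lambda = lambda,
      standardization = standardization,
      fit = fit
    ),
    class = "rs_model"
  )
}

#' @export
print.rs_model <- function(x, ...) {
  cat(sprintf(
    "<rs_model> %s, %d feature(s)%s\n", x$method, length(x$feature_names),
    if (!is.na(x$lambda)) sprintf(", lambda = %.4g", x$lambda) else ""
  ))
  print(round(x$coefficients, 4))
  invisible(x)
}

model_matrix_from <- function(data, features) {
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(data[, features, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Fit the recurrence-score model by ordinary least squares
#'
#' @param data Patient-level data frame containing the features and response.
#' @param features Feature column names (default: the eight model variables).
#' @param response Response column (default `"rs"`).
#' @return An `rs_model` with intercept + per-feature coefficients; supports
#'   [predict_rs()], [tidy()][generics::tidy] and [glance()][generics::glance].
#' @examples
#' co <- gen_cohort(cohort_config(n_patients = 60, seed = 2))
#' fit <- fit_rs_ols(co)
#' tidy(fit)
#' @export
fit_rs_ols <- function(data, features = model_variables(), response = "rs") {
  X <- model_matrix_from(data, features)
  y <- as.numeric(data[[response]])
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 observations", call. = FALSE)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1) {
    dropped <- c("(intercept)", features)[qrX$pivot[-seq_len(qrX$rank)]]
    stop(
      "rank-deficient design; collinear column(s): ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  df <- data.frame(..y = y, X)
  fit <- stats::lm(..y ~ ., data = df)
  coefs <- stats::coef(fit)
  names(coefs) <- c("(intercept)", features)
  new_rs_model(features, coefs, "OLS", fit = fit)
}

#' Fit the recurrence-score model by LASSO
#'
#' L1-penalized least squares on z-scored features with an unpenalized
#' intercept; coefficients are reported on the original feature scale.
#' `lambda = "cv"` selects the penalty by seeded k-fold cross-validation with
#' the one-standard-error rule; `lambda = 0` coincides with OLS.
#'
#' @inheritParams fit_rs_ols
#' @param lambda A non-negative penalty, or `"cv"`.
#' @param nfolds Folds for cross-validation (default 5).
#' @param seed Seed for the CV fold assignment.
#' @return An `rs_model` with `method = "LASSO"` and the `lambda` used.
#' @export
fit_rs_lasso <- function(data, features = model_variables(), response = "rs",
                         lambda = "cv", nfolds = 5, seed = 1L) {
  X <- model_matrix_from(data, features)
  y <- as.numeric(data[[response]])
  if (is.numeric(lambda) && lambda < 0) {
    stop("`lambda` must be non-negative", call. = FALSE)
  }
  std <- list(mean = colMeans(X), sd = apply(X, 2, stats::sd))

  if (identical(lambda, "cv")) {
    foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), nrow(X))))
    cv <- glmnet::cv.glmnet(
      X, y,
      alpha = 1, standardize = TRUE, foldid = foldid,
      type.measure = "mse", thresh = 1e-12
    )
    lambda <- cv$lambda.1se
    fit <- cv$glmnet.fit
    beta <- stats::coef(fit, s = lambda)
  } else {
    fit <- glmnet::glmnet(X, y, alpha = 1, standardize = TRUE, thresh = 1e-12)
    # exact = TRUE refits at the requested lambda, so lambda = 0 matches OLS
    beta <- stats::coef(fit, s = lambda, exact = TRUE, x = X, y = y)
  }
  coefs <- as.numeric(beta)
  names(coefs) <- c("(intercept)", features)
  new_rs_model(features, coefs, "LASSO", lambda = lambda,
               standardization = std, fit = fit)
}

#' Predict recurrence scores
#'
#' Raw linear predictions, deliberately unclamped: correlation metrics use the
#' raw scale, and risk stratification applies its cutoffs to raw predictions.
#'
#' @param model An `rs_model`.
#' @param data New data containing the model's feature columns.
#' @return A numeric vector of predicted RS.
#' @export
predict_rs <- function(model, data) {
  stopifnot(inherits(model, "rs_model"))
  X <- model_matrix_from(data, model$feature_names)
  as.numeric(model$coefficients[1] + X %*% model$coefficients[-1])
}

#' @export
predict.rs_model <- function(object, newdata, ...) predict_rs(object, newdata)

#' Goodness-of-fit metrics for RS predictions
#'
#' R^2 = 1 - SS_res / SS_tot, adjusted R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1),
#' and the Pearson correlation between observed and predicted RS with its
#' two-sided p-value from the t distribution on n - 2 degrees of freedom.
#'
#' @param y_true Observed RS.
#' @param y_pred Predicted RS (same length).
#' @param p Number of model features (for the adjustment).
#' @return A one-row tibble: `r2`, `adj_r2`, `pearson_r`, `p_value`, `n`, `p`.
#' @export
fit_metrics <- function(y_true, y_pred, p) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  n <- length(y_true)
  if (n <= p + 1) stop("need n > p + 1", call. = FALSE)
  if (stats::var(y_true) == 0) {
    stop("`y_true` has zero variance", call. = FALSE)
  }
  ss_res <- sum((y_true - y_pred)^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- 1 - ss_res / ss_tot
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  if (stats::var(y_pred) == 0) {
    r <- NA_real_
    pv <- NA_real_
  } else {
    ct <- stats::cor.test(y_true, y_pred, method = "pearson")
    r <- unname(ct$estimate)
    pv <- ct$p.value
  }
  tibble::tibble(
    r2 = r2, adj_r2 = adj_r2, pearson_r = r, p_value = pv,
    n = n, p = as.integer(p)
  )
}

#' Search image-feature combinations by training adjusted R-squared
#'
#' Enumerates the model family used for feature selection: the tile-wise
#' triplets of the first x = 1..10 top tiles used jointly, with the TIL number
#' variance and the aggregated nuclear grade each toggled on or off, always on
#' top of the Magee variables. Each combination is fit by OLS on `data` and
#' scored by training adjusted R^2; ties go to fewer features.
#'
#' @param data Training data with `rs`, the Magee columns, and tile-feature
#'   columns `t01_tumor` ... `t10_pct` plus `til_var`, `nuc_grade`.
#' @param magee_features Columns always included.
#' @param depths Tile depths x to try (default 1:10).
#' @param response Response column.
#' @return A tibble of combinations (`depth`, `use_til_var`, `use_nuc_grade`,
#'   `n_features`, `r2`, `adj_r2`) sorted best-first; the winning feature set
#'   is in the `best_features` attribute.
#' @export
search_feature_combinations <- function(data,
                                        magee_features = c(
                                          "nottingham", "er_h", "pr_h",
                                          "her2_equivocal", "tumor_size_cm"
                                        ),
                                        depths = 1:10,
                                        response = "rs") {
  combos <- tidyr::expand_grid(
    depth = depths, use_til_var = c(FALSE, TRUE), use_nuc_grade = c(FALSE, TRUE)
  )
  score_one <- function(depth, use_til_var, use_nuc_grade) {
    tiles <- as.vector(vapply(
      seq_len(depth),
      function(i) sprintf("t%02d_%s", i, c("tumor", "til", "pct")),
      character(3)
    ))
    feats <- c(
      magee_features, tiles,
      if (use_til_var) "til_var",
      if (use_nuc_grade) "nuc_grade"
    )
    fit <- fit_rs_ols(data, features = feats, response = response)
    m <- fit_metrics(
      as.numeric(data[[response]]), predict_rs(fit, data), length(feats)
    )
    tibble::tibble(n_features = length(feats), r2 = m$r2, adj_r2 = m$adj_r2)
  }
  res <- dplyr::bind_cols(
    combos,
    purrr::pmap_dfr(combos, score_one)
  ) |>
    dplyr::arrange(dplyr::desc(.data$adj_r2), .data$n_features)
  best <- res[1, ]
  tiles <- as.vector(vapply(
    seq_len(best$depth),
    function(i) sprintf("t%02d_%s", i, c("tumor", "til", "pct")),
    character(3)
  ))
  attr(res, "best_features") <- c(
    magee_features, tiles,
    if (best$use_til_var) "til_var",
    if (best$use_nuc_grade) "nuc_grade"
  )
  res
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an RS model's coefficients
#'
#' @param x An `rs_model`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` and, for OLS fits, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy rs_model
#' @export
tidy.rs_model <- function(x, ...) {
  out <- tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients)
  )
  if (x$method == "OLS" && !is.null(x$fit)) {
    sm <- stats::coef(summary(x$fit))
    out$std.error <- unname(sm[, "Std. Error"])
    out$statistic <- unname(sm[, "t value"])
    out$p.value <- unname(sm[, "Pr(>|t|)"])
  }
  out
}

#' One-row model summary
#'
#' @param x An `rs_model`.
#' @param data Optional data to evaluate on; defaults to the training data for
#'   OLS fits.
#' @param response Response column when `data` is supplied.
#' @param ... Unused.
#' @return A one-row tibble as [fit_metrics()], plus `method` and `lambda`.
#' @method glance rs_model
#' @export
glance.rs_model <- function(x, data = NULL, response = "rs", ...) {
  if (is.null(data)) {
    if (x$method != "OLS" || is.null(x$fit)) {
      stop("supply `data` to evaluate a LASSO model", call. = FALSE)
    }
    y <- x$fit$model$..y
    yhat <- stats::fitted(x$fit)
  } else {
    y <- as.numeric(data[[response]])
    yhat <- predict_rs(x, data)
  }
  m <- fit_metrics(y, yhat, length(x$feature_names))
  m$method <- x$method
  m$lambda <- x$lambda
  m
}

#' Persist an RS model as JSON
#'
#' @param model An `rs_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rs_model <- function(model, path) {
  stopifnot(inherits(model, "rs_model"))
  jsonlite::write_json(
    list(
      feature_names = model$feature_names,
      coefficients = as.list(model$coefficients),
      method = model$method,
      lambda = model$lambda,
      standardization = model$standardization
    ),
    path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read an RS model from JSON
#'
#' @param path File written by [write_rs_model()].
#' @return An `rs_model`.
#' @export
read_rs_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_rs_model(
    feature_names = j$feature_names,
    coefficients = unlist(j$coefficients),
    method = j$method,
    lambda = j$lambda %||% NA_real_,
    standardization = j$standardization
  )
}
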