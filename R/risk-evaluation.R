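risk_levels <- function() c("high", "intermediate", "low")

#' TAILORx risk stratification of a recurrence score
#'
#' Scores below 16 are low risk, 16-25 intermediate, above 25 high. Raw
#' (non-integer, even negative) model predictions are compared directly
#' against the 16 and 25 cutoffs, so 25.4 is intermediate.
#'
#' @param score Recurrence score(s), observed or predicted.
#' @param low_cutoff,high_cutoff Category boundaries (defaults 16 and 25):
#'   low is `score < low_cutoff`, high is `score > high_cutoff`.
#' @return An ordered factor with levels low < intermediate < high.
#' @examples
#' stratify_rs(c(15, 16, 25, 26))
#' @export
stratify_rs <- function(score, low_cutoff = 16, high_cutoff = 25) {
  out <- ifelse(score < low_cutoff, "low",
    ifelse(score <= high_cutoff, "intermediate", "high")
  )
  factor(out, levels = c("low", "intermediate", "high"), ordered = TRUE)
}

as_risk_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  x <- tolower(as.character(x))
  x[x %in% c("middle", "mid")] <- "intermediate"
  bad <- setdiff(unique(x), c("low", "intermediate", "high"))
  if (length(bad) > 0) {
    stop("unknown risk categor(ies): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = c("low", "intermediate", "high"), ordered = TRUE)
}

#' Three-by-three risk category confusion matrix
#'
#' Tabulates ground-truth against predicted risk categories in the
#' high/intermediate/low display order (rows: ground truth).
#'
#' @param gt,pred Equal-length vectors of risk categories (`"low"`,
#'   `"intermediate"`/`"middle"`, `"high"`), e.g. from [stratify_rs()].
#' @return A 3x3 integer matrix with dimnames `gt` x `pred`.
#' @export
confusion3 <- function(gt, pred) {
  gt <- as_risk_factor(gt)
  pred <- as_risk_factor(pred)
  if (length(gt) != length(pred)) {
    stop("`gt` and `pred` must have equal length", call. = FALSE)
  }
  lev <- risk_levels()
  m <- table(
    gt = factor(as.character(gt), levels = lev),
    pred = factor(as.character(pred), levels = lev)
  )
  matrix(as.integer(m), 3, 3, dimnames = list(gt = lev, pred = lev))
}

#' Concordance and step-discordance of a risk confusion matrix
#'
#' With categories totally ordered (low < intermediate < high), each cell of
#' the 3x3 matrix sits at a step distance 0, 1 or 2 from the diagonal.
#' Concordance is the diagonal fraction; one-/two-step discordance are the
#' fractions at distance 1 and 2. The three always sum to exactly 1.
#'
#' @param m A 3x3 count matrix in high/intermediate/low order (rows: ground
#'   truth), e.g. from [confusion3()].
#' @return A one-row tibble: `concordance`, `one_step`, `two_step`, `n`.
#' @export
agreement_stats <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == 3, ncol(m) == 3, all(m >= 0))
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  dist <- abs(outer(1:3, 1:3, "-"))
  tibble::tibble(
    concordance = sum(m[dist == 0]) / n,
    one_step = sum(m[dist == 1]) / n,
    two_step = sum(m[dist == 2]) / n,
    n = as.integer(n)
  )
}

#' TAILORx-style chemotherapy recommendation
#'
#' Chemotherapy is recommended for a high recurrence score (>= 26 by default),
#' or for an intermediate score (>= 16) in younger patients (age <= 50). The
#' rule is an external reconstruction of the trial's suggested practice, not
#' a quotation, and each threshold can be overridden.
#'
#' @param rs Recurrence score(s), observed or predicted.
#' @param age Patient age(s) in years, positive.
#' @param high_rs RS at or above which chemotherapy is always recommended.
#' @param mid_rs RS at or above which chemotherapy is recommended for young
#'   patients.
#' @param young_age Age at or below which the intermediate branch applies.
#' @return `"yes"`/`"no"` per patient.
#' @export
chemo_recommendation <- function(rs, age, high_rs = 26, mid_rs = 16, young_age = 50) {
  if (any(age <= 0)) stop("`age` must be positive", call. = FALSE)
  ifelse(rs >= high_rs | (age <= young_age & rs >= mid_rs), "yes", "no")
}

#' Chemotherapy recommendation discordance
#'
#' Tabulates recommendations from the assay RS against recommendations from
#' predicted RS into a 2x2 matrix (rows: RS no/yes; columns: predicted
#' no/yes); the discordant count is the off-diagonal sum.
#'
#' @param gt_rec,pred_rec Equal-length `"yes"`/`"no"` (or logical) vectors.
#' @return A `chemo_discordance` object: list with `matrix`,
#'   `discordant_count`, `row_totals`, `col_totals`, `n`.
#' @seealso [discordance_stats()] to summarize an already-tabulated matrix.
#' @export
recommendation_discordance <- function(gt_rec, pred_rec) {
  to_yn <- function(x) {
    if (is.logical(x)) x <- ifelse(x, "yes", "no")
    x <- tolower(as.character(x))
    stopifnot(all(x %in% c("yes", "no")))
    factor(x, levels = c("no", "yes"))
  }
  gt_rec <- to_yn(gt_rec)
  pred_rec <- to_yn(pred_rec)
  if (length(gt_rec) != length(pred_rec)) {
    stop("`gt_rec` and `pred_rec` must have equal length", call. = FALSE)
  }
  m <- table(gt_rec, pred_rec)
  m <- matrix(as.integer(m), 2, 2, dimnames = list(
    rs = c("no", "yes"), predicted = c("no", "yes")
  ))
  discordance_stats(m)
}

#' Summarize a 2x2 recommendation matrix
#'
#' @param m A 2x2 count matrix, rows RS no/yes, columns predicted no/yes.
#' @return A `chemo_discordance` object (see
#'   [recommendation_discordance()]).
#' @export
discordance_stats <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == 2, ncol(m) == 2, all(m >= 0))
  structure(
    list(
      matrix = m,
      discordant_count = as.integer(m[1, 2] + m[2, 1]),
      row_totals = as.integer(rowSums(m)),
      col_totals = as.integer(colSums(m)),
      n = as.integer(sum(m))
    ),
    class = "chemo_discordance"
  )
}

#' @export
print.chemo_discordance <- function(x, ...) {
  cat(sprintf(
    "<chemo_discordance> n = %d, discordant = %d\n", x$n, x$discordant_count
  ))
  print(x$matrix)
  invisible(x)
}
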