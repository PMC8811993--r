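#' Empirical (Mann-Whitney) AUC
#'
#' The probability that a randomly chosen positive (refractory) score
#' exceeds a randomly chosen negative (responsive) score, ties counted
#' one-half — the area under the empirical ROC curve. Computed from ranks.
#'
#' @param scores numeric predictor; higher values indicate the positive
#'   class.
#' @param labels binary class labels (0/1, logical, or a two-level factor
#'   whose second level is positive).
#' @return AUC in `[0, 1]`.
#' @export
empirical_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.character(labels)) {
    lv <- sort(unique(labels))
    if (length(lv) > 2L) stop("labels must be binary")
    labels <- as.integer(labels == lv[length(lv)])
  }
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  as.integer(labels)
}

roc_object <- function(scores, labels) {
  y <- as_binary_labels(labels)
  pROC::roc(response = y, predictor = scores, levels = c(0L, 1L),
            direction = "<", quiet = TRUE)
}

#' AUC with DeLong variance and confidence interval
#'
#' Nonparametric variance of the Mann-Whitney AUC from DeLong's structural
#' components, with a normal-approximation two-sided confidence interval
#' clipped to `[0, 1]`.
#'
#' @inheritParams empirical_auc
#' @param conf confidence level (default 0.95).
#' @param logit_scale if `TRUE`, build the interval on the logit scale and
#'   back-transform (never needs clipping); the default is the plain normal
#'   scale.
#' @return list with `auc`, `se`, and `ci95 = c(lo, hi)`.
#' @export
delong_variance_and_ci <- function(scores, labels, conf = 0.95,
                                   logit_scale = FALSE) {
  y <- as_binary_labels(labels)
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L) {
    stop("each class needs at least 2 members")
  }
  r <- roc_object(scores, y)
  a <- as.numeric(pROC::auc(r))
  v <- suppressWarnings(pROC::var(r, method = "delong"))
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- if (logit_scale && a > 0 && a < 1 && se > 0) {
    lg <- stats::qlogis(a)
    se_lg <- se / (a * (1 - a))
    stats::plogis(lg + c(-z, z) * se_lg)
  } else {
    pmin(pmax(a + c(-z, z) * se, 0), 1)
  }
  list(auc = a, se = se, ci95 = ci)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two predictors measured on the same subjects with
#' the same outcome labels, using the covariance of their DeLong structural
#' components. When the two predictors are identical (or both AUCs are
#' degenerate with zero contrast variance) the statistic is 0 and p is 1.
#'
#' @param scores_a,scores_b the two predictors, same subjects in the same
#'   order.
#' @inheritParams empirical_auc
#' @return list with `z` (signed, positive when `scores_a` has the larger
#'   AUC) and two-sided `p`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop("predictors differ in length")
  }
  y <- as_binary_labels(labels)
  ra <- roc_object(scores_a, y)
  rb <- roc_object(scores_b, y)
  ht <- suppressWarnings(
    pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  )
  z <- unname(ht$statistic)
  p <- ht$p.value
  if (!is.finite(z)) {
    # zero contrast variance: identical structural components
    z <- 0
    p <- 1
  }
  list(z = z, p = p)
}

#' Closed-form AUC of two normal score distributions
#'
#' If negatives are `N(mu_neg, sd_neg^2)` and positives are
#' `N(mu_pos, sd_pos^2)`, the AUC is
#' `pnorm((mu_pos - mu_neg) / sqrt(sd_neg^2 + sd_pos^2))`. Serves as the
#' analytic check on simulation-based AUC estimates.
#'
#' @param mu_neg,sd_neg,mu_pos,sd_pos group means and standard deviations
#'   (sds > 0).
#' @return AUC in `[0, 1]`.
#' @export
binormal_auc <- function(mu_neg, sd_neg, mu_pos, sd_pos) {
  if (sd_neg <= 0 || sd_pos <= 0) stop("standard deviations must be > 0")
  stats::pnorm((mu_pos - mu_neg) / sqrt(sd_neg^2 + sd_pos^2))
}

#' Intraclass correlation for two-grader agreement
#'
#' ICC(2,1): two-way random effects, absolute agreement, single measure,
#' computed from the two-way ANOVA mean squares of the eyes-by-graders
#' table. This is the agreement index for two graders independently
#' measuring the same quantity.
#'
#' @param grader_a,grader_b equal-length numeric vectors (>= 3 subjects).
#' @return ICC estimate (at most 1; can be negative for discordant raters).
#' @export
icc_agreement <- function(grader_a, grader_b) {
  if (length(grader_a) != length(grader_b)) stop("grader vectors differ in length")
  n <- length(grader_a)
  if (n < 3L) stop("need at least 3 subjects")
  x <- cbind(grader_a, grader_b)
  k <- 2
  grand <- mean(x)
  if (isTRUE(all.equal(stats::var(as.vector(x)), 0))) {
    stop("zero total variance: ICC undefined")
  }
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Two-sample t-test
#'
#' Student's pooled-variance two-sided test by default (the convention of
#' the statistical software the modelled analysis used); set
#' `welch = TRUE` for the unequal-variance form.
#'
#' @param x,y numeric samples (each >= 2 values).
#' @param welch use the Welch approximation instead of pooled variance.
#' @return list with `t` and two-sided `p`.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 values")
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction (df = 1, two-sided), the variant that
#' reproduces the printed contingency-table p-values of the modelled study.
#'
#' @param table 2x2 matrix of nonnegative counts with positive margins.
#' @return list with `chi2` and `p`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in contingency table")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(ht$statistic), p = ht$p.value)
}
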