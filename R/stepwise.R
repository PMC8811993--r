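#' Backward stepwise logistic regression with Wald elimination
#'
#' Fits the full maximum-likelihood logistic model of a binary response on
#' all supplied covariates, then repeatedly removes the covariate with the
#' largest Wald p-value above `p_stay` and refits, until every remaining
#' covariate satisfies `p <= p_stay`. The selection trace and the final
#' model's odds ratios (`exp(beta)`, per unit of the covariate) with Wald
#' 95% confidence intervals are reported.
#'
#' Complete or quasi-complete separation makes maximum-likelihood estimates
#' diverge; when detected (non-convergence or runaway coefficients) the fit
#' is repeated with a small ridge penalty for stable coefficient reporting,
#' the result is flagged `separated = TRUE`, and no Wald-based elimination
#' is attempted.
#'
#' @param X data.frame (or matrix) of numeric covariates, no missing
#'   values.
#' @param y binary response (0/1, logical, or two-level factor; the second
#'   level is the event).
#' @param p_stay Wald p-value above which a covariate is removed
#'   (default 0.05; the modelled analysis screened candidates at the same
#'   level).
#' @param ridge_lambda penalty used only by the separation fallback.
#' @return a list of class `"selection_trace"`: `trace` (data.frame of
#'   `step`, `variable_removed`, `p_at_removal`), `final` (data.frame of
#'   `variable`, `coef`, `or`, `or_lo`, `or_hi`, `p`), `separated`, and
#'   `model` (the final `glm`, or `NULL` under the ridge fallback).
#' @export
backward_stepwise_logistic <- function(X, y, p_stay = 0.05,
                                       ridge_lambda = 1e-2) {
  X <- as.data.frame(X)
  if (ncol(X) < 1L) stop("need at least one covariate")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  y <- as_binary_labels(y)
  if (nrow(X) != length(y)) stop("X and y differ in length")

  vars <- names(X)
  trace <- data.frame(step = integer(), variable_removed = character(),
                      p_at_removal = numeric(), stringsAsFactors = FALSE)
  step_i <- 0L

  repeat {
    dat <- cbind(X[vars], .y = y)
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = dat, family = stats::binomial())
    )
    if (is_separated(fit)) {
      co <- ridge_logistic(as.matrix(X[vars]), y, ridge_lambda)
      final <- data.frame(
        variable = vars, coef = co, or = exp(co),
        or_lo = NA_real_, or_hi = NA_real_, p = NA_real_,
        stringsAsFactors = FALSE
      )
      return(structure(list(trace = trace, final = final, separated = TRUE,
                            model = NULL),
                       class = "selection_trace"))
    }
    sm <- summary(fit)$coefficients
    pw <- sm[setdiff(rownames(sm), "(Intercept)"), 4, drop = TRUE]
    names(pw) <- setdiff(rownames(sm), "(Intercept)")
    if (length(pw) == 0L || max(pw) <= p_stay) {
      keep <- setdiff(rownames(sm), "(Intercept)")
      est <- sm[keep, 1]
      se <- sm[keep, 2]
      final <- data.frame(
        variable = if (length(keep)) sub("^`(.*)`$", "\\1", keep) else character(),
        coef = unname(est), or = unname(exp(est)),
        or_lo = unname(exp(est - 1.96 * se)),
        or_hi = unname(exp(est + 1.96 * se)),
        p = unname(if (length(keep)) sm[keep, 4] else numeric()),
        stringsAsFactors = FALSE
      )
      return(structure(list(trace = trace, final = final, separated = FALSE,
                            model = fit),
                       class = "selection_trace"))
    }
    worst <- names(pw)[which.max(pw)]
    step_i <- step_i + 1L
    trace <- rbind(trace, data.frame(
      step = step_i, variable_removed = sub("^`(.*)`$", "\\1", worst),
      p_at_removal = unname(max(pw)), stringsAsFactors = FALSE
    ))
    vars <- setdiff(vars, sub("^`(.*)`$", "\\1", worst))
    if (length(vars) == 0L) {
      final <- data.frame(variable = character(), coef = numeric(),
                          or = numeric(), or_lo = numeric(),
                          or_hi = numeric(), p = numeric(),
                          stringsAsFactors = FALSE)
      return(structure(list(trace = trace, final = final, separated = FALSE,
                            model = NULL),
                       class = "selection_trace"))
    }
  }
}

is_separated <- function(fit) {
  !fit$converged ||
    any(abs(stats::coef(fit)[-1]) > 15) ||
    any(summary(fit)$coefficients[, 2] > 1e3)
}

# Ridge-penalized logistic fit by BFGS on the penalized log-likelihood;
# intercept unpenalized. Used only as the separation fallback.
ridge_logistic <- function(X, y, lambda) {
  Xm <- cbind(1, scale(X, scale = FALSE))
  nll <- function(b) {
    eta <- drop(Xm %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      lambda / 2 * sum(b[-1]^2)
  }
  grad <- function(b) {
    mu <- stats::plogis(drop(Xm %*% b))
    g <- drop(crossprod(Xm, mu - y))
    g[-1] <- g[-1] + lambda * b[-1]
    g
  }
  fit <- stats::optim(rep(0, ncol(Xm)), nll, grad, method = "BFGS",
                      control = list(maxit = 500))
  fit$par[-1]
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace>", if (x$separated) "(separation fallback)" else "",
      "\n")
  if (nrow(x$trace)) {
    cat("removed:\n")
    print(x$trace, row.names = FALSE)
  } else {
    cat("no variables removed\n")
  }
  cat("final model:\n")
  print(x$final, row.names = FALSE, digits = 4)
  invisible(x)
}
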