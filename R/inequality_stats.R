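# Inequality measures: concentration index with convenient-regression
# inference, equity gap (Welch t-test), equity ratio, significance stars.

#' Concentration index
#'
#' Measures socioeconomic inequality in a nonnegative outcome as twice the
#' covariance between the outcome and the fractional wealth rank, divided by
#' the outcome mean: \eqn{CI = (2/\mu)\,cov(y_i, R_i)}. Negative values mean
#' the burden is concentrated among the poorest. The covariance uses the
#' population convention (divisor = total weight), which for unit weights
#' makes the identity \eqn{CI = 2\sum y_i R_i/(n\mu) - 1} exact.
#'
#' For binary outcomes the plain index is returned (its attainable range
#' shrinks with the mean); no bounded-outcome rescaling is applied.
#'
#' @param sample a \code{\link{ranked_sample}}, or a numeric vector of
#'   outcome values when \code{ranks} is given.
#' @param ranks fractional ranks (only when \code{sample} is a vector).
#' @param weights positive weights (only when \code{sample} is a vector).
#' @return the concentration index, a dimensionless value in (-1, 1).
#' @export
concentration_index <- function(sample, ranks = NULL, weights = NULL) {
  s <- as_ranked(sample, ranks, weights)
  y <- s$values; r <- s$ranks; w <- s$weights
  if (length(y) < 2L) stop("need at least 2 observations")
  mu <- stats::weighted.mean(y, w)
  if (mu == 0) stop("undefined index: outcome mean is zero")
  2 / mu * wcov_pop(y, r, w)
}

# population-convention weighted covariance (divisor = total weight)
wcov_pop <- function(x, y, w) {
  W <- sum(w)
  mx <- sum(w * x) / W
  my <- sum(w * y) / W
  sum(w * (x - mx) * (y - my)) / W
}

as_ranked <- function(sample, ranks, weights) {
  if (inherits(sample, "ranked_sample")) return(sample)
  n <- length(sample)
  if (is.null(ranks)) stop("supply a ranked_sample or ranks")
  if (is.null(weights)) weights <- rep(1, n)
  list(values = as.numeric(sample), ranks = ranks, weights = weights)
}

#' Concentration-index inference via the convenient regression
#'
#' Regresses \eqn{z_i = 2\,var(R)\,y_i/\mu} on the fractional rank
#' \eqn{R_i} by OLS: the slope equals the concentration index exactly
#' (population-covariance conventions match), and its heteroskedasticity-
#' robust (HC1) standard error provides the test of CI = 0, with a
#' two-sided normal p-value.
#'
#' Degenerate constant outcomes have slope 0 and no sampling variability;
#' they are reported as se = 0, p = 1.
#'
#' @param sample a \code{\link{ranked_sample}} (unit weights assumed for
#'   inference), or outcome vector with \code{ranks}.
#' @param ranks fractional ranks when \code{sample} is a vector.
#' @return list with \code{ci} (the slope), \code{se}, \code{p}.
#' @export
ci_inference <- function(sample, ranks = NULL) {
  s <- as_ranked(sample, ranks, NULL)
  y <- s$values; r <- s$ranks
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations for a standard error")
  mu <- mean(y)
  if (mu == 0) stop("undefined index: outcome mean is zero")
  vr <- wcov_pop(r, r, rep(1, n))
  z <- 2 * vr * y / mu
  if (stats::sd(y) == 0)
    return(list(ci = 0, se = 0, p = 1))
  fit <- stats::lm(z ~ r)
  slope <- unname(stats::coef(fit)[2L])
  # suppress summary.lm's perfect-fit warning for exactly linear outcomes
  se <- suppressWarnings(sqrt(sandwich::vcovHC(fit, type = "HC1")[2L, 2L]))
  p <- if (se == 0) (if (slope == 0) 1 else 0)
       else 2 * stats::pnorm(-abs(slope / se))
  list(ci = slope, se = se, p = p)
}

#' Equity gap between two groups
#'
#' Absolute inequality measure: difference in group means (e.g. poorest
#' minus least poor, or rural minus urban), tested against zero with a
#' Welch two-sample t-test (two-sided, unequal variances).
#'
#' @param values_a,values_b numeric outcome vectors for the two groups.
#' @return list with \code{gap} (mean_a - mean_b), \code{se}, \code{p}.
#' @export
equity_gap <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both groups must be non-empty")
  gap <- mean(values_a) - mean(values_b)
  if (length(values_a) < 2L || length(values_b) < 2L)
    return(list(gap = gap, se = NA_real_, p = NA_real_))
  se <- sqrt(stats::var(values_a) / length(values_a) +
             stats::var(values_b) / length(values_b))
  if (se == 0) # both groups constant: no variability, no evidence of a gap
    return(list(gap = gap, se = 0, p = if (gap == 0) 1 else 0))
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(gap = gap, se = se, p = tt$p.value)
}

#' Equity ratio between two group means
#'
#' Relative inequality measure: mean_a / mean_b. A zero denominator yields
#' an explicit undefined value (NA), not infinity.
#'
#' @param mean_a,mean_b group means.
#' @return the ratio, or NA_real_ when \code{mean_b} is zero.
#' @export
equity_ratio <- function(mean_a, mean_b) {
  if (is.na(mean_b) || mean_b == 0) return(NA_real_)
  mean_a / mean_b
}

#' Significance stars
#'
#' Conventional table annotation: \code{***} for p < 0.01, \code{**} for
#' p < 0.05, \code{*} for p < 0.10, empty otherwise. Inequalities are
#' strict, so a p-value exactly at a threshold maps to the weaker star.
#'
#' @param p p-value(s) in [0, 1]; NA gives "".
#' @return character vector of star strings.
#' @export
stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("")
    if (pi < 0 || pi > 1) stop("p-value outside [0, 1]")
    if (pi < 0.01) "***" else if (pi < 0.05) "**" else if (pi < 0.10) "*" else ""
  }, character(1))
}
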