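# Asset-based wealth index: first-principal-component scores, tie-aware
# fractional ranks, quintile assignment.

#' Household wealth scores from asset indicators
#'
#' Standardises each asset/housing indicator to zero mean and unit variance
#' and projects the rows onto the first principal component of the
#' standardised matrix (PCA on the correlation scale, the standard choice
#' for mixed binary/ordinal items). The eigenvector sign is fixed so that
#' the score correlates positively with the row-sum of standardised
#' indicators: higher score = wealthier.
#'
#' @param survey an \code{exit_survey}, or a numeric indicator matrix.
#' @return numeric vector of scores, one per record.
#' @export
wealth_scores <- function(survey) {
  x <- if (inherits(survey, "exit_survey")) asset_matrix(survey) else as.matrix(survey)
  if (nrow(x) < 2L) stop("need at least 2 records for a wealth index")
  if (anyNA(x))
    stop("missing asset indicator values: impute by mode or drop rows upstream")
  sds <- apply(x, 2L, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    warning("dropping ", sum(constant), " constant indicator(s): ",
            paste(utils::head(colnames(x)[constant], 5), collapse = ", "))
    x <- x[, !constant, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("fewer than 2 usable (non-constant) indicators")
  z <- scale(x)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1L]
  # sign orientation: eigenvectors are sign-ambiguous
  if (sum(score * rowSums(z)) < 0) score <- -score
  as.numeric(score)
}

#' Weighted tie-aware fractional ranks
#'
#' Positions each observation in the wealth ordering as the cumulative
#' weight share up to its midpoint: with unit weights and no ties,
#' \eqn{R_i = (i - 0.5)/n} for the i-th poorest. Tied scores all receive the
#' midpoint rank of their tie block (the average of the ranks the tied
#' positions would occupy), which preserves the weighted mean rank of 0.5
#' exactly -- the identity the concentration index relies on.
#'
#' @param scores numeric vector (any monotone transform gives identical ranks).
#' @param weights positive weights, default all 1.
#' @return numeric vector of ranks in (0, 1), in the order of \code{scores}.
#' @export
fractional_ranks <- function(scores, weights = NULL) {
  n <- length(scores)
  if (n == 0L) stop("empty input")
  if (anyNA(scores)) stop("missing scores")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length mismatch")
  if (any(weights <= 0)) stop("weights must be positive")
  ord <- order(scores)
  w <- weights[ord]
  s <- scores[ord]
  total <- sum(w)
  # block midpoint per tie group of the sorted scores
  grp <- cumsum(!duplicated(s))
  wg <- tapply(w, grp, sum)
  cum_before <- cumsum(c(0, wg[-length(wg)]))
  mid <- (cum_before + wg / 2) / total
  ranks_sorted <- mid[grp]
  out <- numeric(n)
  out[ord] <- ranks_sorted
  out
}

#' Assign wealth quintiles from fractional ranks
#'
#' Cuts the (0,1) rank scale into fifths: quintile
#' \eqn{= \min(\lfloor 5R \rfloor + 1, 5)}; 1 = poorest, 5 = least poor.
#' Cutting on the fractional rank (not raw score percentiles) guarantees
#' tied scores share a quintile, and with distinct scores group sizes differ
#' by at most one.
#'
#' @param ranks numeric vector in (0, 1).
#' @return integer vector of quintile labels 1..5.
#' @export
assign_quintiles <- function(ranks) {
  if (any(is.na(ranks)) || any(ranks <= 0) || any(ranks >= 1))
    stop("ranks must lie strictly in (0, 1)")
  as.integer(pmin(floor(5 * ranks) + 1, 5))
}

#' Pair an outcome with wealth ranks
#'
#' Convenience constructor bundling outcome values with scores, fractional
#' ranks, weights and quintiles for the inequality measures.
#'
#' @param values numeric outcome vector \eqn{y_i}.
#' @param scores wealth scores (same length); ranks are computed from these
#'   unless \code{ranks} is supplied directly.
#' @param weights positive weights, default unit.
#' @param ranks optional precomputed fractional ranks in (0,1).
#' @return object of class \code{ranked_sample} with fields \code{values},
#'   \code{ranks}, \code{weights}, \code{quintile}, \code{score}.
#' @export
ranked_sample <- function(values, scores = NULL, weights = NULL, ranks = NULL) {
  n <- length(values)
  if (n == 0L) stop("empty sample")
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(ranks)) {
    if (is.null(scores)) stop("supply scores or ranks")
    ranks <- fractional_ranks(scores, weights)
  }
  if (length(ranks) != n || length(weights) != n)
    stop("length mismatch among values, ranks, weights")
  structure(
    list(values = as.numeric(values), ranks = ranks, weights = weights,
         quintile = assign_quintiles(ranks),
         score = if (is.null(scores)) ranks else as.numeric(scores)),
    class = "ranked_sample"
  )
}

#' Per-patient wealth audit table
#'
#' @param survey an \code{exit_survey}.
#' @return data.frame of patient_id, score, rank, quintile (1 = poorest).
#' @export
wealth_audit <- function(survey) {
  sc <- wealth_scores(survey)
  r <- fractional_ranks(sc)
  data.frame(patient_id = survey$records$patient_id,
             score = sc, rank = r, quintile = assign_quintiles(r))
}
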