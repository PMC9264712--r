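# Cost pipeline: currency conversion, one-way vs round-trip convention,
# per-outcome summaries, component-share decomposition, and the stratified
# equity tables.

#' Analysis configuration
#'
#' @param convention journey convention for travel time and transport cost:
#'   \code{"one_way"} (default, avoids overestimation) or
#'   \code{"round_trip"} (doubles both, for robustness reporting).
#' @param currency_rate_tzs_per_usd TZS per USD (survey-period rate, 1600).
#' @param restrict_public_only analyse public facilities only.
#' @param strata stratifiers to run in \code{\link{run_analysis}}.
#' @return list of class \code{analysis_config}.
#' @export
analysis_config <- function(convention = c("one_way", "round_trip"),
                            currency_rate_tzs_per_usd = 1600,
                            restrict_public_only = FALSE,
                            strata = c("ses_quintile_extremes", "residence",
                                       "ownership", "level", "service")) {
  convention <- match.arg(convention)
  if (currency_rate_tzs_per_usd <= 0) stop("currency rate must be positive")
  structure(list(convention = convention,
                 currency_rate_tzs_per_usd = currency_rate_tzs_per_usd,
                 restrict_public_only = restrict_public_only,
                 strata = strata),
            class = "analysis_config")
}

#' Convert TZS amounts to USD
#'
#' @param amount_tzs nonnegative amount(s) in Tanzanian shillings.
#' @param rate positive TZS-per-USD exchange rate.
#' @return amount in USD at full precision (round only for reporting).
#' @export
convert_currency <- function(amount_tzs, rate = 1600) {
  if (rate <= 0) stop("rate must be positive")
  if (any(!is.na(amount_tzs) & amount_tzs < 0)) stop("negative amount")
  amount_tzs / rate
}

#' Apply the journey convention to a survey
#'
#' Travel time and transport cost are recorded one-way at ingest. Under the
#' round-trip convention both are doubled (the return journey); waiting,
#' consultation and medical cost never change. Doubling an already
#' round-trip survey is rejected.
#'
#' @param survey an \code{exit_survey}.
#' @param convention \code{"one_way"} (identity) or \code{"round_trip"}.
#' @return the adjusted \code{exit_survey}, tagged with its convention.
#' @export
apply_convention <- function(survey, convention = c("one_way", "round_trip")) {
  convention <- match.arg(convention)
  current <- if (is.null(survey$convention)) "one_way" else survey$convention
  if (convention == "one_way") return(survey)
  if (current == "round_trip")
    stop("survey already holds round-trip values; refusing to double again")
  survey$records$travel_time_min <- 2 * survey$records$travel_time_min
  survey$records$transport_cost_tzs <- 2 * survey$records$transport_cost_tzs
  survey$convention <- "round_trip"
  survey
}

# Outcome extraction: numeric vector (NA = missing), costs in USD, binary
# payment/mode indicators derived on the fly.
outcome_vector <- function(survey, outcome,
                           rate = survey$currency_rate_tzs_per_usd) {
  rec <- survey$records
  switch(outcome,
    travel_time       = rec$travel_time_min,
    waiting_time      = rec$waiting_time_min,
    consultation_time = rec$consultation_time_min,
    transport_cost    = convert_currency(rec$transport_cost_tzs, rate),
    medical_cost      = convert_currency(rec$medical_cost_tzs, rate),
    paid_transport    = as.numeric(rec$transport_cost_tzs > 0),
    paid_medical      = as.numeric(rec$medical_cost_tzs > 0),
    mode_foot         = as.numeric(rec$travel_mode == "foot"),
    mode_car          = as.numeric(rec$travel_mode == "car"),
    mode_motorbike_bicycle = as.numeric(rec$travel_mode == "motorbike_bicycle"),
    stop("unrecognised outcome '", outcome, "'")
  )
}

# column whose missingness defines the complete-case subset of an outcome
outcome_base_column <- function(outcome) {
  switch(outcome,
    travel_time = "travel_time_min",
    waiting_time = "waiting_time_min",
    consultation_time = "consultation_time_min",
    transport_cost = , paid_transport = "transport_cost_tzs",
    medical_cost = , paid_medical = "medical_cost_tzs",
    mode_foot = , mode_car = , mode_motorbike_bicycle = "travel_mode",
    stop("unrecognised outcome '", outcome, "'"))
}

complete_case_outcome <- function(survey, outcome) {
  keep <- !is.na(survey$records[[outcome_base_column(outcome)]])
  if (!any(keep)) stop("no observations for variable '", outcome, "'")
  subset_survey(survey, keep)
}

#' Summary statistics for one outcome
#'
#' Unweighted mean, median and share of nonzero values on the per-outcome
#' complete-case subset (heavily zero-inflated costs make the median zero
#' and the nonzero share the informative quantity).
#'
#' @param survey an \code{exit_survey}.
#' @param outcome outcome name (see \code{\link{outcome_columns}}; also
#'   \code{paid_transport}, \code{paid_medical}, \code{mode_*} indicators).
#' @param config an \code{\link{analysis_config}}; its convention is applied.
#' @return list with \code{n}, \code{mean}, \code{median},
#'   \code{pct_nonzero} (percent).
#' @export
cost_summary <- function(survey, outcome, config = analysis_config()) {
  survey <- apply_convention(survey, config$convention)
  if (config$restrict_public_only) survey <- restrict_public(survey)
  cc <- complete_case_outcome(survey, outcome)
  y <- outcome_vector(cc, outcome, config$currency_rate_tzs_per_usd)
  list(n = length(y), mean = mean(y), median = stats::median(y),
       pct_nonzero = 100 * mean(y > 0))
}

#' Decompose a cost total into component shares
#'
#' Given per-component means (time components in minutes, or direct-cost
#' components in USD -- decompose the two families separately), applies the
#' journey convention (doubling travel components only) and returns each
#' component's share of the total.
#'
#' @param component_means named nonnegative vector, e.g.
#'   \code{c(travel_time = 30.1, waiting_time = 46.7, consultation_time = 12.9)}
#'   or \code{c(transport_cost = 0.41, medical_cost = 0.23)}.
#' @param convention \code{"one_way"} or \code{"round_trip"}.
#' @return object of class \code{cost_share_breakdown}: \code{convention},
#'   adjusted \code{components}, \code{total}, \code{shares} (sum to 1).
#' @export
share_decomposition <- function(component_means,
                                convention = c("one_way", "round_trip")) {
  convention <- match.arg(convention)
  if (is.null(names(component_means)) || any(names(component_means) == ""))
    stop("component means must be named")
  if (any(component_means < 0)) stop("negative component mean")
  comp <- component_means
  travel <- intersect(names(comp), c("travel_time", "transport_cost"))
  if (convention == "round_trip") comp[travel] <- 2 * comp[travel]
  total <- sum(comp)
  if (total == 0) stop("zero total: shares undefined")
  structure(list(convention = convention, components = comp,
                 total = total, shares = comp / total),
            class = "cost_share_breakdown")
}

#' @export
print.cost_share_breakdown <- function(x, ...) {
  cat("Cost shares (", x$convention, "), total = ",
      format(x$total, digits = 4), ":\n", sep = "")
  for (nm in names(x$shares))
    cat(sprintf("  %-18s %8.2f  (%.1f%%)\n", nm, x$components[[nm]],
                100 * x$shares[[nm]]))
  invisible(x)
}

#' Restrict a survey to public facilities
#'
#' Robustness restriction: public facilities are meant to offer free
#' maternal and child health services.
#'
#' @param survey an \code{exit_survey}.
#' @return the public-facility subset.
#' @export
restrict_public <- function(survey) {
  keep <- !is.na(survey$records$ownership) & survey$records$ownership == "public"
  if (!any(keep)) stop("no public-facility records")
  subset_survey(survey, keep)
}

#' Stratified equity analysis for one outcome
#'
#' For the wealth dimension (\code{ses_quintile_extremes}) and residence,
#' returns the full equity panel: overall mean, gap between extreme groups
#' (poorest - least poor, or rural - urban) with a Welch t-test, the equity
#' ratio, and the wealth-rank concentration index with its
#' convenient-regression standard error. For ownership, level and service,
#' returns per-group means Welch-tested against the conventional reference
#' group (public; hospital; ANC).
#'
#' Wealth scores are computed on the full sample; fractional ranks and
#' quintiles are recomputed within each outcome's complete-case subset so
#' the mean-rank identity holds in the estimation sample.
#'
#' @param survey an \code{exit_survey}.
#' @param outcome outcome name.
#' @param stratifier one of \code{"ses_quintile_extremes"},
#'   \code{"residence"}, \code{"ownership"}, \code{"level"}, \code{"service"}.
#' @param config an \code{\link{analysis_config}}.
#' @return data.frame; one row for the two equity dimensions, one row per
#'   group for the facility/service dimensions.
#' @export
stratified_equity_table <- function(survey, outcome,
                                    stratifier = c("ses_quintile_extremes",
                                                   "residence", "ownership",
                                                   "level", "service"),
                                    config = analysis_config()) {
  stratifier <- match.arg(stratifier)
  survey <- apply_convention(survey, config$convention)
  if (config$restrict_public_only) survey <- restrict_public(survey)
  score_all <- wealth_scores(survey)
  keep <- !is.na(survey$records[[outcome_base_column(outcome)]])
  if (!any(keep)) stop("no observations for variable '", outcome, "'")
  cc <- subset_survey(survey, keep)
  y <- outcome_vector(cc, outcome, config$currency_rate_tzs_per_usd)
  n <- length(y)

  if (stratifier == "ses_quintile_extremes") {
    rs <- ranked_sample(y, scores = score_all[keep])
    g <- equity_gap(y[rs$quintile == 1L], y[rs$quintile == 5L])
    ci <- ci_inference(rs)
    return(data.frame(
      outcome = outcome, stratifier = stratifier, n = n, mean = mean(y),
      gap = g$gap, gap_se = g$se, gap_p = g$p, gap_stars = stars(g$p),
      ratio = equity_ratio(mean(y[rs$quintile == 1L]),
                           mean(y[rs$quintile == 5L])),
      ci = ci$ci, ci_se = ci$se, ci_p = ci$p, ci_stars = stars(ci$p),
      stringsAsFactors = FALSE))
  }
  if (stratifier == "residence") {
    res <- cc$records$residence
    if (length(unique(res[!is.na(res)])) < 2L)
      stop("residence has a single group: cell '",
           unique(res[!is.na(res)])[1], "' only")
    g <- equity_gap(y[res == "rural"], y[res == "urban"])
    rs <- ranked_sample(y, scores = score_all[keep])
    ci <- ci_inference(rs)
    return(data.frame(
      outcome = outcome, stratifier = stratifier, n = n, mean = mean(y),
      gap = g$gap, gap_se = g$se, gap_p = g$p, gap_stars = stars(g$p),
      ratio = equity_ratio(mean(y[res == "rural"]), mean(y[res == "urban"])),
      ci = ci$ci, ci_se = ci$se, ci_p = ci$p, ci_stars = stars(ci$p),
      stringsAsFactors = FALSE))
  }

  groups <- cc$records[[stratifier]]
  lev <- ENUM_LEVELS[[stratifier]]
  present <- lev[lev %in% groups]
  if (length(present) < 2L)
    stop(stratifier, " has a single group for all records: cell '",
         present[1], "'")
  ref <- switch(stratifier, ownership = "public", level = "hospital",
                service = "anc")
  if (!ref %in% present) stop("reference cell '", ref, "' is empty")
  rows <- lapply(present, function(gname) {
    yg <- y[groups == gname]
    if (length(yg) == 0L) stop("empty cell '", gname, "'")
    if (gname == ref)
      return(data.frame(outcome = outcome, stratifier = stratifier,
                        group = gname, n = length(yg), mean = mean(yg),
                        p = NA_real_, stars = "(ref)",
                        stringsAsFactors = FALSE))
    g <- equity_gap(yg, y[groups == ref])
    data.frame(outcome = outcome, stratifier = stratifier, group = gname,
               n = length(yg), mean = mean(yg), p = g$p, stars = stars(g$p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Equity table across outcomes (wealth and residence dimensions)
#'
#' Runs \code{\link{stratified_equity_table}} for each outcome over the
#' wealth-quintile and residence dimensions and binds the rows -- the layout
#' of the headline direct/indirect cost table. Mode-specific travel rows are
#' obtained by filtering on travel mode before calling this.
#'
#' @param survey an \code{exit_survey}.
#' @param outcomes character vector of outcome names.
#' @param config an \code{\link{analysis_config}}.
#' @return data.frame, two rows (ses, residence) per outcome.
#' @export
equity_table <- function(survey,
                         outcomes = c("travel_time", "waiting_time",
                                      "consultation_time", "transport_cost",
                                      "paid_medical", "medical_cost"),
                         config = analysis_config()) {
  do.call(rbind, lapply(outcomes, function(oc) rbind(
    stratified_equity_table(survey, oc, "ses_quintile_extremes", config),
    stratified_equity_table(survey, oc, "residence", config))))
}

#' Filter a survey by travel mode
#'
#' @param survey an \code{exit_survey}.
#' @param mode one of \code{"foot"}, \code{"car"}, \code{"motorbike_bicycle"}.
#' @return the subset using that mode.
#' @export
filter_mode <- function(survey, mode) {
  mode <- match.arg(mode, ENUM_LEVELS$travel_mode)
  keep <- !is.na(survey$records$travel_mode) & survey$records$travel_mode == mode
  if (!any(keep)) stop("no records with travel mode '", mode, "'")
  subset_survey(survey, keep)
}
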