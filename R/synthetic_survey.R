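# Synthetic exit-interview generator. Latent household wealth drives asset
# ownership, travel-mode choice, residence, and linear-in-rank expected
# times/costs, so every outcome has a known closed-form concentration index
# and the whole pipeline can be validated without any external data.

#' Default per-outcome generating parameters
#'
#' Expected value is linear in the true fractional wealth rank R:
#' E[y|R] = a + bR, so the large-sample concentration index is
#' \code{\link{closed_form_ci}(a, b)}. Times are gamma-distributed
#' (dispersion = shape), payment amounts lognormal (dispersion = sdlog) and
#' zero-inflated through the payment layer. Defaults are tuned to the
#' headline magnitudes of Tanzanian maternal/child-care exit interviews:
#' mean travel 30, waiting 46.7, consultation 12.9 minutes; transport and
#' medical amounts averaging 1.9 and 2.1 USD among payers.
#' @keywords internal
default_outcome_params <- function() {
  list(
    travel_time      = list(a = 40,   b = -20,   family = "gamma",
                            dispersion = 2),
    waiting_time     = list(a = 54.5, b = -15.6, family = "gamma",
                            dispersion = 1.5),
    consultation_time = list(a = 12.9, b = 0,    family = "gamma",
                            dispersion = 4),
    transport_amount = list(a = 1600, b = 2960,  family = "lognormal",
                            dispersion = 1),
    medical_amount   = list(a = 800,  b = 2534,  family = "lognormal",
                            dispersion = 1)
  )
}

#' Generator configuration
#'
#' Parameters of the synthetic exit-interview survey. Defaults emulate the
#' study conditions of the Tanzanian maternal and child health survey the
#' pipeline targets: 1407 patients across 150 facilities (at most 10 per
#' facility), 82\% public facilities, 82.8\% rural residents, 42 binary
#' asset indicators, ~71\% travelling on foot with a pro-rich motorised
#' share, 21.3\% paying for transport and 17.8\% for care, and per-outcome
#' missingness matching the observed item nonresponse.
#'
#' @param n_patients,n_facilities sample sizes; patients are capped at 10
#'   per facility, so \code{n_patients <= 10 * n_facilities}.
#' @param public_share share of facilities publicly owned.
#' @param level_shares facility-level mix (hospital, health centre,
#'   dispensary).
#' @param rural_share target share of rural residents; rurality is
#'   negatively related to latent wealth (logistic slope
#'   \code{rural_wealth_slope}).
#' @param rural_wealth_slope slope of latent wealth in the rural logit.
#' @param n_assets,asset_loadings number of binary asset indicators and
#'   their loadings on latent wealth; intercepts are spread over
#'   [-1.5, 1.5] so prevalences vary.
#' @param outcomes per-outcome lists (a, b, family, dispersion); see
#'   \code{\link{default_outcome_params}}.
#' @param pay_prob_transport overall share paying for transport; applied to
#'   non-foot travellers (foot travel costs nothing).
#' @param pay_prob_medical overall share paying for care.
#' @param medical_pay_rank_slope logistic slope of the medical payment
#'   probability in the wealth rank (0 = rank-independent; the closed-form
#'   index for medical cost assumes 0).
#' @param mode_logits multinomial-logit coefficients (intercept, rank slope)
#'   for car and motorbike/bicycle vs the foot baseline; defaults are
#'   calibrated to 71/8.5/20.5\% population shares.
#' @param missing_rates per-outcome missingness (MCAR).
#' @param service_shares,insurance_share visit-type mix and household
#'   insurance coverage.
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(n_patients = 1407,
                             n_facilities = 150,
                             public_share = 0.82,
                             level_shares = c(hospital = 12, health_centre = 32,
                                              dispensary = 106) / 150,
                             rural_share = 0.828,
                             rural_wealth_slope = -1,
                             n_assets = 42,
                             asset_loadings = rep(1, n_assets),
                             outcomes = default_outcome_params(),
                             pay_prob_transport = 0.213,
                             pay_prob_medical = 0.178,
                             medical_pay_rank_slope = 0.95,
                             mode_logits = list(
                               car = c(intercept = -3.8441, slope = 3),
                               motorbike_bicycle = c(intercept = -2.0171,
                                                     slope = 1.5)),
                             missing_rates = c(travel_time = 0.1876,
                                               waiting_time = 0.0092,
                                               consultation_time = 0.0235,
                                               transport_amount = 0.0768,
                                               medical_amount = 0.0057),
                             service_shares = c(anc = 334, pnc = 380,
                                                vaccination = 136,
                                                checkup = 557) / 1407,
                             insurance_share = 0.089,
                             seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  cfg <- list(n_patients = n_patients, n_facilities = n_facilities,
              public_share = public_share, level_shares = level_shares,
              rural_share = rural_share,
              rural_wealth_slope = rural_wealth_slope,
              n_assets = n_assets, asset_loadings = asset_loadings,
              outcomes = outcomes, pay_prob_transport = pay_prob_transport,
              pay_prob_medical = pay_prob_medical,
              medical_pay_rank_slope = medical_pay_rank_slope,
              mode_logits = mode_logits, missing_rates = missing_rates,
              service_shares = service_shares / sum(service_shares),
              insurance_share = insurance_share, seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1, cfg$n_facilities >= 1)
  if (cfg$n_patients > 10 * cfg$n_facilities)
    stop("n_patients exceeds 10 patients per facility capacity")
  probs <- c(cfg$public_share, cfg$rural_share, cfg$pay_prob_transport,
             cfg$pay_prob_medical, cfg$level_shares, cfg$missing_rates,
             cfg$insurance_share)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (length(cfg$asset_loadings) != cfg$n_assets)
    stop("asset_loadings length must equal n_assets")
  for (nm in names(cfg$outcomes)) {
    p <- cfg$outcomes[[nm]]
    if (p$a <= 0 || p$a + p$b <= 0)
      stop("outcome '", nm, "': a + b*R must stay positive on (0,1)")
    if (p$dispersion <= 0) stop("outcome '", nm, "': dispersion must be > 0")
    if (!p$family %in% c("gamma", "lognormal"))
      stop("outcome '", nm, "': unknown noise family '", p$family, "'")
  }
  invisible(TRUE)
}

#' Large-sample concentration index of a linear-in-rank outcome
#'
#' For an outcome with conditional mean \eqn{E[y|R] = a + bR} over a
#' uniform fractional rank R, the concentration index
#' \eqn{2\,b\,var(R)/\mu} converges to \eqn{b / (6a + 3b)} as
#' \eqn{var(R) \to 1/12} and \eqn{\mu = a + b/2}. This is the analytic
#' target the pipeline's estimate is validated against.
#'
#' @param a intercept (> 0, outcome units).
#' @param b slope in the fractional rank (negative = pro-poor burden).
#' @return the limiting concentration index.
#' @export
closed_form_ci <- function(a, b) {
  if (a + b / 2 <= 0) stop("mean a + b/2 must be positive")
  b / (6 * a + 3 * b)
}

# draw from the configured noise family with mean m
draw_noise <- function(n, m, family, dispersion) {
  if (family == "gamma") {
    stats::rgamma(n, shape = dispersion, rate = dispersion / m)
  } else {
    stats::rlnorm(n, meanlog = log(m) - dispersion^2 / 2, sdlog = dispersion)
  }
}

# intercept q0 such that mean over R~U(0,1) of plogis(q0 + s(R-1/2)) = p
calibrate_logit_intercept <- function(p, s) {
  if (s == 0) return(stats::qlogis(p))
  grid <- seq(0.0005, 0.9995, length.out = 2000)
  stats::uniroot(function(q0) mean(stats::plogis(q0 + s * (grid - 0.5))) - p,
                 c(-20, 20))$root
}

#' Generate a synthetic exit-interview survey
#'
#' Draws latent wealth w ~ N(0,1) per household; binary assets with
#' probability logistic(alpha_j + lambda_j w); the true fractional rank R
#' from w; each outcome from its configured family with mean a + bR;
#' travel mode from a rank-dependent multinomial logit with transport cost
#' forced to zero on foot; payment indicators thin the cost amounts; and
#' facility ownership/level, residence, service and insurance by the
#' configured shares, with at most 10 patients allocated per facility.
#' Fully reproducible for a fixed seed.
#'
#' @param config a \code{\link{generator_config}}.
#' @return an \code{\link{exit_survey}} with a \code{$truth} element: the
#'   latent wealth, true ranks, and per-outcome (a, b, closed-form CI).
#' @export
generate_survey <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_patients

  w <- stats::rnorm(n)
  R <- (rank(w) - 0.5) / n

  alpha <- seq(-1.5, 1.5, length.out = config$n_assets)
  assets <- matrix(0L, n, config$n_assets)
  for (j in seq_len(config$n_assets))
    assets[, j] <- stats::rbinom(n, 1L,
      stats::plogis(alpha[j] + config$asset_loadings[j] * w))
  colnames(assets) <- paste0("asset_", sprintf("item%02d", seq_len(config$n_assets)))

  # facilities: ownership and level assigned by share, patients <= 10 each
  n_fac <- config$n_facilities
  fac_ids <- sprintf("F%03d", seq_len(n_fac))
  n_pub <- round(config$public_share * n_fac)
  fac_own <- sample(c(rep("public", n_pub),
                      sample(c("fbo", "private"), n_fac - n_pub,
                             replace = TRUE)))
  n_lev <- round(config$level_shares * n_fac)
  n_lev[3] <- n_fac - sum(n_lev[1:2])
  fac_lev <- sample(rep(c("hospital", "health_centre", "dispensary"), n_lev))
  slot_pool <- rep(seq_len(n_fac), each = 10L)
  fac_of <- sample(slot_pool, n)

  rural_q0 <- stats::uniroot(function(q0)
    stats::integrate(function(x) stats::plogis(q0 + config$rural_wealth_slope * x) *
                       stats::dnorm(x), -8, 8)$value - config$rural_share,
    c(-20, 20))$root
  rural <- stats::rbinom(n, 1L, stats::plogis(rural_q0 + config$rural_wealth_slope * w))

  eta_car <- config$mode_logits$car["intercept"] +
    config$mode_logits$car["slope"] * R
  eta_mb <- config$mode_logits$motorbike_bicycle["intercept"] +
    config$mode_logits$motorbike_bicycle["slope"] * R
  denom <- 1 + exp(eta_car) + exp(eta_mb)
  u <- stats::runif(n)
  p_car <- exp(eta_car) / denom
  p_mb <- exp(eta_mb) / denom
  mode <- ifelse(u < p_car, "car",
                 ifelse(u < p_car + p_mb, "motorbike_bicycle", "foot"))

  oc <- config$outcomes
  mean_of <- function(p) p$a + p$b * R
  travel <- draw_noise(n, mean_of(oc$travel_time), oc$travel_time$family,
                       oc$travel_time$dispersion)
  waiting <- draw_noise(n, mean_of(oc$waiting_time), oc$waiting_time$family,
                        oc$waiting_time$dispersion)
  consult <- draw_noise(n, mean_of(oc$consultation_time),
                        oc$consultation_time$family,
                        oc$consultation_time$dispersion)

  # transport: only non-foot travellers can pay; thin so the overall paying
  # share matches the configured target
  nonfoot <- mode != "foot"
  p_pay_nf <- min(1, config$pay_prob_transport / max(mean(nonfoot), 1e-12))
  pays_transport <- nonfoot & stats::rbinom(n, 1L, p_pay_nf) == 1L
  transport <- numeric(n)
  if (any(pays_transport))
    transport[pays_transport] <- draw_noise(sum(pays_transport),
      mean_of(oc$transport_amount)[pays_transport],
      oc$transport_amount$family, oc$transport_amount$dispersion)

  med_q0 <- calibrate_logit_intercept(config$pay_prob_medical,
                                      config$medical_pay_rank_slope)
  pays_medical <- stats::rbinom(n, 1L,
    stats::plogis(med_q0 + config$medical_pay_rank_slope * (R - 0.5))) == 1L
  medical <- numeric(n)
  if (any(pays_medical))
    medical[pays_medical] <- draw_noise(sum(pays_medical),
      mean_of(oc$medical_amount)[pays_medical],
      oc$medical_amount$family, oc$medical_amount$dispersion)

  service <- sample(names(config$service_shares), n, replace = TRUE,
                    prob = config$service_shares)
  insurance <- stats::rbinom(n, 1L, config$insurance_share) == 1L

  rec <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    facility_id = fac_ids[fac_of],
    ownership = fac_own[fac_of],
    level = fac_lev[fac_of],
    service = service,
    residence = ifelse(rural == 1L, "rural", "urban"),
    travel_mode = mode,
    travel_time_min = travel,
    waiting_time_min = waiting,
    consultation_time_min = consult,
    transport_cost_tzs = transport,
    medical_cost_tzs = medical,
    insurance = insurance,
    stringsAsFactors = FALSE
  )
  rec <- cbind(rec, as.data.frame(assets))

  # per-outcome MCAR item nonresponse
  miss_col <- c(travel_time = "travel_time_min",
                waiting_time = "waiting_time_min",
                consultation_time = "consultation_time_min",
                transport_amount = "transport_cost_tzs",
                medical_amount = "medical_cost_tzs")
  for (nm in names(config$missing_rates)) {
    rate <- config$missing_rates[[nm]]
    if (rate > 0)
      rec[[miss_col[[nm]]]][stats::runif(n) < rate] <- NA
  }

  survey <- exit_survey(rec, asset_names = colnames(assets))
  survey$truth <- list(
    latent_wealth = w, true_rank = R, seed = config$seed,
    outcome_params = do.call(rbind, lapply(names(oc), function(nm)
      data.frame(outcome = nm, a = oc[[nm]]$a, b = oc[[nm]]$b,
                 ci_inf = closed_form_ci(oc[[nm]]$a, oc[[nm]]$b),
                 stringsAsFactors = FALSE)))
  )
  survey
}

#' Write the ground-truth sidecar of a synthetic survey
#'
#' Two CSVs for test harnesses: per-patient latent wealth and true rank,
#' and the per-outcome (a, b, closed-form CI) table.
#'
#' @param survey a survey from \code{\link{generate_survey}}.
#' @param path_patients,path_params output CSV paths.
#' @export
write_ground_truth <- function(survey, path_patients, path_params) {
  if (is.null(survey$truth)) stop("survey carries no ground truth")
  utils::write.csv(data.frame(patient_id = survey$records$patient_id,
                              latent_wealth = survey$truth$latent_wealth,
                              true_rank = survey$truth$true_rank),
                   path_patients, row.names = FALSE)
  utils::write.csv(survey$truth$outcome_params, path_params, row.names = FALSE)
  invisible(NULL)
}
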