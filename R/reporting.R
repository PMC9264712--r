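# End-to-end orchestration: ingest (or simulate) -> wealth index -> equity
# tables -> CSV outputs plus a reproducibility manifest.

#' Run the full cost-equity analysis
#'
#' Executes ingest (or synthetic generation), the wealth index, the
#' stratified equity analysis and the share decompositions, writing
#' machine-readable CSV tables and a JSON run manifest to \code{out_dir}.
#' Progress is logged to standard error; tables go only to files.
#'
#' Outputs: \code{table2.csv} (equity by wealth extremes and residence,
#' including mode shares and mode-specific travel rows), \code{table3.csv}
#' (facility ownership and level), \code{table4.csv} (service types),
#' \code{shares.csv} (time and direct-cost component shares under both
#' journey conventions), \code{wealth_audit.csv} (per-patient score, rank,
#' quintile) and \code{manifest.json}.
#'
#' @param input path to a canonical survey CSV, an \code{exit_survey}, or a
#'   \code{\link{generator_config}} (synthetic run).
#' @param config an \code{\link{analysis_config}}.
#' @param out_dir output directory, created if needed.
#' @return the manifest, invisibly.
#' @export
run_analysis <- function(input, config = analysis_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[equicost] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  input_id <- NULL
  survey <- stage("ingest", {
    if (inherits(input, "generator_config")) {
      input_id <- paste0("synthetic(seed=", input$seed, ")")
      generate_survey(input)
    } else if (inherits(input, "exit_survey")) {
      input_id <- "in-memory survey"
      input
    } else {
      input_id <- paste0("md5:", unname(tools::md5sum(input)))
      load_exit_interviews(input)
    }
  })
  n_raw <- n_records(survey)
  survey <- stage("convention", apply_convention(survey, config$convention))
  if (config$restrict_public_only)
    survey <- stage("restrict_public", restrict_public(survey))
  n_used <- n_records(survey)
  message("[equicost] records: ", n_raw, " loaded, ", n_used, " analysed")

  # config with convention already applied upstream of the table calls
  cfg_applied <- config
  cfg_applied$convention <- "one_way"
  cfg_applied$restrict_public_only <- FALSE

  audit <- stage("wealth_index", wealth_audit(survey))

  t2 <- stage("equity_table", {
    rows <- list(
      equity_table(survey, c("mode_foot", "mode_car",
                             "mode_motorbike_bicycle", "travel_time"),
                   cfg_applied))
    for (m in c("foot", "car", "motorbike_bicycle")) {
      sub <- filter_mode(survey, m)
      r <- equity_table(sub, "travel_time", cfg_applied)
      r$outcome <- paste0("travel_time_", m)
      rows <- c(rows, list(r))
    }
    rows <- c(rows, list(
      equity_table(survey, c("waiting_time", "consultation_time",
                             "transport_cost", "paid_transport"),
                   cfg_applied)))
    for (m in c("car", "motorbike_bicycle")) {
      sub <- filter_mode(survey, m)
      # transport cost among users of the mode (all users, zeros included)
      r <- equity_table(sub, "transport_cost", cfg_applied)
      r$outcome <- paste0("transport_cost_", m, "_all")
      rows <- c(rows, list(r))
      payers <- subset_survey(sub, !is.na(sub$records$transport_cost_tzs) &
                                     sub$records$transport_cost_tzs > 0)
      if (n_records(payers) >= 10) {
        rp <- equity_table(payers, "transport_cost", cfg_applied)
        rp$outcome <- paste0("transport_cost_", m, "_payers")
        rows <- c(rows, list(rp))
      }
      rows
    }
    rows <- c(rows, list(
      equity_table(survey, c("paid_medical", "medical_cost"), cfg_applied)))
    do.call(rbind, rows)
  })

  # after a public-only restriction the ownership dimension is degenerate
  fac_strata <- c(if (length(unique(survey$records$ownership)) > 1) "ownership",
                  "level")
  t3 <- stage("facility_table", do.call(rbind, lapply(
    c("travel_time", "waiting_time", "consultation_time",
      "transport_cost", "paid_medical", "medical_cost"),
    function(oc) do.call(rbind, lapply(fac_strata, function(st)
      stratified_equity_table(survey, oc, st, cfg_applied))))))

  t4 <- stage("service_table", do.call(rbind, lapply(
    c("waiting_time", "consultation_time", "paid_medical", "medical_cost"),
    function(oc) stratified_equity_table(survey, oc, "service", cfg_applied))))

  sh <- stage("shares", {
    tm <- vapply(c("travel_time", "waiting_time", "consultation_time"),
                 function(oc) cost_summary(survey, oc, cfg_applied)$mean,
                 numeric(1))
    dm <- vapply(c("transport_cost", "medical_cost"),
                 function(oc) cost_summary(survey, oc, cfg_applied)$mean,
                 numeric(1))
    rows <- list()
    for (conv in c("one_way", "round_trip")) {
      for (fam in c("time", "direct")) {
        comp <- if (fam == "time") tm else dm
        br <- share_decomposition(comp, conv)
        rows[[paste(fam, conv)]] <- data.frame(
          family = fam, convention = conv, component = names(br$shares),
          mean = unname(br$components), total = br$total,
          share_pct = 100 * unname(br$shares), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  outputs <- list(table2 = t2, table3 = t3, table4 = t4, shares = sh,
                  wealth_audit = audit)
  for (nm in names(outputs))
    utils::write.csv(outputs[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "")

  manifest <- list(
    input = input_id,
    config = unclass(config),
    version = as.character(utils::packageVersion("equicost")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = if (inherits(input, "generator_config")) input$seed else NULL,
    records_loaded = n_raw, records_analysed = n_used,
    outputs = lapply(outputs, nrow)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message("[equicost] wrote ", length(outputs) + 1, " files to ", out_dir)
  invisible(manifest)
}

#' Headline replication against the deposited study dataset
#'
#' Runs the pipeline on a local copy of the study's deposited exit-interview
#' data (not shipped with the package; place the canonical CSV at
#' \code{path}) and returns the headline quantities: mean one-way travel
#' time, its wealth concentration index, the share paying for care, and the
#' share travelling on foot.
#'
#' @param path canonical survey CSV of the deposited dataset.
#' @param schema optional column-mapping schema (see
#'   \code{\link{read_schema}}) when the deposit keeps its original headers.
#' @return list with \code{travel_time_mean}, \code{travel_time_ci},
#'   \code{pct_paying_medical}, \code{pct_on_foot}, \code{n}.
#' @export
replicate_study <- function(path, schema = NULL) {
  if (!file.exists(path))
    stop("study dataset not found at '", path,
         "': download the deposit and convert it to the canonical CSV")
  survey <- load_exit_interviews(path, schema)
  cfg <- analysis_config()
  ses <- stratified_equity_table(survey, "travel_time",
                                 "ses_quintile_extremes", cfg)
  list(travel_time_mean = cost_summary(survey, "travel_time", cfg)$mean,
       travel_time_ci = ses$ci,
       pct_paying_medical = cost_summary(survey, "paid_medical", cfg)$mean * 100,
       pct_on_foot = cost_summary(survey, "mode_foot", cfg)$mean * 100,
       n = n_records(survey))
}
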