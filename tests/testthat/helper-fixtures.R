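# Small deterministic fixtures built in code.

# canonical records: n rows, k binary asset columns, no missingness
toy_records <- function(n = 6, k = 3) {
  set.seed(42)
  rec <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    facility_id = rep(c("F1", "F2"), length.out = n),
    ownership = rep(c("public", "public", "fbo"), length.out = n),
    level = rep(c("dispensary", "health_centre", "hospital"), length.out = n),
    service = rep(c("anc", "pnc", "vaccination", "checkup"), length.out = n),
    residence = rep(c("rural", "urban"), length.out = n),
    travel_mode = rep(c("foot", "car", "motorbike_bicycle"), length.out = n),
    travel_time_min = seq(10, by = 5, length.out = n),
    waiting_time_min = seq(20, by = 3, length.out = n),
    consultation_time_min = rep(10, n),
    transport_cost_tzs = rep(c(0, 800), length.out = n),
    medical_cost_tzs = rep(c(0, 0, 400), length.out = n),
    insurance = rep(c(TRUE, FALSE), length.out = n),
    stringsAsFactors = FALSE
  )
  for (j in seq_len(k))
    rec[[paste0("asset_a", j)]] <- rep(c(0, 1), length.out = n + j - 1)[j:(n + j - 1)]
  rec
}

toy_survey <- function(n = 6, k = 3) exit_survey(toy_records(n, k))

write_fixture_csv <- function(records, path = tempfile(fileext = ".csv")) {
  write.csv(records, path, row.names = FALSE, na = "")
  path
}

# survey with a prescribed travel-time vector, assets from a wealth gradient
survey_with_travel <- function(travel) {
  n <- length(travel)
  rec <- toy_records(n, 3)
  rec$travel_time_min <- travel
  exit_survey(rec)
}
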