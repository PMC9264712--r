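# Exit-interview survey data: canonical schema, ingest, validation,
# complete-case subsetting.

#' Canonical exit-interview columns
#'
#' Non-asset columns every canonical survey table carries. Asset indicator
#' columns are prefixed \code{asset_} and their number varies by dataset.
#' @keywords internal
CANONICAL_COLUMNS <- c(
  "patient_id", "facility_id", "ownership", "level", "service", "residence",
  "travel_mode", "travel_time_min", "waiting_time_min",
  "consultation_time_min", "transport_cost_tzs", "medical_cost_tzs",
  "insurance"
)

ENUM_LEVELS <- list(
  ownership   = c("public", "fbo", "private"),
  level       = c("hospital", "health_centre", "dispensary"),
  service     = c("anc", "pnc", "vaccination", "checkup"),
  residence   = c("rural", "urban"),
  travel_mode = c("foot", "car", "motorbike_bicycle")
)

NUMERIC_COLUMNS <- c(
  "travel_time_min", "waiting_time_min", "consultation_time_min",
  "transport_cost_tzs", "medical_cost_tzs"
)

#' Recognised outcome variables
#'
#' Maps short outcome names to the canonical column holding them. Binary
#' "probability of paying" outcomes are derived from the cost columns at
#' analysis time, not stored.
#' @export
outcome_columns <- function() {
  c(travel_time       = "travel_time_min",
    waiting_time      = "waiting_time_min",
    consultation_time = "consultation_time_min",
    transport_cost    = "transport_cost_tzs",
    medical_cost      = "medical_cost_tzs")
}

#' Construct an exit-interview survey object
#'
#' Bundles a validated record table with its asset-indicator labels and the
#' TZS-per-USD conversion rate. One row is one interviewed patient.
#'
#' @param records data.frame holding the canonical columns plus one
#'   \code{asset_*} column per household indicator.
#' @param asset_names character vector of indicator labels; defaults to the
#'   \code{asset_*} column names found in \code{records}.
#' @param currency_rate_tzs_per_usd positive exchange rate used when costs
#'   are reported in USD (survey-period rate; 1600 TZS per USD).
#' @return An object of class \code{exit_survey}.
#' @export
exit_survey <- function(records, asset_names = NULL,
                        currency_rate_tzs_per_usd = 1600) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("exit_survey: no records")
  if (currency_rate_tzs_per_usd <= 0) stop("currency rate must be positive")
  missing_cols <- setdiff(CANONICAL_COLUMNS, names(records))
  if (length(missing_cols))
    stop("missing canonical column(s): ", paste(missing_cols, collapse = ", "))
  asset_cols <- grep("^asset_", names(records), value = TRUE)
  if (is.null(asset_names)) asset_names <- sub("^asset_", "", asset_cols)
  if (length(asset_names) != length(asset_cols))
    stop("asset_names length (", length(asset_names),
         ") does not match asset column count (", length(asset_cols), ")")
  validate_records(records)
  structure(
    list(records = records, asset_names = asset_names,
         currency_rate_tzs_per_usd = currency_rate_tzs_per_usd),
    class = "exit_survey"
  )
}

#' @export
print.exit_survey <- function(x, ...) {
  cat("Exit-interview survey: ", nrow(x$records), " patients, ",
      length(unique(x$records$facility_id)), " facilities, ",
      length(x$asset_names), " asset indicators\n", sep = "")
  invisible(x)
}

#' Number of patient records
#' @param survey an \code{exit_survey}.
#' @export
n_records <- function(survey) nrow(survey$records)

#' Asset indicator matrix
#'
#' @param survey an \code{exit_survey}.
#' @return numeric matrix, one row per patient, one column per indicator.
#' @export
asset_matrix <- function(survey) {
  cols <- grep("^asset_", names(survey$records), value = TRUE)
  m <- as.matrix(survey$records[cols])
  colnames(m) <- survey$asset_names
  storage.mode(m) <- "double"
  m
}

validate_records <- function(records) {
  for (col in names(ENUM_LEVELS)) {
    vals <- records[[col]]
    bad <- !is.na(vals) & !(vals %in% ENUM_LEVELS[[col]])
    if (any(bad))
      stop("unknown ", col, " label '", vals[which(bad)[1]],
           "' at row ", which(bad)[1])
  }
  for (col in NUMERIC_COLUMNS) {
    vals <- records[[col]]
    if (!is.numeric(vals))
      stop("column ", col, " is not numeric")
    neg <- !is.na(vals) & vals < 0
    if (any(neg))
      stop("negative value in ", col, " at row ", which(neg)[1])
  }
  invisible(TRUE)
}

#' Read a column-mapping schema file
#'
#' The schema is a plain key-value (YAML) file mapping canonical field names
#' to the column headers of an arbitrary survey export, e.g.
#' \code{travel_time_min: q12_minutes}. An \code{assets} entry lists the
#' columns to treat as household asset indicators.
#'
#' @param path path to the schema file.
#' @return named list with \code{$map} (canonical -> source column) and
#'   \code{$assets} (character vector of source asset columns).
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  assets <- unlist(raw$assets)
  raw$assets <- NULL
  map <- vapply(raw, function(x) as.character(x)[1], character(1))
  list(map = map, assets = assets)
}

#' Load an exit-interview CSV
#'
#' Reads a survey export, applies the column mapping, decodes enums, parses
#' numerics (blank cells and \code{na_strings} become missing) and validates
#' nonnegativity. Row order is preserved. Unmapped extra columns are dropped
#' with a warning, as real survey exports carry many.
#'
#' @param path CSV file (UTF-8, comma-separated, single header row).
#' @param schema either the result of \code{\link{read_schema}}, a path to a
#'   schema file, or NULL when the file already uses canonical column names
#'   (asset columns prefixed \code{asset_}).
#' @param na_strings values treated as missing in addition to empty cells.
#' @param currency_rate_tzs_per_usd exchange rate stored on the result.
#' @return an \code{\link{exit_survey}}.
#' @export
load_exit_interviews <- function(path, schema = NULL, na_strings = "NA",
                                 currency_rate_tzs_per_usd = 1600) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (is.character(schema) && length(schema) == 1L) schema <- read_schema(schema)
  if (is.null(schema)) {
    asset_src <- grep("^asset_", names(raw), value = TRUE)
    map <- stats::setNames(CANONICAL_COLUMNS, CANONICAL_COLUMNS)
  } else {
    map <- schema$map
    asset_src <- schema$assets
  }
  absent <- setdiff(unname(c(map, asset_src)), names(raw))
  if (length(absent))
    stop("schema error: mapped column(s) not in header: ",
         paste(absent, collapse = ", "))
  extra <- setdiff(names(raw), c(unname(map), asset_src))
  if (length(extra))
    warning("ignoring ", length(extra), " unmapped column(s): ",
            paste(utils::head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ..." else "")

  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in CANONICAL_COLUMNS) {
    src <- if (canon %in% names(map)) map[[canon]] else canon
    v <- raw[[src]]
    v[v %in% c("", na_strings)] <- NA
    if (canon %in% NUMERIC_COLUMNS) {
      num <- suppressWarnings(as.numeric(v))
      if (any(!is.na(v) & is.na(num)))
        stop("non-numeric value in ", canon, " at row ",
             which(!is.na(v) & is.na(num))[1])
      v <- num
    } else if (canon == "insurance") {
      v <- as.logical(toupper(v) %in% c("TRUE", "T", "1", "YES"))
    }
    out[[canon]] <- v
  }
  if (!is.null(schema)) {
    for (i in seq_along(asset_src)) {
      v <- raw[[asset_src[i]]]
      v[v %in% c("", na_strings)] <- NA
      out[[paste0("asset_", asset_src[i])]] <- suppressWarnings(as.numeric(v))
    }
    asset_names <- asset_src
  } else {
    for (col in grep("^asset_", names(raw), value = TRUE)) {
      v <- raw[[col]]
      v[v %in% c("", na_strings)] <- NA
      out[[col]] <- suppressWarnings(as.numeric(v))
    }
    asset_names <- NULL
  }
  exit_survey(out, asset_names = asset_names,
              currency_rate_tzs_per_usd = currency_rate_tzs_per_usd)
}

#' Write the canonical survey CSV
#'
#' Emits the validated table with fixed canonical column names so downstream
#' stages (and re-loading) need no schema.
#'
#' @param survey an \code{exit_survey}.
#' @param path output CSV path.
#' @export
write_exit_interviews <- function(survey, path) {
  utils::write.csv(survey$records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-variable complete-case subset
#'
#' Each outcome is analysed on the records where it is observed, so the
#' effective n differs by outcome; no imputation is performed.
#'
#' @param survey an \code{exit_survey}.
#' @param variable an outcome name from \code{\link{outcome_columns}} or a
#'   canonical column name.
#' @return an \code{exit_survey} restricted to records with the outcome
#'   present.
#' @export
complete_case <- function(survey, variable) {
  col <- resolve_outcome(variable)
  keep <- !is.na(survey$records[[col]])
  if (!any(keep)) stop("no observations for variable '", variable, "'")
  subset_survey(survey, keep)
}

resolve_outcome <- function(variable) {
  oc <- outcome_columns()
  if (variable %in% names(oc)) return(oc[[variable]])
  if (variable %in% CANONICAL_COLUMNS) return(variable)
  stop("unrecognised outcome '", variable, "'")
}

subset_survey <- function(survey, keep) {
  out <- survey
  out$records <- survey$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}
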