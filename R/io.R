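# CSV schemas and atomic table I/O for the pipeline's on-disk interface

table_schemas <- function() {
  list(
    clinical = readr::cols(
      case_id = readr::col_character(), age = readr::col_double(),
      sex = readr::col_character(), height = readr::col_double(),
      weight = readr::col_double(), asa_class = readr::col_integer(),
      surgery_type = readr::col_character(),
      surgical_approach = readr::col_character(),
      fev1_fvc_ratio = readr::col_double(),
      fvc_pct_predicted = readr::col_double()
    ),
    signals = readr::cols(
      case_id = readr::col_character(), channel = readr::col_character(),
      time_s = readr::col_double(), value = readr::col_double()
    ),
    abga = readr::cols(
      case_id = readr::col_character(), event_id = readr::col_character(),
      recorded_time_s = readr::col_double(), paco2 = readr::col_double(),
      surge_present = readr::col_logical(), .default = readr::col_double()
    ),
    events = readr::cols(
      case_id = readr::col_character(), event_id = readr::col_character(),
      status = readr::col_character(), .default = readr::col_double()
    ),
    features = readr::cols(
      case_id = readr::col_character(), event_id = readr::col_character(),
      sex = readr::col_character(), surgery_type = readr::col_character(),
      surgical_approach = readr::col_character(),
      asa_class = readr::col_character(), pft_grade = readr::col_character(),
      .default = readr::col_double()
    ),
    predictions = readr::cols(
      event_id = readr::col_character(), case_id = readr::col_character(),
      model = readr::col_character(), outer_fold = readr::col_integer(),
      actual = readr::col_double(), predicted = readr::col_double()
    )
  )
}

#' Write a pipeline table as CSV
#'
#' Writes atomically (temp file in the target directory, then rename) with
#' floating-point values at 6 significant digits.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param table Schema name (`clinical`, `signals`, `abga`, `events`,
#'   `features`, `predictions`), used for validation on write.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, table = NULL) {
  if (!is.null(table)) validate_table(x, table)
  out <- dplyr::mutate(
    tibble::as_tibble(x),
    dplyr::across(dplyr::where(is.double), ~ signif(.x, 6))
  )
  tmp <- tempfile("co2gap_", tmpdir = dirname(path), fileext = ".csv")
  readr::write_csv(out, tmp, na = "")
  file.rename(tmp, path)
  invisible(path)
}

#' Read a pipeline table
#'
#' Applies the documented column schema and the table's structural invariants
#' (required columns present, strictly increasing sample times and no
#' duplicate `(case_id, channel, time_s)` for signals).
#'
#' @param path CSV path.
#' @param table Schema name, see [write_table()].
#' @return A validated tibble.
#' @export
read_table <- function(path, table) {
  schemas <- table_schemas()
  if (!table %in% names(schemas)) stop_config("unknown table schema: ", table)
  x <- readr::read_csv(path, col_types = schemas[[table]],
                       progress = FALSE, show_col_types = FALSE)
  validate_table(x, table)
  x
}

validate_table <- function(x, table) {
  required <- list(
    clinical = c("case_id", "age", "sex", "height", "weight", "asa_class",
                 "surgery_type", "surgical_approach"),
    signals = c("case_id", "channel", "time_s", "value"),
    abga = c("case_id", "recorded_time_s", "paco2"),
    events = c("case_id", "event_id", "recorded_time_s", "status"),
    features = c("case_id", "event_id", "paco2", "etco2"),
    predictions = c("event_id", "case_id", "model", "outer_fold", "actual",
                    "predicted")
  )[[table]]
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop_schema(table, ": missing column(s): ", paste(missing, collapse = ", "))
  }
  if (table == "signals" && nrow(x) > 0) {
    key <- paste(x$case_id, x$channel, sep = "\r")
    dt <- ave(x$time_s, key, FUN = function(t) c(1, diff(t)))
    if (any(dt <= 0)) {
      bad <- which(dt <= 0)[1]
      stop_schema("signals: sample times not strictly increasing for case ",
                  x$case_id[bad], ", channel ", x$channel[bad],
                  " near time ", x$time_s[bad])
    }
  }
  if (table == "abga" && any(x$paco2 <= 0, na.rm = TRUE)) {
    stop_schema("abga: paco2 must be > 0")
  }
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' Full-precision, deterministically ordered JSON; identical reports produce
#' byte-identical files.
#'
#' @param report A `co2gap_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "co2gap_report"))
  payload <- list(
    provenance = report$provenance,
    counts = report$counts,
    metrics = report$metrics,
    agreement = report$agreement,
    utility = report$utility,
    attribution = report$attribution
  )
  tmp <- tempfile("co2gap_", tmpdir = dirname(path), fileext = ".json")
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, na = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' Write the synthetic cohort's input tables
#'
#' Emits `clinical.csv`, `signals.csv`, `abga.csv` (with the synthetic-only
#' truth columns) and a `manifest.json` recording configuration and seed.
#'
#' @param cohort A `co2gap_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "co2gap_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(cohort$clinical, file.path(dir, "clinical.csv"), "clinical")
  write_table(cohort$signals, file.path(dir, "signals.csv"), "signals")
  write_table(cohort$abga, file.path(dir, "abga.csv"), "abga")
  manifest <- list(
    package = "co2gap",
    seed = cohort$config$seed,
    n_cases = nrow(cohort$clinical),
    n_events = nrow(cohort$abga),
    config = unclass(cohort$config)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
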