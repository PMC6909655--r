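# Raw-file dialect: one RFC 4180 CSV per patient with ISO-8601 UTC timestamps,
# saturations in percent (as monitors print them), plus one demographics CSV
# and a data dictionary. This layout is the canonical raw format the platform
# module ingests.

raw_ts_cols <- c(timestamp = "c", patient_id = "c", flow_lpm = "d",
                 hb_g_dl = "d", sao2_pct = "d", svo2_pct = "d",
                 pao2_mmhg = "d", map_mmhg = "d")

#' Write a cohort to raw per-patient CSV files
#'
#' Writes one time-series CSV per patient (`<patient_id>_timeseries.csv`),
#' one `demographics.csv`, and a `data_dictionary.csv` documenting columns and
#' units. Saturations are written in percent, matching monitor output; the
#' ingest step converts them back to fractions.
#'
#' @param cohort a [simulate_cohort()] result (or any list with `records` and
#'   `profiles` tibbles in the same layout).
#' @param dir output directory, created if absent.
#'
#' @return `dir`, invisibly.
#' @examples
#' cohort <- simulate_cohort(gdp_sim_config(n_patients = 2, seed = 1))
#' d <- write_raw_cohort(cohort, tempfile("raw"))
#' list.files(d)
#' @export
write_raw_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  profiles <- cohort$profiles
  readr::write_csv(
    dplyr::rename(profiles, age_years = "age", bsa_m2 = "bsa"),
    file.path(dir, "demographics.csv")
  )
  dict <- tibble(
    column = c("timestamp", "patient_id", "flow_lpm", "hb_g_dl", "sao2_pct",
               "svo2_pct", "pao2_mmhg", "map_mmhg"),
    unit = c("ISO-8601 UTC", "-", "L/min", "g/dL", "%", "%", "mmHg", "mmHg"),
    description = c(
      "sampling time", "patient identifier", "pump flow",
      "haemoglobin concentration", "arterial oxygen saturation",
      "mixed venous oxygen saturation", "arterial oxygen tension",
      "mean arterial pressure")
  )
  readr::write_csv(dict, file.path(dir, "data_dictionary.csv"))
  if (nrow(profiles) == 0) return(invisible(dir))

  records <- cohort$records
  for (pid in profiles$patient_id) {
    out <- records[records$patient_id == pid, ]
    out <- tibble(
      timestamp = format(out$timestamp, "%Y-%m-%dT%H:%M:%OS1Z", tz = "UTC"),
      patient_id = out$patient_id,
      flow_lpm = round(out$flow, 3),
      hb_g_dl = round(out$hb, 2),
      sao2_pct = round(out$sao2 * 100, 2),
      svo2_pct = round(out$svo2 * 100, 2),
      pao2_mmhg = round(out$pao2, 1),
      map_mmhg = round(out$map, 1)
    )
    readr::write_csv(out, file.path(dir, paste0(pid, "_timeseries.csv")))
  }
  invisible(dir)
}

#' Ingest and merge raw per-patient time series
#'
#' Reads every `*_timeseries.csv` in `dir`, converts percent saturations to
#' fractions, parses ISO-8601 timestamps, and concatenates all patients into
#' one time-indexed table. Row provenance (source file and source row) is
#' retained. The result is uncleaned: duplicated rows, empty rows and missing
#' cells injected upstream are still present.
#'
#' @param dir directory holding the raw CSV dialect written by
#'   [write_raw_cohort()].
#'
#' @return A tibble of perfusion records with columns `timestamp`,
#'   `patient_id`, `flow`, `hb`, `sao2`, `svo2`, `pao2`, `map`,
#'   `source_file`, `source_row`, sorted by patient then time.
#' @export
ingest_records <- function(dir) {
  files <- list.files(dir, pattern = "_timeseries\\.csv$", full.names = TRUE)
  if (length(files) == 0) {
    abort(sprintf("no *_timeseries.csv files found in '%s'.", dir))
  }
  purrr::map(files, read_one_timeseries) %>%
    bind_rows() %>%
    arrange(.data$patient_id, .data$timestamp)
}

read_one_timeseries <- function(path) {
  raw <- readr::read_csv(path, col_types = paste(raw_ts_cols, collapse = ""),
                         progress = FALSE)
  check_cols(raw, names(raw_ts_cols), sprintf("file '%s'", basename(path)))
  ts <- parse_iso_timestamp(raw$timestamp)
  bad <- which(is.na(ts))
  if (length(bad) > 0) {
    abort(sprintf("file '%s' line %d: unparseable timestamp '%s'.",
                  basename(path), bad[1] + 1L, raw$timestamp[bad[1]]))
  }
  tibble(
    timestamp = ts,
    patient_id = raw$patient_id,
    flow = raw$flow_lpm,
    hb = raw$hb_g_dl,
    sao2 = raw$sao2_pct / 100,
    svo2 = raw$svo2_pct / 100,
    pao2 = raw$pao2_mmhg,
    map = raw$map_mmhg,
    source_file = basename(path),
    source_row = seq_len(nrow(raw)) + 1L  # header is line 1
  )
}

# strptime maps entries that fail every accepted format to NA instead of
# erroring, so the caller can point at the offending line
parse_iso_timestamp <- function(x) {
  formats <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in formats) {
    todo <- is.na(out) & !is.na(x)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
  }
  out
}

#' Read the cohort demographics file
#'
#' @param dir directory holding `demographics.csv` as written by
#'   [write_raw_cohort()].
#'
#' @return A tibble with `patient_id`, `age`, `sex`, `bsa`, `bmi`.
#' @export
ingest_profiles <- function(dir) {
  path <- file.path(dir, "demographics.csv")
  if (!file.exists(path)) {
    abort(sprintf("demographics file not found: '%s'.", path))
  }
  readr::read_csv(path, col_types = "cdcdd", progress = FALSE) %>%
    dplyr::rename(age = "age_years", bsa = "bsa_m2")
}
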