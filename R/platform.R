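# Platform module: turn raw merged records into the single analysis dataset.
# Pipeline: ingest_records() %>% clean_records() %>% interpolate_gaps() %>%
#           derive_columns(profiles)

#' Remove duplicated and empty rows
#'
#' Exact-duplicate rows (byte-identical on patient, timestamp and every
#' measurement column) are reduced to one occurrence; rows whose measurement
#' fields are all missing are dropped. Remaining ties on (patient_id,
#' timestamp) keep the first occurrence. The operation is idempotent, and
#' total rows are conserved: input rows = output rows + duplicates removed +
#' empty rows removed (the accounting is attached as the `"cleaning"`
#' attribute and retrievable with [cleaning_report()]).
#'
#' @param records a tibble of perfusion records (see [ingest_records()]).
#'
#' @return The cleaned tibble, sorted by patient then time, with a
#'   `"cleaning"` attribute holding the row accounting.
#' @export
clean_records <- function(records) {
  check_cols(records, c("timestamp", "patient_id", MEASUREMENT_COLS),
             "records")
  n_in <- nrow(records)
  key <- records[, c("patient_id", "timestamp", MEASUREMENT_COLS)]
  dup <- duplicated(key)
  out <- records[!dup, , drop = FALSE]
  # ties on the primary key with differing measurements: keep first
  tie <- duplicated(out[, c("patient_id", "timestamp")])
  n_dup <- sum(dup) + sum(tie)
  out <- out[!tie, , drop = FALSE]
  empty <- rowSums(!is.na(out[, MEASUREMENT_COLS])) == 0
  n_empty <- sum(empty)
  out <- arrange(out[!empty, , drop = FALSE], .data$patient_id, .data$timestamp)
  attr(out, "cleaning") <- tibble(
    n_ingested = n_in, n_duplicates_removed = n_dup,
    n_empty_removed = n_empty, n_cleaned = nrow(out)
  )
  out
}

#' Row-accounting report of a cleaning step
#'
#' @param records the result of [clean_records()].
#' @return A one-row tibble: rows ingested, duplicates removed, empty rows
#'   removed, rows retained.
#' @export
cleaning_report <- function(records) {
  rep <- attr(records, "cleaning")
  if (is.null(rep)) abort("`records` carries no cleaning report; run clean_records() first.")
  rep
}

# fill interior NA runs of x by linear interpolation in time, only when the
# flanking measured points span at most max_gap seconds
fill_gaps_guarded <- function(t, x, max_gap) {
  filled <- rep(FALSE, length(x))
  meas <- which(!is.na(x))
  if (length(meas) < 2) return(list(x = x, filled = filled))
  idx <- seq_along(x)
  prev_pos <- findInterval(idx, meas)           # last measured index <= i
  nxt_pos <- prev_pos + 1L                      # first measured index > i
  cand <- is.na(x) & prev_pos >= 1L & nxt_pos <= length(meas)
  if (!any(cand)) return(list(x = x, filled = filled))
  pi <- meas[pmax(prev_pos, 1L)]
  ni <- meas[pmin(nxt_pos, length(meas))]
  ok <- cand & (t[ni] - t[pi] <= max_gap)
  frac <- (t[ok] - t[pi[ok]]) / (t[ni[ok]] - t[pi[ok]])
  x[ok] <- x[pi[ok]] + frac * (x[ni[ok]] - x[pi[ok]])
  filled[ok] <- TRUE
  list(x = x, filled = filled)
}

#' Interpolate short measurement gaps
#'
#' Fills missing numeric cells by linear interpolation in time, within each
#' patient only, and only when the flanking measured values lie within
#' `max_gap` seconds of each other. Leading and trailing gaps, and gaps wider
#' than the guard, are left missing (those rows are later excluded from
#' analysis). Each measurement column gains a `<col>_src` provenance column
#' with values `"measured"` or `"interpolated"` (`NA` if still missing);
#' provenance from a previous pass is preserved, making the operation
#' idempotent.
#'
#' @param records a cleaned records tibble ([clean_records()]).
#' @param max_gap widest gap (seconds, between flanking measured samples) the
#'   interpolator is allowed to bridge. Default 120.
#'
#' @return The records tibble with gaps filled and provenance columns added.
#' @export
interpolate_gaps <- function(records, max_gap = 120) {
  check_range(max_gap, "max_gap", 0, strict_lower = TRUE)
  check_cols(records, c("timestamp", "patient_id", MEASUREMENT_COLS),
             "records")
  if (nrow(records) == 0) return(records)
  out <- records %>%
    group_by(.data$patient_id) %>%
    group_modify(function(df, key) {
      tsec <- as.numeric(df$timestamp)
      for (col in MEASUREMENT_COLS) {
        src_col <- paste0(col, "_src")
        src <- if (src_col %in% names(df)) df[[src_col]] else
          ifelse(is.na(df[[col]]), NA_character_, "measured")
        res <- fill_gaps_guarded(tsec, df[[col]], max_gap)
        df[[col]] <- res$x
        src[res$filled] <- "interpolated"
        df[[src_col]] <- src
      }
      df
    }) %>%
    ungroup()
  attr(out, "cleaning") <- attr(records, "cleaning")
  out
}

#' Derive cardiac index, DO2i and O2ER columns
#'
#' Joins body surface area from the demographics table and computes the
#' analysis columns through the physiology calculators: `ci = flow / bsa`,
#' `do2i` (including the dissolved-oxygen term) and `o2er`. Rows with any
#' required measurement still missing get `NA` derived values and are excluded
#' by downstream filters.
#'
#' @param records a records tibble (cleaned and optionally interpolated).
#' @param profiles demographics tibble with `patient_id` and `bsa`
#'   ([ingest_profiles()] or a cohort's `$profiles`).
#' @param constants a [phys_constants()] object.
#'
#' @return The records tibble with `bsa`, `ci`, `do2i`, `o2er` columns — the
#'   platform dataset.
#' @examples
#' cohort <- simulate_cohort(gdp_sim_config(n_patients = 1, seed = 1))
#' platform <- cohort$records %>%
#'   clean_records() %>%
#'   interpolate_gaps() %>%
#'   derive_columns(cohort$profiles)
#' @export
derive_columns <- function(records, profiles, constants = phys_constants()) {
  check_cols(records, c("patient_id", MEASUREMENT_COLS), "records")
  check_cols(profiles, c("patient_id", "bsa"), "profiles")
  unknown <- setdiff(unique(records$patient_id), profiles$patient_id)
  if (length(unknown) > 0) {
    abort(sprintf(
      "join failure: no demographics (bsa) for patient%s %s.",
      if (length(unknown) > 1) "s" else "",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  if (any(is.na(profiles$bsa) | profiles$bsa <= 0)) {
    abort("`bsa` must be present and positive for every patient in `profiles`.")
  }
  records %>%
    left_join(select(profiles, "patient_id", "bsa"), by = "patient_id") %>%
    mutate(
      ci = .data$flow / .data$bsa,
      do2i = do2i(.data$flow, .data$hb, .data$sao2, .data$pao2,
                  bsa = .data$bsa, constants = constants),
      o2er = o2_extraction_ratio(.data$sao2, .data$svo2)
    )
}
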