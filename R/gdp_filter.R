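#' Goal-directed perfusion thresholds
#'
#' The physiological constraints defining adequate perfusion, plus the
#' measurement-density filter settings. Defaults are the standard GDP
#' criteria: oxygen delivery index at least 280 mL/min/m^2, mixed venous
#' saturation above 68%, mean arterial pressure above 60 mmHg; cardiac-index
#' bins of width 0.1 L/min/m^2 require at least 100 haemoglobin measurements
#' to be kept.
#'
#' @param do2i_min minimum oxygen delivery index, mL/min/m^2 (retained when
#'   `do2i >= do2i_min`).
#' @param svo2_min venous saturation threshold, fraction (retained when
#'   `svo2 > svo2_min`, strict).
#' @param map_min mean arterial pressure threshold, mmHg (retained when
#'   `map > map_min`, strict).
#' @param ci_bin_width cardiac-index bin width for the density filter,
#'   L/min/m^2.
#' @param min_bin_count minimum haemoglobin measurements per CI bin.
#'
#' @return A named list of class `gdp_thresholds`.
#' @export
gdp_thresholds <- function(do2i_min = 280, svo2_min = 0.68, map_min = 60,
                           ci_bin_width = 0.1, min_bin_count = 100) {
  check_range(do2i_min, "do2i_min", 0, strict_lower = TRUE)
  check_range(svo2_min, "svo2_min", 0, 1)
  check_range(map_min, "map_min", 0, strict_lower = TRUE)
  check_range(ci_bin_width, "ci_bin_width", 0, strict_lower = TRUE)
  check_range(min_bin_count, "min_bin_count", 0)
  structure(
    list(do2i_min = do2i_min, svo2_min = svo2_min, map_min = map_min,
         ci_bin_width = ci_bin_width, min_bin_count = min_bin_count),
    class = "gdp_thresholds"
  )
}

#' Apply the GDP physiological constraints
#'
#' Retains exactly the rows satisfying all three criteria:
#' `do2i >= do2i_min`, `svo2 > svo2_min` and `map > map_min`
#' (set-intersection semantics, so the operation is idempotent and
#' order-independent). Rows with a missing `do2i`, `svo2` or `map` are
#' excluded as incomplete. Removal counts, attributed to the first failing
#' criterion in the order incomplete, DO2i, SvO2, MAP, are attached as the
#' `"gdp_report"` attribute ([gdp_report()]).
#'
#' @param data a platform dataset with derived columns ([derive_columns()]).
#' @param thresholds a [gdp_thresholds()] object.
#'
#' @return The filtered tibble.
#' @export
apply_gdp_constraints <- function(data, thresholds = gdp_thresholds()) {
  check_cols(data, c("do2i", "svo2", "map"), "data")
  incomplete <- is.na(data$do2i) | is.na(data$svo2) | is.na(data$map)
  fail_do2i <- !incomplete & data$do2i < thresholds$do2i_min
  fail_svo2 <- !incomplete & !fail_do2i & data$svo2 <= thresholds$svo2_min
  fail_map <- !incomplete & !fail_do2i & !fail_svo2 &
    data$map <= thresholds$map_min
  keep <- !(incomplete | fail_do2i | fail_svo2 | fail_map)
  out <- data[keep, , drop = FALSE]
  attr(out, "gdp_report") <- tibble(
    n_in = nrow(data),
    removed_incomplete = sum(incomplete),
    removed_do2i = sum(fail_do2i),
    removed_svo2 = sum(fail_svo2),
    removed_map = sum(fail_map),
    n_retained = nrow(out)
  )
  out
}

#' Removal report of a GDP constraint filter
#'
#' @param data the result of [apply_gdp_constraints()].
#' @return A one-row tibble of rows removed per criterion (first-failing
#'   attribution) and rows retained.
#' @export
gdp_report <- function(data) {
  rep <- attr(data, "gdp_report")
  if (is.null(rep)) abort("`data` carries no GDP report; run apply_gdp_constraints() first.")
  rep
}

# left-closed right-open CI bin index; small epsilon guards against values
# such as 2.8 - 1e-16 falling one bin low after division
ci_bin_index <- function(ci, width) {
  as.integer(floor(ci / width + 1e-9))
}

#' Measurement-density filter on cardiac-index bins
#'
#' Reduces the influence of sparse, outlier-prone regions: cardiac index is
#' binned at `ci_bin_width` (left-closed, right-open bins) and every row
#' falling in a bin holding fewer than `min_bin_count` rows with a valid
#' haemoglobin measurement is removed. A single pass: bins are counted once,
#' with no re-binning after removal.
#'
#' @param data a (typically constraint-filtered) platform dataset with `ci`
#'   and `hb` columns.
#' @param thresholds a [gdp_thresholds()] object.
#'
#' @return The filtered tibble, with a `"density_report"` attribute giving
#'   bins and rows removed.
#' @export
density_filter <- function(data, thresholds = gdp_thresholds()) {
  check_cols(data, c("ci", "hb"), "data")
  if (thresholds$ci_bin_width <= 0) {
    abort("`ci_bin_width` must be strictly positive.")
  }
  if (nrow(data) == 0) {
    attr(data, "density_report") <- tibble(
      n_in = 0L, bins_total = 0L, bins_removed = 0L,
      rows_removed = 0L, n_retained = 0L)
    return(data)
  }
  bin <- ci_bin_index(data$ci, thresholds$ci_bin_width)
  counts <- table(bin[!is.na(data$hb) & !is.na(bin)])
  good_bins <- as.integer(names(counts)[counts >= thresholds$min_bin_count])
  keep <- !is.na(bin) & bin %in% good_bins
  out <- data[keep, , drop = FALSE]
  attr(out, "density_report") <- tibble(
    n_in = nrow(data),
    bins_total = length(counts),
    bins_removed = length(counts) - length(good_bins),
    rows_removed = nrow(data) - nrow(out),
    n_retained = nrow(out)
  )
  out
}
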