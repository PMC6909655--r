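# Internal validation helpers. Every check names the offending field so
# errors are actionable; NA values pass (they propagate as NA downstream).

check_range <- function(x, field, lower = -Inf, upper = Inf,
                        strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be numeric.", field))
  }
  bad_low <- if (strict_lower) x <= lower else x < lower
  bad_high <- if (strict_upper) x >= upper else x > upper
  if (any(bad_low, na.rm = TRUE) || any(bad_high, na.rm = TRUE)) {
    abort(sprintf(
      "`%s` out of range: must be in %s%g, %g%s (got %g).",
      field,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]",
      x[which(bad_low | bad_high)[1]]
    ))
  }
  invisible(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", field))
  }
  invisible(x)
}

check_cols <- function(data, cols, what) {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s.",
      what, if (length(missing_cols) > 1) "s" else "",
      paste0("`", missing_cols, "`", collapse = ", ")
    ))
  }
  invisible(data)
}
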