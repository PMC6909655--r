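# Iso-DO2i analysis: extract bands of near-constant oxygen delivery, fit the
# weighted quadratic CI-versus-Hb curve for each target level, compare with
# the exact closed-form hyperbola, and issue pump-flow recommendations.

#' Extract an iso-DO2i band
#'
#' Selects the rows whose oxygen delivery index lies within `tolerance` of a
#' target `level` and weights them by proximity with a triangular kernel,
#' `w = 1 - |do2i - level| / tolerance` (weight 1 exactly on the level;
#' rows exactly at the band edge are kept with a vanishing positive weight).
#' With `tolerance = 0` only rows with `do2i == level` are kept, at weight 1.
#'
#' @param data a filtered platform dataset with `ci`, `hb`, `do2i` columns.
#' @param level target oxygen delivery index, mL/min/m^2.
#' @param tolerance half-width of the band, mL/min/m^2. Default 10.
#'
#' @return A tibble of band members (`ci`, `hb`, `do2i`, `weight`) of class
#'   `iso_band`, with `level` and `tolerance` attributes.
#' @export
extract_iso_band <- function(data, level, tolerance = 10) {
  check_cols(data, c("ci", "hb", "do2i"), "data")
  check_range(level, "level", 0, strict_lower = TRUE)
  check_range(tolerance, "tolerance", 0)
  dist <- abs(data$do2i - level)
  keep <- !is.na(dist) & dist <= tolerance & !is.na(data$ci) & !is.na(data$hb)
  band <- data[keep, , drop = FALSE]
  if (nrow(band) == 0) {
    abort(sprintf(
      "insufficient data: no rows within %.4g mL/min/m^2 of DO2i level %.4g.",
      tolerance, level
    ))
  }
  w <- if (tolerance == 0) rep(1, nrow(band)) else
    pmax(1 - abs(band$do2i - level) / tolerance, 1e-8)
  band <- mutate(band, weight = w)
  attr(band, "level") <- level
  attr(band, "tolerance") <- tolerance
  class(band) <- c("iso_band", class(band))
  band
}

#' Weighted quadratic fit of cardiac index on haemoglobin
#'
#' Fits `ci = a0 + a1 * hb + a2 * hb^2` to an iso-DO2i band by weighted least
#' squares (weights from the band's triangular kernel). The fit approximates
#' the exact iso-delivery hyperbola `ci = level / (10 * 1.36 * hb * sao2)`
#' over the band's haemoglobin support; the fitted curve is never evaluated
#' outside that support.
#'
#' @param band an [extract_iso_band()] result.
#'
#' @return An object of class `iso_do2_fit`: level, tolerance, coefficients
#'   `a0`, `a1`, `a2` (with standard errors), number of points, weighted
#'   residual sum of squares, and the haemoglobin evaluation domain.
#' @export
fit_iso_quadratic <- function(band) {
  check_cols(band, c("ci", "hb", "weight"), "band")
  n_hb <- dplyr::n_distinct(band$hb)
  if (n_hb < 10) {
    abort(sprintf(
      "band has only %d distinct haemoglobin values; at least 10 are needed for a stable quadratic fit.",
      n_hb
    ))
  }
  fit <- lm(ci ~ hb + I(hb^2), data = band, weights = band$weight)
  if (fit$rank < 3) {
    abort("band is rank deficient (haemoglobin values too degenerate to fit a quadratic).")
  }
  cf <- unname(coef(fit))
  se <- unname(sqrt(diag(stats::vcov(fit))))
  structure(
    list(
      level = attr(band, "level"),
      tolerance = attr(band, "tolerance"),
      coefficients = c(a0 = cf[1], a1 = cf[2], a2 = cf[3]),
      std_errors = c(a0 = se[1], a1 = se[2], a2 = se[3]),
      n_points = nrow(band),
      weighted_rss = sum(band$weight * stats::residuals(fit)^2),
      hb_range = range(band$hb)
    ),
    class = "iso_do2_fit"
  )
}

#' Fit iso-DO2i curves at several target levels
#'
#' Convenience wrapper: extracts one band per level and fits each quadratic.
#' Defaults to the three standard GDP reference levels 280, 330 and
#' 380 mL/min/m^2.
#'
#' @param data a filtered platform dataset.
#' @param levels target DO2i levels, mL/min/m^2.
#' @param tolerance band half-width, mL/min/m^2.
#'
#' @return A named list of `iso_do2_fit` objects of class `iso_do2_fits`.
#' @export
fit_iso_curves <- function(data, levels = c(280, 330, 380), tolerance = 10) {
  fits <- purrr::map(levels, function(lv) {
    fit_iso_quadratic(extract_iso_band(data, lv, tolerance))
  })
  names(fits) <- as.character(levels)
  structure(fits, class = "iso_do2_fits")
}

#' Evaluate a fitted iso-DO2i curve
#'
#' @param object an `iso_do2_fit`.
#' @param hb haemoglobin values, g/dL.
#' @param clip_to_domain if `TRUE` (default), values of `hb` outside the
#'   band's observed haemoglobin range return `NA` rather than extrapolating.
#' @param ... unused.
#'
#' @return Predicted cardiac index, L/min/m^2.
#' @export
predict.iso_do2_fit <- function(object, hb, clip_to_domain = TRUE, ...) {
  check_flag(clip_to_domain, "clip_to_domain")
  cf <- object$coefficients
  out <- cf[["a0"]] + cf[["a1"]] * hb + cf[["a2"]] * hb^2
  if (clip_to_domain) {
    out[hb < object$hb_range[1] | hb > object$hb_range[2]] <- NA_real_
  }
  out
}

#' @export
print.iso_do2_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "<iso_do2_fit> DO2i %g mL/min/m^2 (+/- %g): ci = %.4g %+.4g hb %+.4g hb^2\n  n = %d, Hb domain [%.2f, %.2f] g/dL, weighted RSS = %.4g\n",
    x$level, x$tolerance, cf[["a0"]], cf[["a1"]], cf[["a2"]],
    x$n_points, x$hb_range[1], x$hb_range[2], x$weighted_rss
  ))
  invisible(x)
}

#' @export
print.iso_do2_fits <- function(x, ...) {
  for (f in x) print(f)
  invisible(x)
}

#' Tidy an iso-DO2i quadratic fit
#'
#' @param x an `iso_do2_fit` or `iso_do2_fits` object.
#' @param ... unused.
#' @return A tibble with one row per coefficient: `level`, `term`,
#'   `estimate`, `std.error`.
#' @export
tidy.iso_do2_fit <- function(x, ...) {
  tibble(
    level = x$level,
    term = c("(Intercept)", "hb", "hb^2"),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_errors)
  )
}

#' @rdname tidy.iso_do2_fit
#' @export
tidy.iso_do2_fits <- function(x, ...) {
  purrr::map(unclass(x), tidy) %>% bind_rows()
}

#' Glance at an iso-DO2i quadratic fit
#'
#' @param x an `iso_do2_fit` or `iso_do2_fits` object.
#' @param ... unused.
#' @return A one-row-per-fit tibble: `level`, `tolerance`, `n_points`,
#'   `weighted_rss`, `hb_min`, `hb_max`.
#' @export
glance.iso_do2_fit <- function(x, ...) {
  tibble(
    level = x$level, tolerance = x$tolerance, n_points = x$n_points,
    weighted_rss = x$weighted_rss,
    hb_min = x$hb_range[1], hb_max = x$hb_range[2]
  )
}

#' @rdname glance.iso_do2_fit
#' @export
glance.iso_do2_fits <- function(x, ...) {
  purrr::map(unclass(x), glance) %>% bind_rows()
}

#' Exact iso-delivery curve
#'
#' The closed-form locus of (Hb, CI) pairs giving a constant oxygen delivery
#' index: `ci(hb) = level / (10 * (1.36 * hb * sao2 + 0.003 * pao2))`. This is
#' the physiological reference the quadratic band fits approximate; it is
#' strictly decreasing and convex in haemoglobin.
#'
#' @param level target DO2i, mL/min/m^2.
#' @param sao2 arterial saturation, fraction. Default 1 (reference
#'   conditions).
#' @param pao2 arterial oxygen tension, mmHg. Default 0 (dissolved oxygen
#'   neglected).
#' @param constants a [phys_constants()] object.
#'
#' @return A function `hb -> ci`.
#' @examples
#' curve280 <- closed_form_curve(280)
#' curve280(8)   # 2.574 L/min/m^2
#' @export
closed_form_curve <- function(level, sao2 = 1, pao2 = 0,
                              constants = phys_constants()) {
  check_range(level, "level", 0)
  force(sao2); force(pao2); force(constants)
  function(hb) required_ci(level, hb, sao2, pao2, constants)
}

#' Recommend a pump flow for a DO2i target
#'
#' The goal-directed flow calculator: given the patient's haemoglobin (and
#' optionally saturation, oxygen tension and body surface area), returns the
#' minimum cardiac index — and pump flow — that sustains the target oxygen
#' delivery index. At Hb 8 g/dL and the default reference conditions the
#' recommended CI for the 280 mL/min/m^2 goal rounds to 2.6 L/min/m^2.
#'
#' @param hb haemoglobin, g/dL (vectorised).
#' @param bsa body surface area, m^2. Default 1.95 (cohort mean); the flow
#'   column is `ci * bsa`.
#' @param level target DO2i, mL/min/m^2. Default 280.
#' @param sao2 arterial saturation, fraction. Default 1.
#' @param pao2 arterial oxygen tension, mmHg. Default 0.
#' @param constants a [phys_constants()] object.
#'
#' @return A tibble with `hb`, `level`, `ci`, `flow` (full precision) and
#'   display columns `ci_rounded`, `flow_rounded` (one decimal).
#' @examples
#' recommend_flow(hb = c(8, 10))
#' @export
recommend_flow <- function(hb, bsa = 1.95, level = 280, sao2 = 1, pao2 = 0,
                           constants = phys_constants()) {
  validate_oxygen_state(bsa = bsa)
  ci <- required_ci(level, hb, sao2, pao2, constants)
  tibble(
    hb = hb, level = level, ci = ci, flow = ci * bsa,
    ci_rounded = round(ci, 1), flow_rounded = round(ci * bsa, 1)
  )
}
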