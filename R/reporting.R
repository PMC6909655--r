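# Reporting: figures mirroring the standard GDP visualisations (Hb on x,
# CI on y, DO2i as a sequential colour scale with darker shades for lower
# delivery) and a cohort demographics summary. Figures are by-products: every
# quantitative claim a figure carries is available from the underlying
# tibbles (iso_curve_points(), cohort_table()), so nothing needs to be read
# off pixels.

#' Scatter of cardiac index against haemoglobin, coloured by DO2i
#'
#' On the full dataset the point cloud extends below the iso-280 curve
#' (transient low-flow episodes); after GDP filtering the lower edge shows
#' the characteristic arch-shaped cut along that curve.
#'
#' @param data a platform dataset with `hb`, `ci`, `do2i` columns.
#' @param alpha point transparency.
#'
#' @return A ggplot object.
#' @export
plot_do2i_scatter <- function(data, alpha = 0.25) {
  check_cols(data, c("hb", "ci", "do2i"), "data")
  data <- filter(data, !is.na(.data$hb), !is.na(.data$ci), !is.na(.data$do2i))
  if (nrow(data) == 0) abort("nothing to plot: no complete rows in `data`.")
  ggplot2::ggplot(data, ggplot2::aes(.data$hb, .data$ci, colour = .data$do2i)) +
    ggplot2::geom_point(alpha = alpha, size = 0.6) +
    ggplot2::scale_colour_viridis_c(name = expression(DO[2] * i ~ (mL / min / m^2))) +
    ggplot2::labs(
      x = "Haemoglobin (g/dL)",
      y = expression(Cardiac ~ index ~ (L / min / m^2))
    ) +
    ggplot2::theme_minimal()
}

#' Sampled points of fitted iso-DO2i curves
#'
#' Serialises each fitted curve as `n` (hb, ci) samples over its own
#' haemoglobin domain — the array behind [plot_iso_curves()], and the object
#' to assert curve ordering and monotonicity on.
#'
#' @param fits an `iso_do2_fits` list (or a single `iso_do2_fit`).
#' @param n samples per curve.
#'
#' @return A tibble with `level`, `hb`, `ci`.
#' @export
iso_curve_points <- function(fits, n = 100) {
  if (inherits(fits, "iso_do2_fit")) fits <- structure(list(fits), class = "iso_do2_fits")
  purrr::map(unclass(fits), function(f) {
    hb <- seq(f$hb_range[1], f$hb_range[2], length.out = n)
    tibble(level = f$level, hb = hb, ci = predict(f, hb))
  }) %>% bind_rows()
}

#' Plot fitted iso-DO2i curves over the band scatter
#'
#' Each curve is drawn only over its own band's haemoglobin domain (no
#' extrapolation). With data supplied, the underlying band members are shown
#' as a scatter.
#'
#' @param fits an `iso_do2_fits` list (or a single fit).
#' @param data optional platform dataset for the background scatter.
#'
#' @return A ggplot object.
#' @export
plot_iso_curves <- function(fits, data = NULL) {
  curves <- iso_curve_points(fits)
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    data <- filter(data, !is.na(.data$hb), !is.na(.data$ci))
    p <- p + ggplot2::geom_point(
      data = data, ggplot2::aes(.data$hb, .data$ci),
      colour = "grey70", alpha = 0.15, size = 0.5
    )
  }
  p +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(.data$hb, .data$ci, colour = factor(.data$level)),
      linewidth = 1
    ) +
    ggplot2::scale_colour_viridis_d(name = expression(DO[2] * i ~ level)) +
    ggplot2::labs(
      x = "Haemoglobin (g/dL)",
      y = expression(Cardiac ~ index ~ (L / min / m^2))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.iso_do2_fits <- function(object, data = NULL, ...) {
  plot_iso_curves(object, data)
}

#' @export
autoplot.iso_do2_fit <- function(object, data = NULL, ...) {
  plot_iso_curves(object, data)
}

#' Cohort demographics summary
#'
#' Summarises a demographics table the way clinical baseline tables are
#' reported: count, mean and standard deviation of age, body surface area and
#' body mass index, and sex counts with percentages. With a single patient
#' the standard deviations are `NA` (flagged, not zero).
#'
#' @param profiles a demographics tibble (`patient_id`, `age`, `sex`, `bsa`,
#'   `bmi`).
#'
#' @return A one-row tibble of class `cohort_summary`.
#' @export
cohort_table <- function(profiles) {
  check_cols(profiles, c("patient_id", "age", "sex", "bsa", "bmi"), "profiles")
  if (nrow(profiles) == 0) abort("`profiles` has no patients.")
  male <- sum(profiles$sex == "male")
  out <- tibble(
    n = nrow(profiles),
    age_mean = mean(profiles$age), age_sd = sd(profiles$age),
    male_n = male, male_pct = 100 * male / nrow(profiles),
    female_n = nrow(profiles) - male,
    female_pct = 100 * (nrow(profiles) - male) / nrow(profiles),
    bsa_mean = mean(profiles$bsa), bsa_sd = sd(profiles$bsa),
    bmi_mean = mean(profiles$bmi), bmi_sd = sd(profiles$bmi)
  )
  class(out) <- c("cohort_summary", class(out))
  out
}
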