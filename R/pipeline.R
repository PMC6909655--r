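#' Full-run configuration
#'
#' Bundles every stage's settings for [run_gdp_pipeline()]: the synthetic
#' cohort generator, the interpolation gap guard, the GDP thresholds, the
#' iso-DO2i levels and band tolerance, and the haemoglobin grid of the
#' recommendation table.
#'
#' @param sim a [gdp_sim_config()].
#' @param max_gap interpolation gap guard, seconds.
#' @param thresholds a [gdp_thresholds()].
#' @param levels iso-DO2i target levels, mL/min/m^2.
#' @param tolerance iso band half-width, mL/min/m^2.
#' @param recommend_hb haemoglobin grid (g/dL) for the recommendation table.
#' @param seed overrides `sim$seed` when not `NULL`, so one integer seeds the
#'   whole run.
#'
#' @return A named list of class `gdp_run_config`.
#' @export
gdp_run_config <- function(sim = gdp_sim_config(),
                           max_gap = 120,
                           thresholds = gdp_thresholds(),
                           levels = c(280, 330, 380),
                           tolerance = 10,
                           recommend_hb = seq(6, 14, by = 0.5),
                           seed = NULL) {
  if (!is.null(seed)) sim$seed <- seed
  structure(
    list(sim = sim, max_gap = max_gap, thresholds = thresholds,
         levels = levels, tolerance = tolerance,
         recommend_hb = recommend_hb, seed = sim$seed),
    class = "gdp_run_config"
  )
}

#' Run the whole goal-directed-perfusion pipeline
#'
#' Executes every stage in order — simulate, (optionally) write and re-ingest
#' the raw per-patient files, clean, interpolate, derive, apply GDP
#' constraints, density-filter, fit the three iso-DO2i curves, build the
#' flow-recommendation table, and draw the figures — writing all outputs and
#' a manifest (configuration hash plus per-stage row counts) under `out_dir`.
#' An identical configuration and seed reproduces the manifest and the fit
#' coefficients exactly.
#'
#' @param config a [gdp_run_config()].
#' @param out_dir output directory, created if absent.
#' @param write_raw if `TRUE`, round-trip the cohort through the raw CSV
#'   dialect on disk (slower, exercises the ingest path and applies the raw
#'   files' printed precision); if `FALSE` (default) the in-memory records
#'   feed the platform directly.
#'
#' @return Invisibly, a list with the stage outputs: `cohort`, `platform`,
#'   `constrained`, `filtered`, `fits`, `recommendations`, `manifest`.
#' @examples
#' \donttest{
#' cfg <- gdp_run_config(sim = gdp_sim_config(n_patients = 5, seed = 1))
#' res <- run_gdp_pipeline(cfg, tempfile("run"))
#' res$manifest$stages$fit
#' }
#' @export
run_gdp_pipeline <- function(config = gdp_run_config(), out_dir,
                             write_raw = FALSE) {
  if (!inherits(config, "gdp_run_config")) {
    abort("`config` must be created with gdp_run_config().")
  }
  check_flag(write_raw, "write_raw")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  cohort <- stage("simulate", simulate_cohort(config$sim))
  stages$simulate <- list(patients = nrow(cohort$profiles),
                          raw_rows = nrow(cohort$records))

  if (write_raw) {
    raw_dir <- file.path(out_dir, "raw")
    stage("write-raw", write_raw_cohort(cohort, raw_dir))
    records <- stage("ingest", ingest_records(raw_dir))
    profiles <- stage("ingest", ingest_profiles(raw_dir))
  } else {
    records <- cohort$records
    profiles <- cohort$profiles
  }

  cleaned <- stage("clean", clean_records(records))
  stages$clean <- as.list(cleaning_report(cleaned))

  interp <- stage("interpolate", interpolate_gaps(cleaned, config$max_gap))
  platform <- stage("derive", derive_columns(interp, profiles))
  stages$platform <- list(rows = nrow(platform))

  constrained <- stage("filter", apply_gdp_constraints(platform, config$thresholds))
  stages$filter <- as.list(gdp_report(constrained))
  filtered <- stage("filter", density_filter(constrained, config$thresholds))
  stages$filter <- c(stages$filter, as.list(attr(filtered, "density_report")))

  fits <- stage("fit", fit_iso_curves(filtered, config$levels, config$tolerance))
  stages$fit <- glance(fits)

  recommendations <- stage("recommend", purrr::map(
    config$levels,
    function(lv) recommend_flow(config$recommend_hb, level = lv,
                                bsa = mean(profiles$bsa))
  ) %>% bind_rows())
  stages$recommend <- list(rows = nrow(recommendations))

  stage("plot", {
    grDevices::pdf(file.path(out_dir, "figures.pdf"), width = 7, height = 5)
    print(plot_do2i_scatter(platform))
    print(plot_do2i_scatter(filtered))
    print(plot_iso_curves(fits, filtered))
    grDevices::dev.off()
  })
  stages$plot <- list(figures = 3L)

  readr::write_csv(select(platform, -dplyr::ends_with("_src")),
                   file.path(out_dir, "platform_dataset.csv"))
  readr::write_csv(select(filtered, -dplyr::ends_with("_src")),
                   file.path(out_dir, "filtered_dataset.csv"))
  readr::write_csv(recommendations, file.path(out_dir, "recommendations.csv"))
  jsonlite::write_json(
    purrr::map(unclass(fits), function(f) {
      list(level = f$level, tolerance = f$tolerance,
           coefficients = as.list(f$coefficients),
           n_points = f$n_points, weighted_rss = f$weighted_rss,
           hb_range = f$hb_range)
    }),
    file.path(out_dir, "iso_fits.json"), auto_unbox = TRUE, digits = NA
  )

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, platform = platform,
                 constrained = constrained, filtered = filtered,
                 fits = fits, recommendations = recommendations,
                 manifest = manifest))
}
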