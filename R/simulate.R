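#' Synthetic cohort generator configuration
#'
#' Parameters controlling [simulate_cohort()]. Defaults emulate the structure
#' of a ~272-patient cardiac-surgery cohort monitored continuously on bypass:
#' cardiac index concentrated in 1.3-2.8 L/min/m^2 around a set point near
#' 2.2-2.4, haemoglobin concentrated in 9-12 g/dL under haemodilution, a
#' moderate fraction of transient low-DO2i episodes caused by short pump-flow
#' reductions, and raw-file corruption (duplicated rows, fully empty rows,
#' missing cells) typical of exported monitor spreadsheets. At the default
#' 5-second sampling interval and 90-150 minute case durations the full
#' cohort holds roughly 390,000 rows.
#'
#' @param n_patients number of patients.
#' @param sampling_interval monitor sampling interval, seconds.
#' @param duration_range per-case bypass duration range, minutes.
#' @param ci_setpoint_mean,ci_setpoint_sd between-patient distribution of the
#'   cardiac-index set point, L/min/m^2.
#' @param ci_noise_sd within-patient flow noise around the set point (CI units).
#' @param hb_start_mean,hb_start_sd distribution of post-dilution starting
#'   haemoglobin, g/dL.
#' @param hb_drift_sd per-sample haemoglobin random-walk standard deviation, g/dL.
#' @param hb_range hard physiological bounds on haemoglobin, g/dL (random walk
#'   reflects at the bounds).
#' @param low_flow_episode_rate expected transient flow-reduction episodes per
#'   hour of bypass.
#' @param low_flow_depth mean fractional flow reduction during an episode.
#' @param low_flow_duration episode duration range, seconds.
#' @param vo2i_mean,vo2i_sd between-patient latent oxygen consumption,
#'   mL O2/min/m^2. Venous saturation is derived from this via the inverse
#'   Fick relation so that flow reductions depress DO2i and SvO2 together.
#' @param sao2_mean,sao2_sd arterial saturation level (fraction) and noise.
#' @param pao2_mean,pao2_sd arterial oxygen tension, mmHg.
#' @param map_intercept,map_slope,map_noise_sd linear map from cardiac index to
#'   mean arterial pressure, mmHg.
#' @param duplicate_row_rate,empty_row_rate,missing_cell_rate corruption rates
#'   in \[0, 1): fraction of rows duplicated, fraction of rows inserted fully
#'   empty, fraction of measurement cells blanked.
#' @param bsa_mean,bsa_sd body surface area distribution, m^2.
#' @param bmi_mean,bmi_sd body mass index distribution.
#' @param male_fraction fraction of male patients.
#' @param age_mean,age_sd age distribution, years.
#' @param seed integer seed; a fixed seed makes [simulate_cohort()] fully
#'   deterministic. `NULL` leaves the RNG state alone.
#'
#' @return A named list of class `gdp_sim_config`.
#' @examples
#' cfg <- gdp_sim_config(n_patients = 4, seed = 1)
#' @export
gdp_sim_config <- function(n_patients = 272,
                           sampling_interval = 5,
                           duration_range = c(90, 150),
                           ci_setpoint_mean = 2.3,
                           ci_setpoint_sd = 0.15,
                           ci_noise_sd = 0.06,
                           hb_start_mean = 10.8,
                           hb_start_sd = 0.85,
                           hb_drift_sd = 0.012,
                           hb_range = c(7, 14),
                           low_flow_episode_rate = 2,
                           low_flow_depth = 0.35,
                           low_flow_duration = c(30, 180),
                           vo2i_mean = 75,
                           vo2i_sd = 10,
                           sao2_mean = 0.98,
                           sao2_sd = 0.004,
                           pao2_mean = 250,
                           pao2_sd = 40,
                           map_intercept = 20,
                           map_slope = 22,
                           map_noise_sd = 6,
                           duplicate_row_rate = 0.01,
                           empty_row_rate = 0.005,
                           missing_cell_rate = 0.01,
                           bsa_mean = 1.95,
                           bsa_sd = 0.21,
                           bmi_mean = 28.38,
                           bmi_sd = 4.78,
                           male_fraction = 0.736,
                           age_mean = 62.5,
                           age_sd = 12.4,
                           seed = NULL) {
  check_range(n_patients, "n_patients", 0)
  check_range(sampling_interval, "sampling_interval", 0, strict_lower = TRUE)
  if (length(duration_range) != 2 || diff(duration_range) < 0) {
    abort("`duration_range` must be c(min, max) in minutes.")
  }
  for (r in c("duplicate_row_rate", "empty_row_rate", "missing_cell_rate")) {
    check_range(get(r), r, 0, 1, strict_upper = TRUE)
  }
  check_range(male_fraction, "male_fraction", 0, 1)
  check_range(low_flow_depth, "low_flow_depth", 0, 1, strict_upper = TRUE)
  if (!is.null(seed)) check_range(seed, "seed", -2^31 + 1, 2^31 - 1)
  cfg <- as.list(environment())
  structure(cfg, class = "gdp_sim_config")
}

# reflecting random walk kept inside [lo, hi]
reflect_walk <- function(start, steps_sd, n, lo, hi) {
  x <- start + cumsum(c(0, rnorm(n - 1, 0, steps_sd)))
  # fold back into the band; one pass suffices for small drifts
  over <- x > hi
  x[over] <- 2 * hi - x[over]
  under <- x < lo
  x[under] <- 2 * lo - x[under]
  pmin(pmax(x, lo), hi)
}

simulate_patient <- function(id, profile, config) {
  interval <- config$sampling_interval
  dur_min <- runif(1, config$duration_range[1], config$duration_range[2])
  n <- max(2L, floor(dur_min * 60 / interval))
  t0 <- as.POSIXct("2018-06-01 08:00:00", tz = "UTC") + (id - 1) * 86400
  timestamp <- t0 + (seq_len(n) - 1L) * interval

  ci_set <- rnorm(1, config$ci_setpoint_mean, config$ci_setpoint_sd)
  ci_set <- pmin(pmax(ci_set, 1.6), 3.0)
  ci <- ci_set + rnorm(n, 0, config$ci_noise_sd)

  # transient low-flow episodes (surgical manipulation, aortic clamping etc.)
  n_ep <- rpois(1, config$low_flow_episode_rate * dur_min / 60)
  if (n_ep > 0) {
    for (k in seq_len(n_ep)) {
      ep_len <- round(runif(1, config$low_flow_duration[1],
                            config$low_flow_duration[2]) / interval)
      ep_start <- sample.int(max(1L, n - ep_len), 1)
      depth <- min(0.9, config$low_flow_depth * runif(1, 0.6, 1.6))
      idx <- ep_start:min(n, ep_start + ep_len - 1L)
      ci[idx] <- ci[idx] * (1 - depth)
    }
  }
  ci <- pmax(ci, 0.1)
  flow <- ci * profile$bsa

  hb <- reflect_walk(rnorm(1, config$hb_start_mean, config$hb_start_sd),
                     config$hb_drift_sd, n,
                     config$hb_range[1], config$hb_range[2])
  sao2 <- pmin(pmax(config$sao2_mean + rnorm(n, 0, config$sao2_sd), 0.9), 1)
  pao2 <- pmax(rnorm(n, config$pao2_mean, config$pao2_sd), 60)

  # venous saturation from latent consumption via inverse Fick:
  # VO2i = 10 * CI * 1.36 * Hb * (SaO2 - SvO2)  (dissolved term neglected)
  vo2i <- pmax(rnorm(1, config$vo2i_mean, config$vo2i_sd), 30) +
    as.numeric(stats::filter(rnorm(n, 0, 2), 0.95, method = "recursive"))
  svo2 <- sao2 - vo2i / (10 * ci * 1.36 * hb)
  svo2 <- pmin(pmax(svo2, 0.3), sao2)

  map <- config$map_intercept + config$map_slope * ci +
    rnorm(n, 0, config$map_noise_sd)
  map <- pmax(map, 20)

  tibble(
    timestamp = timestamp,
    patient_id = profile$patient_id,
    flow = flow, hb = hb, sao2 = sao2, svo2 = svo2, pao2 = pao2, map = map
  )
}

corrupt_patient <- function(rec, config) {
  n <- nrow(rec)
  m <- length(MEASUREMENT_COLS)

  # blank random measurement cells, never the entire row
  mask <- matrix(rbinom(n * m, 1, config$missing_cell_rate) == 1, nrow = n)
  full <- rowSums(mask) == m
  mask[full, 1] <- FALSE
  for (j in seq_len(m)) {
    rec[[MEASUREMENT_COLS[j]]][mask[, j]] <- NA_real_
  }
  n_missing <- sum(mask)

  # fully empty rows at off-grid timestamps (unique, so they never collide)
  n_empty <- rbinom(1, n, config$empty_row_rate)
  if (n_empty > 0) {
    at <- sort(sample.int(n - 1L, min(n_empty, n - 1L)))
    n_empty <- length(at)
    empty <- rec[at, ]
    empty$timestamp <- empty$timestamp + config$sampling_interval / 2
    for (col in MEASUREMENT_COLS) empty[[col]] <- NA_real_
    rec <- bind_rows(rec, empty)
  }

  # exact duplicates of existing rows
  n_dup <- rbinom(1, n, config$duplicate_row_rate)
  if (n_dup > 0) {
    rec <- bind_rows(rec, rec[sample.int(n, n_dup), ])
  }

  rec <- arrange(rec, .data$timestamp)
  list(records = rec,
       ledger = tibble(n_duplicates = n_dup, n_empty = n_empty,
                       n_missing_cells = n_missing))
}

#' Simulate a synthetic bypass cohort
#'
#' Generates per-patient demographics and intra-operative time series with the
#' statistical structure of real goal-directed-perfusion monitoring data, plus
#' a corruption pass that mimics raw spreadsheet exports. The uncorrupted
#' series are retained (`$truth`) with the true derived DO2i and a
#' `low_do2i` tag (true DO2i < 280 mL/min/m^2), so downstream filters can be
#' validated against known ground truth; the corruption counts are retained
#' per patient in `$ledger` so cleaning can be validated by exact accounting.
#'
#' @param config a [gdp_sim_config()].
#'
#' @return An object of class `gdp_cohort`: a list with
#'   \describe{
#'     \item{profiles}{tibble of patient demographics (patient_id, age, sex,
#'       bsa, bmi).}
#'     \item{records}{tibble of corrupted raw records, one row per sampling
#'       tick (plus injected duplicates/empties), measurement columns
#'       `flow` (L/min), `hb` (g/dL), `sao2`/`svo2` (fractions),
#'       `pao2`/`map` (mmHg).}
#'     \item{truth}{tibble of the uncorrupted records with `ci`, `do2i` and
#'       the `low_do2i` ground-truth tag.}
#'     \item{ledger}{per-patient corruption counts (duplicates, empty rows,
#'       missing cells).}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' cohort <- simulate_cohort(gdp_sim_config(n_patients = 2, seed = 7))
#' nrow(cohort$records)
#' @export
simulate_cohort <- function(config = gdp_sim_config()) {
  if (!inherits(config, "gdp_sim_config")) {
    abort("`config` must be created with gdp_sim_config().")
  }
  run <- function() {
    n <- config$n_patients
    if (n == 0) {
      return(structure(list(
        profiles = tibble(patient_id = character(), age = numeric(),
                          sex = character(), bsa = numeric(), bmi = numeric()),
        records = tibble(), truth = tibble(),
        ledger = tibble(patient_id = character(), n_duplicates = integer(),
                        n_empty = integer(), n_missing_cells = integer()),
        config = config
      ), class = "gdp_cohort"))
    }
    profiles <- tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      age = round(pmin(pmax(rnorm(n, config$age_mean, config$age_sd), 18), 95)),
      sex = ifelse(runif(n) < config$male_fraction, "male", "female"),
      bsa = round(pmin(pmax(rnorm(n, config$bsa_mean, config$bsa_sd), 1.2), 2.8), 2),
      bmi = round(pmin(pmax(rnorm(n, config$bmi_mean, config$bmi_sd), 15), 50), 1)
    )
    truth_list <- vector("list", n)
    rec_list <- vector("list", n)
    led_list <- vector("list", n)
    for (i in seq_len(n)) {
      prof <- profiles[i, ]
      clean <- simulate_patient(i, prof, config)
      tr <- mutate(clean,
        ci = .data$flow / prof$bsa,
        do2i = do2i(.data$flow, .data$hb, .data$sao2, .data$pao2, bsa = prof$bsa),
        low_do2i = .data$do2i < 280
      )
      cor <- corrupt_patient(clean, config)
      truth_list[[i]] <- tr
      rec_list[[i]] <- cor$records
      led_list[[i]] <- mutate(cor$ledger, patient_id = prof$patient_id,
                              n_rows_true = nrow(clean), .before = 1)
    }
    structure(list(
      profiles = profiles,
      records = bind_rows(rec_list),
      truth = bind_rows(truth_list),
      ledger = bind_rows(led_list),
      config = config
    ), class = "gdp_cohort")
  }
  if (!is.null(config$seed)) {
    withr::with_seed(config$seed, run())
  } else {
    run()
  }
}

#' @export
print.gdp_cohort <- function(x, ...) {
  cat(sprintf(
    "<gdp_cohort> %d patients, %d raw rows (%d true), seed %s\n",
    nrow(x$profiles), nrow(x$records), nrow(x$truth),
    if (is.null(x$config$seed)) "unset" else x$config$seed
  ))
  invisible(x)
}
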