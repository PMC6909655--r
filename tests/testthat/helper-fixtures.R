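# Fixtures are built in code: small seeded cohorts (short cases keep tests
# fast) and noise-free iso-bands lying exactly on the closed-form curve.

small_cohort <- function(n = 6, seed = 42, ...) {
  simulate_cohort(gdp_sim_config(
    n_patients = n, duration_range = c(20, 35), seed = seed, ...
  ))
}

# platform dataset built from a cohort's uncorrupted records (ground truth)
truth_platform <- function(cohort) {
  cohort$truth |>
    dplyr::select(timestamp, patient_id, flow, hb, sao2, svo2, pao2, map) |>
    derive_columns(cohort$profiles)
}

# rows lying exactly on the iso-DO2i hyperbola at reference conditions
noise_free_band <- function(level, hb = seq(8, 12, length.out = 201),
                            sao2 = 1, pao2 = 0) {
  ci <- required_ci(level, hb, sao2, pao2)
  tibble::tibble(
    hb = hb, ci = ci,
    do2i = do2i(ci, hb, sao2 = sao2, pao2 = pao2)
  )
}

# brute-force GDP predicate, written independently of apply_gdp_constraints
brute_force_gdp <- function(data, do2i_min = 280, svo2_min = 0.68, map_min = 60) {
  keep <- logical(nrow(data))
  for (i in seq_len(nrow(data))) {
    keep[i] <- !is.na(data$do2i[i]) && !is.na(data$svo2[i]) &&
      !is.na(data$map[i]) &&
      data$do2i[i] >= do2i_min && data$svo2[i] > svo2_min &&
      data$map[i] > map_min
  }
  data[keep, , drop = FALSE]
}
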