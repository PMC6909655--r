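make_records <- function(n, pid = "P001", t0 = "2018-06-01 08:00:00",
                         interval = 5) {
  tibble::tibble(
    timestamp = as.POSIXct(t0, tz = "UTC") + (seq_len(n) - 1) * interval,
    patient_id = pid,
    flow = rep(4.0, n), hb = rep(10, n), sao2 = rep(0.98, n),
    svo2 = rep(0.75, n), pao2 = rep(200, n), map = rep(65, n)
  )
}

test_that("ingest concatenates all patient files and keeps provenance", {
  cohort <- small_cohort(n = 3, seed = 21, duplicate_row_rate = 0,
                         empty_row_rate = 0, missing_cell_rate = 0)
  dir <- withr::local_tempdir()
  write_raw_cohort(cohort, dir)
  records <- ingest_records(dir)
  expect_equal(nrow(records), nrow(cohort$records))
  expect_setequal(unique(records$source_file),
                  paste0(cohort$profiles$patient_id, "_timeseries.csv"))
  expect_true(all(records$source_row >= 2))  # line 1 is the header
  # saturations came back as fractions
  expect_true(all(records$sao2 <= 1 & records$sao2 >= 0))
})

test_that("an unparseable timestamp is reported with file and line", {
  cohort <- small_cohort(n = 1, seed = 22)
  dir <- withr::local_tempdir()
  write_raw_cohort(cohort, dir)
  f <- list.files(dir, pattern = "_timeseries", full.names = TRUE)[1]
  lines <- readLines(f)
  lines[4] <- sub("^[^,]+", "not-a-time", lines[4])
  writeLines(lines, f)
  expect_error(ingest_records(f |> dirname()), "line 4")
})

test_that("cleaning removes exactly the duplicated and empty rows", {
  base <- make_records(100)
  # inject 7 duplicates and 5 empty rows
  dup <- base[c(3, 10, 22, 41, 57, 80, 99), ]
  empty <- base[1:5, ]
  empty$timestamp <- empty$timestamp + 2.5
  empty[, c("flow", "hb", "sao2", "svo2", "pao2", "map")] <- NA_real_
  corrupted <- dplyr::bind_rows(base, dup, empty)
  cleaned <- clean_records(corrupted)
  rep <- cleaning_report(cleaned)
  expect_equal(rep$n_ingested, 112)
  expect_equal(rep$n_duplicates_removed, 7)
  expect_equal(rep$n_empty_removed, 5)
  expect_equal(nrow(cleaned), 100)
  # conservation: in = out + removed
  expect_equal(rep$n_ingested,
               rep$n_cleaned + rep$n_duplicates_removed + rep$n_empty_removed)
  # idempotence
  again <- clean_records(cleaned)
  expect_equal(nrow(again), nrow(cleaned))
  expect_equal(cleaning_report(again)$n_duplicates_removed, 0)
})

test_that("primary-key ties keep the first occurrence", {
  base <- make_records(10)
  conflict <- base[4, ]
  conflict$hb <- 9.1  # same key, different measurement: not a byte-duplicate
  cleaned <- clean_records(dplyr::bind_rows(base, conflict))
  expect_equal(nrow(cleaned), 10)
  expect_equal(cleaned$hb[4], 10)  # first occurrence wins
  expect_false(any(duplicated(cleaned[, c("patient_id", "timestamp")])))
})

test_that("an all-empty dataset cleans to an empty dataset", {
  base <- make_records(5)
  base[, c("flow", "hb", "sao2", "svo2", "pao2", "map")] <- NA_real_
  cleaned <- clean_records(base)
  expect_equal(nrow(cleaned), 0)
  expect_equal(cleaning_report(cleaned)$n_empty_removed, 5)
})

test_that("interpolation fills interior gaps linearly, under the gap guard", {
  rec <- make_records(7)
  rec$hb <- c(9.0, NA, 10.0, NA, NA, NA, 9.4)
  out <- interpolate_gaps(rec, max_gap = 12)
  # single missing Hb flanked at 10 s spacing: linear midpoint
  expect_equal(out$hb[2], 9.5)
  expect_equal(out$hb_src[2], "interpolated")
  expect_equal(out$hb_src[1], "measured")
  # the 3-wide gap spans 20 s > max_gap: left missing
  expect_true(all(is.na(out$hb[4:6])))
  expect_true(all(is.na(out$hb_src[4:6])))
  # wider guard fills it
  out2 <- interpolate_gaps(rec, max_gap = 120)
  expect_equal(out2$hb[4:6], 10 + (9.4 - 10) * (1:3) / 4)
})

test_that("leading and trailing gaps are never invented", {
  rec <- make_records(5)
  rec$svo2 <- c(NA, 0.7, 0.72, 0.74, NA)
  out <- interpolate_gaps(rec, max_gap = 600)
  expect_true(is.na(out$svo2[1]))
  expect_true(is.na(out$svo2[5]))
  expect_false(anyNA(out$svo2[2:4]))
})

test_that("interpolation is idempotent and a no-op on complete data", {
  cohort <- small_cohort(n = 2, seed = 23)
  cleaned <- clean_records(cohort$records)
  once <- interpolate_gaps(cleaned, max_gap = 120)
  twice <- interpolate_gaps(once, max_gap = 120)
  expect_equal(as.data.frame(once), as.data.frame(twice), ignore_attr = TRUE)

  full <- make_records(20)
  out <- interpolate_gaps(full, max_gap = 120)
  expect_identical(out[, names(full)][[3]], full[[3]])
  expect_true(all(out$hb_src == "measured"))
})

test_that("interpolation never crosses patients", {
  a <- make_records(3, pid = "P001")
  b <- make_records(3, pid = "P002", t0 = "2018-06-01 08:00:20")
  a$hb[3] <- NA  # trailing within P001, adjacent in time to P002's rows
  out <- interpolate_gaps(dplyr::bind_rows(a, b), max_gap = 600)
  expect_true(is.na(out$hb[out$patient_id == "P001"][3]))
})

test_that("derived columns agree with the physiology calculators", {
  rec <- make_records(1)
  rec$flow <- 4.29
  rec$sao2 <- 1
  rec$pao2 <- 0
  profiles <- tibble::tibble(patient_id = "P001", bsa = 1.95)
  out <- derive_columns(rec, profiles)
  expect_equal(out$ci, 2.2)
  expect_equal(out$do2i, 299.2)

  cohort <- small_cohort(n = 3, seed = 24)
  platform <- cohort$records |> clean_records() |>
    interpolate_gaps() |> derive_columns(cohort$profiles)
  complete <- !is.na(platform$do2i)
  redo <- do2i(platform$flow[complete], platform$hb[complete],
               platform$sao2[complete], platform$pao2[complete],
               bsa = platform$bsa[complete])
  expect_lt(max(abs(platform$do2i[complete] - redo)), 1e-9)
  expect_equal(platform$o2er,
               (platform$sao2 - platform$svo2) / platform$sao2)
})

test_that("incomplete rows get missing derived values, unknown patients fail", {
  rec <- make_records(2)
  rec$hb[2] <- NA
  profiles <- tibble::tibble(patient_id = "P001", bsa = 1.95)
  out <- derive_columns(rec, profiles)
  expect_false(is.na(out$do2i[1]))
  expect_true(is.na(out$do2i[2]))

  rec$patient_id <- "P999"
  expect_error(derive_columns(rec, profiles), "join failure.*P999")
  expect_error(
    derive_columns(make_records(1), tibble::tibble(patient_id = "P001", bsa = NA_real_)),
    "bsa"
  )
})

test_that("end-to-end row accounting matches the corruption ledger", {
  cohort <- small_cohort(n = 5, seed = 25)
  cleaned <- clean_records(cohort$records)
  rep <- cleaning_report(cleaned)
  expect_equal(rep$n_ingested, nrow(cohort$records))
  expect_equal(rep$n_duplicates_removed, sum(cohort$ledger$n_duplicates))
  expect_equal(rep$n_empty_removed, sum(cohort$ledger$n_empty))
  expect_equal(rep$n_cleaned, sum(cohort$ledger$n_rows_true))
})
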