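# hand-built miniature relational source used across mapping tests
tiny_source <- function() {
  patients <- data.frame(
    patient_id = c("P1", "P2"),
    birth_date = as.Date(c("1950-03-01", "1942-07-15")),
    sex = c(1L, 2L),
    death_date = as.Date(c(NA, "2010-05-10")),
    stringsAsFactors = FALSE)
  visits <- data.frame(
    visit_id = c("V1", "V2", "V3", "V4"),
    patient_id = c("P1", "P1", "P1", "P2"),
    arrival = as.Date(c("2008-01-10", "2008-01-10", "2009-06-01",
                        "2010-05-01")),
    discharge = as.Date(c("2008-01-10", "2008-01-10", "2009-06-05",
                          "2010-05-10")),
    department = c("cardiology", "emergency", "cardiology", "cardiology"),
    stringsAsFactors = FALSE)
  diagnoses <- data.frame(
    visit_id = c("V1", "V3", "V4"),
    code = c("428.0", "427.31", "428.9"),
    history = c(0L, 1L, 0L),
    stringsAsFactors = FALSE)
  drugs <- data.frame(patient_id = "P1", date = as.Date("2009-06-01"),
                      atc = "C07AB02", stringsAsFactors = FALSE)
  measures <- data.frame(
    patient_id = c("P1", "P1", "P1", "P1"),
    date = as.Date(c("2008-01-10", "2008-01-10", "2009-06-01",
                     "2009-06-01")),
    name = c("height", "weight", "height", "weight"),
    value = c(171.0, 66.0, 171.0, 68.0),
    stringsAsFactors = FALSE)
  list(patients = patients, visits = visits, diagnoses = diagnoses,
       drugs = drugs, measures = measures)
}

test_that("same-day visits share date-matched clinical data", {
  tb <- map_to_ichom(tiny_source())
  raw <- tb$raw
  sameday <- raw[raw$date_of_arrival == "10/01/2008", ]
  expect_equal(nrow(sameday), 2L)
  expect_length(unique(sameday$visit_id), 2L)
  # identical clinical data: all fields except visit ID agree
  cols <- setdiff(names(raw), "visit_id")
  expect_identical(sameday[1, cols], sameday[2, cols],
                   ignore_attr = "row.names")
  expect_equal(uniqueness_result2(tb)$numerator, 2)
})

test_that("discordant same-day weights create partial duplicates", {
  src <- tiny_source()
  src$measures <- rbind(src$measures,
                        data.frame(patient_id = "P1",
                                   date = as.Date("2009-06-01"),
                                   name = "weight", value = 69.3))
  tb <- map_to_ichom(src)
  v3 <- tb$raw[tb$raw$visit_id == "V3", ]
  expect_equal(nrow(v3), 2L)
  expect_setequal(v3$weight, c("68", "69.3"))
  expect_length(unique(v3$height), 1L)
  expect_equal(uniqueness_result1(tb)$numerator, 2)
})

test_that("unmeasured visits are zero-coded and deaths stay in-visit", {
  tb <- map_to_ichom(tiny_source())
  raw <- tb$raw
  v4 <- raw[raw$visit_id == "V4", ]
  expect_identical(v4$height, "0")
  expect_identical(v4$weight, "0")
  expect_identical(v4$date_of_death, "10/05/2010") # died during V4
  expect_true(all(raw$date_of_death[raw$visit_id != "V4"] == ""))
})

test_that("condition flags are cumulative 0/1, 999 only in strict mode", {
  tb <- map_to_ichom(tiny_source())
  raw <- tb$raw
  # AF diagnosed at V3 (2009): absent at earlier visits, present from V3 on
  expect_identical(raw$atrial_fibrillation[raw$visit_id %in% c("V1", "V2")],
                   c("0", "0"))
  expect_identical(raw$atrial_fibrillation[raw$visit_id == "V3"], "1")
  expect_false(any(raw$atrial_fibrillation == "999"))
  strict <- map_to_ichom(tiny_source(), strict_history = TRUE)
  expect_identical(
    strict$raw$atrial_fibrillation[strict$raw$visit_id == "V1"], "999")
  expect_identical(
    strict$raw$atrial_fibrillation[strict$raw$visit_id == "V3"], "1")
})

test_that("treatment flags come from ATC prefix matches on the visit date", {
  tb <- map_to_ichom(tiny_source())
  raw <- tb$raw
  expect_identical(raw$beta_blocker[raw$visit_id == "V3"], "1")
  expect_true(all(raw$beta_blocker[raw$visit_id != "V3"] == "0"))
  expect_true(all(raw$digoxin == "0"))
})

test_that("burden-of-care counts reflect the prior 365 days", {
  tb <- map_to_ichom(tiny_source())
  raw <- tb$raw
  # V3 (2009-06-01): the two 2008-01-10 appointments fall outside 365 days
  expect_identical(raw$hospital_admissions[raw$visit_id == "V3"], "0")
  expect_identical(raw$hospital_appointments[raw$visit_id == "V3"], "0")
  src <- tiny_source()
  src$visits$arrival[3] <- as.Date("2008-06-01")
  src$visits$discharge[3] <- as.Date("2008-06-05")
  tb2 <- map_to_ichom(src)
  expect_identical(
    tb2$raw$hospital_appointments[tb2$raw$visit_id == "V3"], "2")
})

test_that("cohort selection keeps exactly HF-coded patients", {
  src <- tiny_source()
  # strip P2's HF code: only P1 (via V1, 428.0) qualifies
  src$diagnoses <- src$diagnoses[src$diagnoses$visit_id != "V4", ]
  kept <- select_cohort(src)
  expect_identical(kept$patients$patient_id, "P1")
  expect_setequal(kept$visits$visit_id, c("V1", "V2", "V3"))
  expect_true(all(kept$measures$patient_id == "P1"))
  # all HF-coded: identity
  all_kept <- select_cohort(tiny_source())
  expect_setequal(all_kept$patients$patient_id, c("P1", "P2"))
  src$diagnoses <- src$diagnoses[0, ]
  expect_warning(empty <- select_cohort(src), "no patients")
  expect_equal(nrow(empty$patients), 0L)
})

test_that("dangling foreign keys abort the mapping with offenders named", {
  src <- tiny_source()
  src$diagnoses$visit_id[1] <- "V999"
  expect_error(map_to_ichom(src), "V999")
  src2 <- tiny_source()
  src2$visits$patient_id[1] <- "P999"
  expect_error(map_to_ichom(src2), "P999")
})

test_that("a clean generated source maps to perfect structural scores", {
  cfg <- generator_config(n_patients = 120, seed = 19, same_day_rate = 0,
                          duplicate_measure_rate = 0, measure_prob = 1,
                          regime_shift = NULL, thin_months = NULL,
                          errors = zero_errors())
  src <- select_cohort(generate_source(cfg)$source)
  tb <- map_to_ichom(src)
  # left-spine conservation: every cohort visit appears in >= 1 output row
  expect_setequal(unique(tb$raw$visit_id), src$visits$visit_id)
  expect_equal(uniqueness_result1(tb)$score, 100)
  expect_equal(uniqueness_result2(tb)$score, 100)
  expect_equal(consistency_by_type(tb)$score, 100)
  expect_equal(consistency_by_range(tb)$score, 100)
  expect_equal(consistency_by_rules(tb)$score, 100)
  expect_equal(completeness(tb)$score, 100)
})

test_that("mapped output row order is the documented stable sort", {
  cfg <- generator_config(n_patients = 40, seed = 23)
  src <- generate_source(cfg)$source
  tb <- map_to_ichom(src)
  arr <- as.Date(tb$raw$date_of_arrival, format = "%d/%m/%Y")
  ord <- order(tb$raw$patient_id, arr, tb$raw$visit_id)
  expect_identical(ord, seq_along(ord))
})
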