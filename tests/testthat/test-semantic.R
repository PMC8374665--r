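# table with explicit arrival months and one indicator column
series_table <- function(months, values, patient = NULL) {
  n <- length(months)
  r <- data.frame(
    patient_id = if (is.null(patient)) sprintf("P%d", seq_len(n)) else patient,
    visit_id = sprintf("V%d", seq_len(n)),
    date_of_birth = "01/01/1950", sex = "1",
    atrial_fibrillation = as.character(values), prior_mi = "0",
    hypertension = "0", diabetes_mellitus = "0", echocardiogram = "0",
    height = "170", weight = "70", alcohol_use = "0", smoking_status = "0",
    beta_blocker = "0", calcium_channel_blocker = "0", digoxin = "0",
    diuretics = "0",
    date_of_arrival = format(as.Date(paste0(months, "-15")), "%d/%m/%Y"),
    date_of_discharge = format(as.Date(paste0(months, "-16")), "%d/%m/%Y"),
    hospital_admissions = "0", hospital_appointments = "0",
    date_of_death = "", stringsAsFactors = FALSE)
  visit_table(r)
}

test_that("monthly frequencies bin by arrival month with 999 in the
          denominator only", {
  months <- c(rep("2010-03", 40), rep("2010-04", 7))
  values <- c(rep("1", 10), rep("0", 25), rep("999", 5), rep("0", 7))
  ms <- monthly_frequency(series_table(months, values),
                          "atrial_fibrillation")
  mar <- ms[ms$month == as.Date("2010-03-01"), ]
  expect_equal(mar$denominator, 40)
  expect_equal(mar$numerator, 10)
  expect_equal(mar$frequency, 0.25)
  expect_false(mar$low_support)
  apr <- ms[ms$month == as.Date("2010-04-01"), ]
  expect_true(apr$low_support) # 7 records < default threshold 10
  # empty months inside the window are present with undefined frequency
  may <- ms[ms$month == as.Date("2010-05-01"), ]
  expect_equal(may$denominator, 0)
  expect_true(is.na(may$frequency))
  expect_equal(nrow(ms), 143) # every month of the window
  expect_equal(sum(ms$denominator), 47)
})

test_that("a constant-1 indicator is 1.0 in every supported month", {
  months <- rep(sprintf("2010-%02d", 1:6), each = 15)
  ms <- monthly_frequency(series_table(months, "1"), "atrial_fibrillation")
  expect_true(all(ms$frequency[!is.na(ms$frequency)] == 1))
})

test_that("detect_shift localises a planted regime change and stays quiet
          otherwise", {
  mk <- function(freqs) {
    # 60 records per month across 2008-2013 with the given monthly P(1)
    months <- format(seq(as.Date("2008-01-01"), as.Date("2013-12-01"),
                         by = "month"), "%Y-%m")
    set.seed(99)
    mm <- rep(months, each = 60)
    vv <- stats::rbinom(length(mm), 1, rep(freqs, each = 60))
    monthly_frequency(series_table(mm, vv), "atrial_fibrillation")
  }
  nm <- length(seq(as.Date("2008-01-01"), as.Date("2013-12-01"),
                   by = "month"))
  drop_at <- which(format(seq(as.Date("2008-01-01"), by = "month",
                              length.out = nm), "%Y-%m") == "2011-01")
  f <- c(rep(0.3, drop_at - 1), rep(0.09, nm - drop_at + 1))
  sh <- detect_shift(mk(f))
  expect_false(is.null(sh))
  expect_lte(abs(as.numeric(sh$month - as.Date("2011-01-01"))), 31)
  # constant series: nothing to report
  expect_null(detect_shift(mk(rep(0.3, nm))))
  # gentle monotone trend below the relative-change threshold
  expect_null(detect_shift(mk(seq(0.30, 0.36, length.out = nm))))
})

test_that("bmi follows the metric formula and its monotonicities", {
  expect_equal(bmi(170, 65), 22.49, tolerance = 1e-3)
  expect_equal(bmi(100, 100), 100)
  expect_true(is.na(bmi(0, 70)))  # zero-coded height: excluded
  expect_true(is.na(bmi(170, NA)))
  h <- seq(150, 200, by = 5)
  expect_true(all(diff(bmi(h, 80)) < 0))
  w <- seq(50, 120, by = 5)
  expect_true(all(diff(bmi(170, w)) > 0))
})

test_that("bmi plausibility flags <10 and >70 over all records", {
  r <- series_table(rep("2010-03", 5), "0")$raw
  r$height <- c("65", "180", "0", "190", "abc")
  r$weight <- c("170", "80", "70", "25", "70")
  res <- bmi_plausibility(visit_table(r))
  cnt <- attr(res, "counts")
  expect_equal(unname(cnt["n_high"]), 1L) # 170/0.65^2 = 402
  expect_equal(unname(cnt["n_low"]), 1L)  # 25/1.90^2 = 6.9
  expect_equal(unname(cnt["n_skipped"]), 2L) # zero-coded + unparseable
  expect_equal(res$numerator, 2)
  expect_equal(res$denominator, 5)
})

test_that("inversion candidates require weight above height and label
          plausible swaps", {
  r <- series_table(rep("2010-03", 4), "0")$raw
  r$height <- c("65", "170", "150", "0")
  r$weight <- c("170", "65", "160", "80")
  inv <- inversion_candidates(visit_table(r))
  expect_setequal(inv$record, c(1L, 3L))
  expect_equal(inv$swapped_bmi[inv$record == 1], 22.49, tolerance = 1e-3)
  expect_true(inv$swap_plausible[inv$record == 1])
  expect_equal(round(inv$swapped_bmi[inv$record == 3], 1), 58.6)
  expect_true(inv$swap_plausible[inv$record == 3])
})

test_that("temporal-order violations follow the stated enumeration rule", {
  seqs <- list(list(v = c(0, 1, 1, 0, 1), expected = 1),
               list(v = c(1, 0, 0), expected = 2),
               list(v = c(0, 0, 1), expected = 0),
               list(v = c(1, 999, 0), expected = 1),  # 999 does not reset
               list(v = c(999, 0, 1), expected = 0))
  for (s in seqs) {
    months <- sprintf("2010-%02d", seq_along(s$v))
    tb <- series_table(months, s$v, patient = rep("P1", length(s$v)))
    res <- history_order_violations(tb, "atrial_fibrillation")
    expect_equal(res$numerator, s$expected,
                 info = paste(s$v, collapse = ","))
  }
})

test_that("order violations match a per-patient brute-force scan and are
          order invariant", {
  raw <- random_raw_table(120, seed = 7)
  tb <- visit_table(raw)
  res <- history_order_violations(tb)
  for (nm in c("atrial_fibrillation", "hypertension", "diabetes_mellitus",
               "prior_mi")) {
    expect_equal(res$per_variable$numerator[res$per_variable$variable == nm],
                 oracle_history_violations(raw, nm), info = nm)
  }
  set.seed(2)
  perm <- sample(nrow(raw))
  res2 <- history_order_violations(visit_table(raw[perm, ]))
  expect_equal(res2$per_variable$numerator, res$per_variable$numerator)
})

test_that("planted history flips are recovered exactly in exact mode and
          within binomial error in rate mode", {
  cfg <- generator_config(
    n_patients = 250, seed = 13, regime_shift = NULL, thin_months = NULL,
    errors = zero_errors(history_flip = err_plan(n = 9)))
  tb <- generate_visit_table(clean_config(n_patients = 250, seed = 13))
  pl <- plant_errors(tb, cfg)
  res <- history_order_violations(pl$table)
  expect_true(all(res$per_variable$numerator == 9))
  expect_equal(res$numerator, sum(pl$ledger$class == "history_flip"))

  cfgr <- generator_config(
    n_patients = 800, seed = 29, mode = "rate", regime_shift = NULL,
    thin_months = NULL,
    errors = zero_errors(history_flip = err_plan(p = 0.3)))
  tbr <- generate_visit_table(clean_config(n_patients = 800, seed = 29))
  plr <- plant_errors(tbr, cfgr)
  resr <- history_order_violations(plr$table)
  expect_equal(resr$numerator, sum(plr$ledger$class == "history_flip"))
})
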