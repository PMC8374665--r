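# minimal well-formed raw row used to hand-build tables
blank_row <- function() {
  data.frame(
    patient_id = "P1", visit_id = "V1", date_of_birth = "01/01/1950",
    sex = "1", atrial_fibrillation = "0", prior_mi = "0",
    hypertension = "0", diabetes_mellitus = "0", echocardiogram = "0",
    height = "170", weight = "70", alcohol_use = "0", smoking_status = "0",
    beta_blocker = "0", calcium_channel_blocker = "0", digoxin = "0",
    diuretics = "0", date_of_arrival = "05/03/2010",
    date_of_discharge = "08/03/2010", hospital_admissions = "0",
    hospital_appointments = "0", date_of_death = "",
    stringsAsFactors = FALSE)
}

rows <- function(n) {
  r <- blank_row()[rep(1, n), ]
  r$visit_id <- sprintf("V%d", seq_len(n))
  r$patient_id <- sprintf("P%d", seq_len(n))
  rownames(r) <- NULL
  r
}

test_that("uniqueness result 1 counts shared-ID records with differing
          content and excludes exact duplicates", {
  r <- rows(6)
  expect_equal(uniqueness_result1(visit_table(r))$score, 100)
  # a colliding pair differing in weight: both members count
  r$visit_id[2] <- r$visit_id[1]
  r$weight[2] <- "71"
  res <- uniqueness_result1(visit_table(r))
  expect_equal(res$numerator, 2)
  expect_equal(res$score, round(100 * (1 - 2 / 6), 2))
  # an exact full duplicate does not count toward result 1
  r2 <- rows(6)
  r2[2, ] <- r2[1, ]
  res2 <- uniqueness_result1(visit_table(r2))
  expect_equal(res2$numerator, 0)
  expect_equal(sum(res2$findings$check == "uniqueness_exact_duplicate"), 2)
})

test_that("uniqueness result 2 needs same day, same clinical data and a
          different visit ID", {
  r <- rows(6)
  expect_equal(uniqueness_result2(visit_table(r))$score, 100)
  # same patient, same day, identical clinical data, different IDs
  r[2, ] <- r[1, ]
  r$visit_id[2] <- "V2"
  res <- uniqueness_result2(visit_table(r))
  expect_equal(res$numerator, 2)
  # a same-day pair differing in smoking status is not counted
  r$smoking_status[2] <- "1"
  expect_equal(uniqueness_result2(visit_table(r))$numerator, 0)
})

test_that("planted duplicate scores reproduce the published arithmetic", {
  tb <- clean_table_of_size(1000, seed = 55)
  cfg <- generator_config(
    n_patients = 10, seed = 55, regime_shift = NULL, thin_months = NULL,
    errors = zero_errors(duplicate_id = err_plan(n = 12)))
  pl <- plant_errors(visit_table(tb$raw[seq_len(988), ]), cfg)
  res <- uniqueness_result1(pl$table)
  expect_equal(n_visits(pl$table), 1000L)
  expect_equal(res$numerator, 12)
  expect_equal(res$score, 98.8)
})

test_that("type consistency scores per variable and averages over them", {
  r <- rows(10)
  expect_equal(consistency_by_type(visit_table(r))$score, 100)
  r$height[1] <- "abc"
  res <- consistency_by_type(visit_table(r))
  per <- res$per_variable
  expect_equal(per$score[per$variable == "height"], 90)
  expect_true(all(per$score[per$variable != "height"] == 100))
  expect_equal(res$score, round(mean(per$score), 2))
  # an all-missing column is vacuous: scores 100 with a warning flag
  r2 <- rows(10)
  r2$smoking_status <- ""
  res2 <- consistency_by_type(visit_table(r2))
  expect_equal(res2$per_variable$score[
    res2$per_variable$variable == "smoking_status"], 100)
  expect_true("vacuous_denominator" %in% res2$flags)
})

test_that("range consistency flags zeros, early dates and illegal codes", {
  r <- rows(10)
  r$height[1] <- "0"          # zero-coded measurement
  r$date_of_arrival[2] <- "31/12/2005" # before the window start
  r$sex[3] <- "3"             # outside {1, 2}
  r$hospital_admissions[4] <- "-1"
  r$date_of_death[5] <- "999" # legal unknown code: not a violation
  res <- consistency_by_range(visit_table(r))
  per <- res$per_variable
  viol <- per$variable[per$numerator > 0]
  expect_setequal(viol, c("height", "date_of_arrival", "sex",
                          "hospital_admissions"))
  expect_true(all(per$numerator[per$variable %in% viol] == 1))
  expect_equal(sum(res$findings$variable == "height"), 1)
})

test_that("rule consistency counts evaluable records only", {
  r <- rows(10)
  r$date_of_arrival[1] <- "05/03/2010"
  r$date_of_discharge[1] <- "01/03/2010" # arrival after discharge
  r$date_of_discharge[2] <- "05/03/2010"
  r$date_of_arrival[2] <- "05/03/2010"   # equal dates: allowed
  r$date_of_discharge[3] <- ""           # not evaluable
  res <- consistency_by_rules(visit_table(r))
  expect_equal(res$numerator, 1)
  expect_equal(res$denominator, 9)
  # death before discharge violates the second default rule
  r2 <- rows(4)
  r2$date_of_death[1] <- "08/03/2010"  # equal to discharge: fine
  r2$date_of_death[2] <- "01/03/2010"  # before discharge: violation
  res2 <- consistency_by_rules(visit_table(r2))
  expect_equal(res2$numerator, 1)
})

test_that("consistency aggregates by unweighted mean", {
  expect_equal(consistency_overall(list(100, 100, 91.21)), 97.07)
  expect_equal(consistency_overall(list(100, 100, 100)), 100)
  expect_equal(consistency_overall(list(0, 0, 0)), 0)
})

test_that("completeness averages variables and honours valid
          incompleteness", {
  r <- rows(10)
  r$date_of_death <- ""
  r$smoking_status[1:3] <- ""
  res <- completeness(visit_table(r))
  per <- res$per_variable
  expect_equal(per$score[per$variable == "smoking_status"], 70)
  # nobody died during a visit: the death-date denominator is empty
  expect_equal(per$denominator[per$variable == "date_of_death"], 0)
  expect_equal(per$score[per$variable == "date_of_death"], 100)
  expect_equal(per$raw_rate[per$variable == "date_of_death"], 0)
  # unknown codes count as complete but are reported separately
  r2 <- rows(10)
  r2$alcohol_use <- "999"
  res2 <- completeness(visit_table(r2))
  per2 <- res2$per_variable
  expect_equal(per2$score[per2$variable == "alcohol_use"], 100)
  expect_equal(per2$unknown_rate[per2$variable == "alcohol_use"], 100)
  # an explicit expected-present mask makes the rule falsifiable
  mask <- rep(FALSE, 10); mask[4] <- TRUE
  res3 <- completeness(visit_table(r), exclusions = list(date_of_death = mask))
  per3 <- res3$per_variable
  expect_equal(per3$score[per3$variable == "date_of_death"], 0)
})

test_that("scores obey the score algebra and monotonicity", {
  tb <- generate_visit_table(clean_config(n_patients = 60, seed = 91))
  for (res in list(uniqueness_result1(tb), uniqueness_result2(tb),
                   consistency_by_rules(tb))) {
    expect_gte(res$score, 0); expect_lte(res$score, 100)
    expect_equal(res$score,
                 round(100 * (1 - res$numerator / max(1, res$denominator)),
                       2))
  }
  # adding one violating record never increases the score
  r <- tb$raw
  r2 <- rbind(r, r[1, ])
  r2$visit_id[nrow(r2)] <- r$visit_id[1]
  r2$weight[nrow(r2)] <- "71.5"
  expect_lt(uniqueness_result1(visit_table(r2))$score,
            uniqueness_result1(tb)$score)
})

test_that("all structural checks are row-order invariant", {
  raw <- random_raw_table(80, seed = 17)
  tb <- visit_table(raw)
  set.seed(1)
  perm <- sample(nrow(raw))
  tbp <- visit_table(raw[perm, ])
  for (f in list(uniqueness_result1, uniqueness_result2,
                 consistency_by_type, consistency_by_range,
                 consistency_by_rules, completeness,
                 history_order_violations)) {
    a <- f(tb); b <- f(tbp)
    expect_equal(a$numerator, b$numerator)
    expect_equal(a$score, b$score)
  }
})

test_that("numerators match brute-force recounts on random tables", {
  for (seed in c(101, 202, 303)) {
    raw <- random_raw_table(60, seed = seed)
    tb <- visit_table(raw)
    expect_equal(uniqueness_result1(tb)$numerator, oracle_uniqueness1(raw),
                 info = paste("seed", seed))
    expect_equal(uniqueness_result2(tb)$numerator, oracle_uniqueness2(raw),
                 info = paste("seed", seed))
    type_counts <- oracle_type_counts(tb)
    expect_equal(consistency_by_type(tb)$per_variable$numerator,
                 unname(type_counts), info = paste("seed", seed))
    miss <- oracle_completeness_counts(raw)
    per <- completeness(tb)$per_variable
    plain <- per$variable != "date_of_death"
    expect_equal(per$numerator[plain], unname(miss[per$variable[plain]]),
                 info = paste("seed", seed))
  }
})
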