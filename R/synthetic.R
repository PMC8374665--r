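# Seeded synthetic generator: a clean flat ICHOM visit table emulating the
# mapped extract of a hospital EHR, plus an error-planting step that records
# every planted defect in a ground-truth ledger.

# Class-local RNG substreams: each generation stage re-seeds from a seed
# derived from (master seed, stage index), so disabling one error class does
# not perturb the draws of another.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 7919) %% 2147483629L)
}

#' Error-class plan
#'
#' Specifies how one error class is planted: an exact row count (`n`) or an
#' independent per-row probability (`p`). Exact counts give bit-exact
#' recovery tests; rates give realistic stochastic contamination.
#'
#' @param n Exact number of affected rows (even for the duplicate-pair
#'   classes), or `NULL`.
#' @param p Per-row probability in `[0, 1]`, or `NULL`.
#' @return A plan list used in `generator_config(errors = ...)`.
#' @export
err_plan <- function(n = NULL, p = NULL) {
  if (!is.null(n)) stopifnot(length(n) == 1L, n >= 0)
  if (!is.null(p)) stopifnot(length(p) == 1L, p >= 0, p <= 1)
  list(n = n, p = p)
}

#' Synthetic-generator configuration
#'
#' Defaults mirror the documented study conditions: a 2006-01-01..2017-11-07
#' visit window; 85% of height/weight fields zero-coded; 54 out-of-range
#' heights, 20 out-of-range weights and 16 pre-window arrival dates; BMI
#' error counts 16 (low) and 180 (high); partial-duplicate rates 1.2%
#' (shared visit identifiers) and 2.8% (same-day clones); an abrupt
#' documentation-practice shift for past medical conditions at 2011-01-01
#' (frequency multiplier 0.3); a gradual increase in medication recording;
#' and months thinned below 10 records in the first half of 2016. Cohort
#' size and per-patient visit counts default to a desk-scale table
#' (1,000 patients, geometric visits with mean 4); demographics (ages 40-95,
#' ~55% male) are unconstrained defaults.
#'
#' @param n_patients Number of patients.
#' @param mean_visits Mean visits per patient (1 + geometric).
#' @param window Length-2 extraction window (start, end).
#' @param seed Master RNG seed (integer).
#' @param mode `"exact_count"` (bit-exact planted counts) or `"rate"`
#'   (independent per-row planting).
#' @param death_probability Probability that a patient dies during their
#'   final visit (writes the date of death on that record only).
#' @param condition_prevalence Named per-condition prevalences.
#' @param condition_recording Base probability that a visit of a
#'   condition-positive patient (after onset) records the history flag.
#' @param condition_onset `"uniform"`: onset at a uniformly drawn visit of
#'   the patient (visits before it are honest 0s); `"first_visit"`: the
#'   condition predates cohort entry, so every visit is eligible (makes the
#'   per-visit flag frequency exactly prevalence x recording probability).
#' @param regime_shift `list(date =, multiplier =)` applied to the
#'   condition-recording probability from the shift date onward, or `NULL`.
#' @param medication_base,medication_slope Named per-drug base monthly
#'   recording probability and per-month linear slope.
#' @param thin_months `list(months = <"YYYY-MM" character>, factor =)` visit
#'   thinning, or `NULL`.
#' @param same_day_rate Probability that a visit spawns a second same-day
#'   visit in another department (relational source only).
#' @param duplicate_measure_rate Probability that a visit date carries two
#'   distinct weight measurements (relational source only).
#' @param measure_prob Probability that height/weight were measured on a
#'   visit date (relational source; unmeasured visits are zero-coded by the
#'   mapper).
#' @param errors Named list of error-class plans, each `err_plan(n =)` or
#'   `err_plan(p =)`: `zero_height_weight`, `out_of_range_height`,
#'   `out_of_range_weight`, `early_arrival_dates`, `hw_inversion`,
#'   `low_bmi`, `high_bmi`, `duplicate_id`, `same_day_duplicate`,
#'   `history_flip`.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 1000,
                             mean_visits = 4,
                             window = c("2006-01-01", "2017-11-07"),
                             seed = 1L,
                             mode = c("exact_count", "rate"),
                             death_probability = 0.3,
                             condition_prevalence = c(
                               atrial_fibrillation = 0.35, hypertension = 0.6,
                               diabetes_mellitus = 0.4, prior_mi = 0.25,
                               echocardiogram = 0.5, alcohol_use = 0.15,
                               smoking_status = 0.25),
                             condition_recording = 1,
                             condition_onset = c("uniform", "first_visit"),
                             regime_shift = list(date = "2011-01-01",
                                                 multiplier = 0.3),
                             medication_base = c(
                               beta_blocker = 0.2, calcium_channel_blocker = 0.15,
                               digoxin = 0.1, diuretics = 0.25),
                             medication_slope = c(
                               beta_blocker = 0.002, calcium_channel_blocker = 0.0005,
                               digoxin = 0.0002, diuretics = 0.0015),
                             thin_months = list(
                               months = sprintf("2016-%02d", 1:6),
                               factor = 0.1),
                             same_day_rate = 0.02,
                             duplicate_measure_rate = 0.01,
                             measure_prob = 0.15,
                             errors = list()) {
  mode <- match.arg(mode)
  condition_onset <- match.arg(condition_onset)
  window <- as.Date(window)
  stopifnot(n_patients >= 1, mean_visits >= 1, window[1] < window[2],
            death_probability >= 0, death_probability <= 1)
  defaults <- list(
    zero_height_weight = err_plan(p = 0.85),
    out_of_range_height = err_plan(n = 54),
    out_of_range_weight = err_plan(n = 20),
    early_arrival_dates = err_plan(n = 16),
    hw_inversion = err_plan(n = 0),
    low_bmi = err_plan(n = 16),
    high_bmi = err_plan(n = 180),
    duplicate_id = err_plan(p = 0.012),
    same_day_duplicate = err_plan(p = 0.028),
    history_flip = err_plan(n = 0))
  unknown <- setdiff(names(errors), names(defaults))
  if (length(unknown))
    stop("unknown error class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults[names(errors)] <- errors
  structure(
    list(n_patients = as.integer(n_patients), mean_visits = mean_visits,
         window = window, seed = as.integer(seed), mode = mode,
         death_probability = death_probability,
         condition_prevalence = condition_prevalence,
         condition_recording = condition_recording,
         condition_onset = condition_onset,
         regime_shift = regime_shift,
         medication_base = medication_base,
         medication_slope = medication_slope,
         thin_months = thin_months, same_day_rate = same_day_rate,
         duplicate_measure_rate = duplicate_measure_rate,
         measure_prob = measure_prob, errors = defaults),
    class = "generator_config")
}

fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%d/%m/%Y"))
fmt_num <- function(x, digits = 1) {
  out <- formatC(round(x, digits), format = "fg", digits = 15)
  trimws(out)
}

months_since <- function(dates, start) {
  12L * (as.integer(format(dates, "%Y")) - as.integer(format(start, "%Y"))) +
    (as.integer(format(dates, "%m")) - as.integer(format(start, "%m")))
}

# Per-visit recording probability of a condition history flag, with the
# documentation-practice regime shift applied from its date onward.
recording_prob <- function(dates, config) {
  p <- rep(config$condition_recording, length(dates))
  rs <- config$regime_shift
  if (!is.null(rs) && !is.null(rs$date)) {
    sd <- as.Date(rs$date)
    if (sd <= config$window[2]) p[dates >= sd] <- p[dates >= sd] * rs$multiplier
  }
  pmin(pmax(p, 0), 1)
}

# Visit-date sampling weights over the window, honouring thinned months.
day_weights <- function(days, config) {
  w <- rep(1, length(days))
  tm <- config$thin_months
  if (!is.null(tm) && length(tm$months))
    w[format(days, "%Y-%m") %in% tm$months] <- tm$factor
  w
}

#' Generate a clean flat ICHOM visit table
#'
#' Builds the fully documented visit-centered table the error planter and the
#' checks consume: one row per visit, every field populated (date of death
#' only on records where the patient died during the visit), heights and
#' weights drawn from truncated normals inside their plausibility ranges,
#' hospital admission/appointment counts computed from each patient's own
#' visit history, condition flags driven by per-visit recording probabilities
#' (including the regime shift) and medication flags by linear monthly
#' trends. Deterministic under the configuration seed.
#'
#' @param config A [generator_config()].
#' @return A [visit_table()] with attribute `truth`: a list with `died`
#'   (logical per record: patient died during that visit) and
#'   `condition_ever` (logical patient-condition matrix expanded per record).
#' @export
generate_visit_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  win <- config$window
  days <- seq(win[1], win[2], by = "day")
  wts <- day_weights(days, config)

  set.seed(sub_seed(config$seed, 1L))
  np <- config$n_patients
  nv <- 1L + stats::rgeom(np, prob = 1 / config$mean_visits)
  pid <- sprintf("P%05d", seq_len(np))

  # visit dates: distinct days per patient, weighted by monthly volume
  set.seed(sub_seed(config$seed, 2L))
  arr_list <- lapply(nv, function(k)
    sort(sample(days, min(k, length(days)), replace = FALSE, prob = wts)))
  nv <- lengths(arr_list)
  arrival <- as.Date(unlist(arr_list), origin = "1970-01-01")
  patient <- rep(pid, nv)
  n <- length(arrival)

  set.seed(sub_seed(config$seed, 3L))
  same_day <- stats::runif(n) < 0.6
  stay <- ifelse(same_day, 0L, sample(1:14, n, replace = TRUE))
  # a discharge date recorded in the extract cannot postdate the extraction
  discharge <- pmin(arrival + stay, win[2])
  visit_id <- sprintf("V%07d", seq_len(n))

  set.seed(sub_seed(config$seed, 4L))
  sex <- ifelse(stats::runif(np) < 0.55, 1L, 2L)
  age_first <- stats::runif(np, 40, 95)
  first_arr <- as.Date(vapply(arr_list, function(a) as.numeric(a[1]),
                              numeric(1)), origin = "1970-01-01")
  birth <- first_arr - round(age_first * 365.25)

  # truncated normals keep every clean BMI inside (10, 70)
  set.seed(sub_seed(config$seed, 5L))
  height <- pmin(pmax(stats::rnorm(n, 165, 10), 145), 200)
  weight <- pmin(pmax(stats::rnorm(n, 75, 15), 45), 130)

  set.seed(sub_seed(config$seed, 6L))
  died <- stats::runif(np) < config$death_probability
  # death occurs during the final visit; the date is the discharge date
  last_idx <- cumsum(nv)
  death_row <- rep(FALSE, n)
  death_row[last_idx[died]] <- TRUE
  date_of_death <- as.Date(rep(NA_real_, n), origin = "1970-01-01")
  date_of_death[death_row] <- discharge[death_row]

  tmon <- months_since(arrival, win[1])
  flags <- list()
  cond_ever <- list()
  ki <- 10L
  recp <- recording_prob(arrival, config)
  visit_idx_in_patient <- sequence(nv)
  for (nm in names(config$condition_prevalence)) {
    ki <- ki + 1L
    set.seed(sub_seed(config$seed, ki))
    has <- stats::runif(np) < config$condition_prevalence[[nm]]
    onset <- if (config$condition_onset == "first_visit") rep(1L, np) else
      ceiling(stats::runif(np) * nv) # visit index of onset
    has_v <- rep(has, nv)
    onset_v <- rep(onset, nv)
    eligible <- has_v & visit_idx_in_patient >= onset_v
    flag <- integer(n)
    flag[eligible] <- as.integer(stats::runif(sum(eligible)) < recp[eligible])
    flags[[nm]] <- flag
    cond_ever[[nm]] <- has_v
  }
  meds <- list()
  for (nm in names(config$medication_base)) {
    ki <- ki + 1L
    set.seed(sub_seed(config$seed, ki))
    p <- pmin(pmax(config$medication_base[[nm]] +
                     config$medication_slope[[nm]] * tmon, 0), 1)
    meds[[nm]] <- as.integer(stats::runif(n) < p)
  }

  counts <- visit_burden_counts(patient, arrival, discharge)

  raw <- data.frame(
    patient_id = patient,
    visit_id = visit_id,
    date_of_birth = fmt_date(rep(birth, nv)),
    sex = as.character(rep(sex, nv)),
    atrial_fibrillation = as.character(flags$atrial_fibrillation),
    prior_mi = as.character(flags$prior_mi),
    hypertension = as.character(flags$hypertension),
    diabetes_mellitus = as.character(flags$diabetes_mellitus),
    echocardiogram = as.character(flags$echocardiogram),
    height = fmt_num(height),
    weight = fmt_num(weight),
    alcohol_use = as.character(flags$alcohol_use),
    smoking_status = as.character(flags$smoking_status),
    beta_blocker = as.character(meds$beta_blocker),
    calcium_channel_blocker = as.character(meds$calcium_channel_blocker),
    digoxin = as.character(meds$digoxin),
    diuretics = as.character(meds$diuretics),
    date_of_arrival = fmt_date(arrival),
    date_of_discharge = fmt_date(discharge),
    hospital_admissions = as.character(counts$admissions),
    hospital_appointments = as.character(counts$appointments),
    date_of_death = fmt_date(date_of_death),
    stringsAsFactors = FALSE)

  tbl <- visit_table(raw, default_dictionary(),
                     source = sprintf("synthetic seed %d", config$seed),
                     window = win)
  attr(tbl, "truth") <- list(died = death_row,
                             condition_ever = as.data.frame(cond_ever))
  tbl
}

# Hospitalisations (overnight visits) and same-day appointments of the same
# patient in the 365 days before each arrival.
visit_burden_counts <- function(patient, arrival, discharge) {
  n <- length(arrival)
  admissions <- appointments <- integer(n)
  overnight <- discharge != arrival
  for (idx in split(seq_len(n), patient)) {
    a <- as.numeric(arrival[idx])
    for (j in seq_along(idx)) {
      prior <- a >= a[j] - 365 & a < a[j]
      admissions[idx[j]] <- sum(prior & overnight[idx])
      appointments[idx[j]] <- sum(prior & !overnight[idx])
    }
  }
  list(admissions = admissions, appointments = appointments)
}

# Number of affected rows for a class: exact count, or binomial draw in rate
# mode ("each row independently affected"); `even` forces pair classes.
class_count <- function(plan, n_eligible, mode, class, even = FALSE) {
  if (mode == "exact_count" && !is.null(plan$n)) {
    k <- as.integer(plan$n)
  } else if (!is.null(plan$p)) {
    k <- stats::rbinom(1L, n_eligible, plan$p)
  } else if (!is.null(plan$n)) {
    k <- as.integer(plan$n)
  } else {
    k <- 0L
  }
  if (even) k <- (k %/% 2L) * 2L
  if (k > n_eligible && !even)
    stop(sprintf("config error: %s requests %d rows but only %d eligible",
                 class, k, n_eligible), call. = FALSE)
  k
}

ledger_row <- function(class, row, visit_id, variable, true_value) {
  data.frame(class = class, row = as.integer(row),
             visit_id = as.character(visit_id),
             variable = as.character(variable),
             true_value = as.character(true_value),
             stringsAsFactors = FALSE)
}

empty_ledger <- function() {
  ledger_row(character(0), integer(0), character(0), character(0),
             character(0))
}

#' Plant data errors into a clean flat visit table
#'
#' Applies the configured error classes and records every affected row with
#' its pre-error value in a ground-truth ledger. In-place classes modify
#' existing rows: height/weight zero-coding, out-of-range heights/weights,
#' pre-window arrival dates, height/weight value inversions (swapping the two
#' fields), low/high implausible-BMI pairs, and history flips (a later
#' history flag 1 rewritten to 0 for a patient with an earlier recorded 1).
#' Duplicate classes append rows: `duplicate_id` adds pairs sharing a fresh
#' visit identifier but differing in weight; `same_day_duplicate` adds
#' same-patient same-day pairs with identical clinical data under two fresh
#' visit identifiers. Classes draw from disjoint row pools; in
#' `exact_count` mode exactly the requested number of rows is affected per
#' class.
#'
#' @param table A clean [visit_table()] (no pre-existing planted errors).
#' @param config A [generator_config()]; only its `errors`, `mode` and
#'   `seed` are used here.
#' @return A list with `table` (the modified `visit_table`) and `ledger`
#'   (data.frame: `class`, `row` index into the returned table, `visit_id`,
#'   `variable`, `true_value`).
#' @export
plant_errors <- function(table, config) {
  stopifnot(inherits(table, "visit_table"),
            inherits(config, "generator_config"))
  raw <- table$raw
  n0 <- nrow(raw)
  pool <- seq_len(n0)
  ledger <- list()
  mode <- config$mode
  take <- function(k, from) {
    if (k > length(from))
      stop(sprintf("config error: class requests %d rows but only %d remain",
                   k, length(from)), call. = FALSE)
    if (k == 0L) return(integer(0))
    picked <- sort(sample(from, k))
    pool <<- setdiff(pool, picked)
    picked
  }

  # 1: zero-coded height/weight
  set.seed(sub_seed(config$seed, 101L))
  plan <- config$errors$zero_height_weight
  if (mode == "rate" && !is.null(plan$p)) {
    hit <- pool[stats::runif(length(pool)) < plan$p]
    pool <- setdiff(pool, hit)
  } else {
    hit <- take(class_count(plan, length(pool), mode, "zero_height_weight"),
                pool)
  }
  if (length(hit)) {
    ledger[[length(ledger) + 1L]] <-
      rbind(ledger_row("zero_height_weight", hit, raw$visit_id[hit],
                       "height", raw$height[hit]),
            ledger_row("zero_height_weight", hit, raw$visit_id[hit],
                       "weight", raw$weight[hit]))
    raw$height[hit] <- "0"
    raw$weight[hit] <- "0"
  }

  # 2/3: out-of-range measurements
  set.seed(sub_seed(config$seed, 102L))
  hit <- take(class_count(config$errors$out_of_range_height, length(pool),
                          mode, "out_of_range_height"), pool)
  if (length(hit)) {
    ledger[[length(ledger) + 1L]] <-
      ledger_row("out_of_range_height", hit, raw$visit_id[hit], "height",
                 raw$height[hit])
    raw$height[hit] <- fmt_num(sample(c(stats::runif(length(hit), 240, 320),
                                        stats::runif(length(hit), 30, 95)),
                                      length(hit)))
  }
  set.seed(sub_seed(config$seed, 103L))
  hit <- take(class_count(config$errors$out_of_range_weight, length(pool),
                          mode, "out_of_range_weight"), pool)
  if (length(hit)) {
    ledger[[length(ledger) + 1L]] <-
      ledger_row("out_of_range_weight", hit, raw$visit_id[hit], "weight",
                 raw$weight[hit])
    raw$weight[hit] <- fmt_num(sample(c(stats::runif(length(hit), 320, 450),
                                        stats::runif(length(hit), 1, 15)),
                                      length(hit)))
  }

  # 4: arrival dates before the extraction window
  set.seed(sub_seed(config$seed, 104L))
  hit <- take(class_count(config$errors$early_arrival_dates, length(pool),
                          mode, "early_arrival_dates"), pool)
  if (length(hit)) {
    ledger[[length(ledger) + 1L]] <-
      ledger_row("early_arrival_dates", hit, raw$visit_id[hit],
                 "date_of_arrival", raw$date_of_arrival[hit])
    early <- table$provenance$window_start -
      sample(30:1100, length(hit), replace = TRUE)
    raw$date_of_arrival[hit] <- fmt_date(early)
  }

  # 5: height/weight inversion (swap the two fields)
  set.seed(sub_seed(config$seed, 105L))
  h <- suppressWarnings(as.numeric(raw$height))
  w <- suppressWarnings(as.numeric(raw$weight))
  elig <- pool[!is.na(h[pool]) & !is.na(w[pool]) &
                 h[pool] > w[pool] & w[pool] > 0]
  hit <- take(class_count(config$errors$hw_inversion, length(elig), mode,
                          "hw_inversion"), elig)
  if (length(hit)) {
    ledger[[length(ledger) + 1L]] <-
      rbind(ledger_row("hw_inversion", hit, raw$visit_id[hit], "height",
                       raw$height[hit]),
            ledger_row("hw_inversion", hit, raw$visit_id[hit], "weight",
                       raw$weight[hit]))
    tmp <- raw$height[hit]
    raw$height[hit] <- raw$weight[hit]
    raw$weight[hit] <- tmp
  }

  # 6/7: implausible BMI plants (values stay inside the plausibility ranges
  # and keep weight < height, so only the BMI check fires)
  set.seed(sub_seed(config$seed, 106L))
  hit <- take(class_count(config$errors$low_bmi, length(pool), mode,
                          "low_bmi"), pool)
  if (length(hit)) {
    ledger[[length(ledger) + 1L]] <-
      rbind(ledger_row("low_bmi", hit, raw$visit_id[hit], "height",
                       raw$height[hit]),
            ledger_row("low_bmi", hit, raw$visit_id[hit], "weight",
                       raw$weight[hit]))
    raw$height[hit] <- fmt_num(stats::runif(length(hit), 190, 210))
    raw$weight[hit] <- fmt_num(stats::runif(length(hit), 20, 30))
  }
  set.seed(sub_seed(config$seed, 107L))
  hit <- take(class_count(config$errors$high_bmi, length(pool), mode,
                          "high_bmi"), pool)
  if (length(hit)) {
    ledger[[length(ledger) + 1L]] <-
      rbind(ledger_row("high_bmi", hit, raw$visit_id[hit], "height",
                       raw$height[hit]),
            ledger_row("high_bmi", hit, raw$visit_id[hit], "weight",
                       raw$weight[hit]))
    hh <- stats::runif(length(hit), 105, 115)
    raw$height[hit] <- fmt_num(hh)
    raw$weight[hit] <- fmt_num(hh - stats::runif(length(hit), 1, 5))
  }

  # 8: history flips — a later 1 rewritten to 0 (the patient's first
  # recorded 1 is never flipped, so each flip is exactly one violation)
  set.seed(sub_seed(config$seed, 108L))
  plan <- config$errors$history_flip
  cond_vars <- c("atrial_fibrillation", "hypertension", "diabetes_mellitus",
                 "prior_mi")
  ord <- order(raw$patient_id, as.Date(raw$date_of_arrival, "%d/%m/%Y"),
               raw$visit_id)
  for (nm in cond_vars) {
    v <- raw[[nm]][ord]
    pid <- raw$patient_id[ord]
    ones <- which(v == "1")
    # eligible: a 1 whose patient has a strictly earlier recorded 1 (the
    # first 1 is never flipped, so each flip yields exactly one violation)
    if (length(ones)) {
      firsts <- tapply(ones, pid[ones], min)
      elig_sorted <- ones[ones > firsts[pid[ones]]]
    } else {
      elig_sorted <- integer(0)
    }
    elig <- intersect(ord[elig_sorted], pool)
    k <- if (mode == "rate" && !is.null(plan$p)) {
      hit <- elig[stats::runif(length(elig)) < plan$p]
      pool <- setdiff(pool, hit)
      length(hit)
    } else {
      hit <- take(class_count(plan, length(elig), mode,
                              paste0("history_flip:", nm)), elig)
      length(hit)
    }
    if (k) {
      ledger[[length(ledger) + 1L]] <-
        ledger_row("history_flip", hit, raw$visit_id[hit], nm, "1")
      raw[[nm]][hit] <- "0"
    }
  }

  # 9: duplicate visit identifiers — append fresh pairs sharing one new
  # visit ID, identical except for weight
  set.seed(sub_seed(config$seed, 109L))
  k <- class_count(config$errors$duplicate_id, n0, mode, "duplicate_id",
                   even = TRUE)
  if (k > 0L) {
    tpl <- sample(seq_len(n0), k / 2L, replace = TRUE)
    a <- raw[tpl, , drop = FALSE]
    b <- a
    newid <- sprintf("VDUP%06d", seq_len(k / 2L))
    a$visit_id <- newid; b$visit_id <- newid
    # 4-decimal weights are unreachable by the clean generator and unique
    # per pair, so planted rows collide only with their own partner
    a$weight <- sprintf("%.4f", 80 + seq_len(k / 2L) * 0.001)
    b$weight <- sprintf("%.4f", 80 + seq_len(k / 2L) * 0.001 + 0.0005)
    rows <- nrow(raw) + seq_len(k)
    raw <- rbind(raw, a, b)
    ledger[[length(ledger) + 1L]] <-
      ledger_row("duplicate_id", rows, raw$visit_id[rows], "visit_id",
                 "planted pair")
  }

  # 10: same-day clones — append pairs for a fresh patient, identical
  # clinical data under two distinct fresh visit IDs
  set.seed(sub_seed(config$seed, 110L))
  k <- class_count(config$errors$same_day_duplicate, n0, mode,
                   "same_day_duplicate", even = TRUE)
  if (k > 0L) {
    tpl <- sample(seq_len(n0), k / 2L, replace = TRUE)
    a <- raw[tpl, , drop = FALSE]
    a$patient_id <- sprintf("PSDD%05d", seq_len(k / 2L))
    b <- a
    a$visit_id <- sprintf("VSDA%06d", seq_len(k / 2L))
    b$visit_id <- sprintf("VSDB%06d", seq_len(k / 2L))
    rows <- nrow(raw) + seq_len(k)
    raw <- rbind(raw, a, b)
    ledger[[length(ledger) + 1L]] <-
      ledger_row("same_day_duplicate", rows, raw$visit_id[rows], "visit_id",
                 "planted pair")
  }

  rownames(raw) <- NULL
  out <- visit_table(raw, table$dictionary,
                     source = paste0(table$provenance$source, " + planted"),
                     window = c(table$provenance$window_start,
                                table$provenance$window_end))
  led <- do.call(rbind, c(ledger, list(empty_ledger())))
  rownames(led) <- NULL
  list(table = out, ledger = led)
}
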