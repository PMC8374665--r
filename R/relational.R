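# Synthetic relational EHR source: patients / visits / diagnoses / drugs /
# measures tables, with the join topology of a hospital data warehouse —
# diagnoses attach to visits by visit ID, drugs and measures attach to
# patients by (patient ID, date) only.

ICD9_CODES <- list(
  atrial_fibrillation = "427.31",
  prior_mi = c("410.9", "412"),
  hypertension = c("401.0", "401.9"),
  diabetes_mellitus = c("250.00", "250.01"),
  echocardiogram = "88.72",
  alcohol_use = c("303.90", "305.00"),
  smoking_status = c("305.1", "V15.82"))

ATC_CODES <- list(
  beta_blocker = c("C07AB02", "C07AB07"),
  calcium_channel_blocker = c("C08CA01", "C08CA05"),
  digoxin = "C01AA05",
  diuretics = c("C03CA01", "C03DA01"))

DEPARTMENTS <- c("cardiology", "emergency", "internal medicine",
                 "outpatient clinic")

#' Generate a synthetic relational EHR source
#'
#' Builds five tables: `patients` (patient ID, birth date, sex, death date),
#' `visits` (visit ID, patient ID, arrival, discharge, department),
#' `diagnoses` (visit ID, ICD-9 code, history-of flag), `drugs` (patient ID,
#' date, ATC code) and `measures` (patient ID, date, measure name, value).
#' Every patient carries at least one heart-failure ICD-9 diagnosis from the
#' built-in 428-family list. A configurable fraction of visits spawns a
#' second same-day visit in another department, and a fraction of visit
#' dates carries two distinct weight measurements — the two mechanisms from
#' which the flat mapper manufactures partial row duplicates. Height/weight
#' are measured on a visit date with probability `measure_prob`; unmeasured
#' dates become zero-coded fields downstream. Deterministic under the
#' configuration seed.
#'
#' @param config A [generator_config()].
#' @return A list with `source` (list of the five data.frames) and `truth`
#'   (ledger of generated artifacts: same-day visit pairs, duplicated
#'   measures, in-visit deaths).
#' @export
generate_source <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  win <- config$window
  days <- seq(win[1], win[2], by = "day")
  wts <- day_weights(days, config)

  set.seed(sub_seed(config$seed, 201L))
  np <- config$n_patients
  pid <- sprintf("P%05d", seq_len(np))
  nv <- 1L + stats::rgeom(np, prob = 1 / config$mean_visits)

  set.seed(sub_seed(config$seed, 202L))
  arr_list <- lapply(nv, function(k)
    sort(sample(days, min(k, length(days)), replace = FALSE, prob = wts)))
  nv <- lengths(arr_list)
  arrival <- as.Date(unlist(arr_list), origin = "1970-01-01")
  patient <- rep(pid, nv)
  n <- length(arrival)

  set.seed(sub_seed(config$seed, 203L))
  sameday <- stats::runif(n) < 0.6
  discharge <- pmin(arrival + ifelse(sameday, 0L, sample(1:14, n, replace = TRUE)),
                    win[2])
  dept <- sample(DEPARTMENTS, n, replace = TRUE)
  visits <- data.frame(visit_id = sprintf("V%07d", seq_len(n)),
                       patient_id = patient, arrival = arrival,
                       discharge = discharge, department = dept,
                       stringsAsFactors = FALSE)

  # same-day second visits in a different department
  set.seed(sub_seed(config$seed, 204L))
  extra_of <- which(stats::runif(n) < config$same_day_rate)
  truth_sameday <- empty_ledger()
  if (length(extra_of)) {
    ev <- visits[extra_of, , drop = FALSE]
    ev$visit_id <- sprintf("V%07d", n + seq_along(extra_of))
    ev$discharge <- ev$arrival # second contact is an appointment
    ev$department <- vapply(ev$department, function(d)
      sample(setdiff(DEPARTMENTS, d), 1L), character(1))
    visits <- rbind(visits, ev)
    truth_sameday <- ledger_row("same_day_visit",
                                n + seq_along(extra_of), ev$visit_id,
                                "visit_id", visits$visit_id[extra_of])
  }
  nvis <- nrow(visits)

  set.seed(sub_seed(config$seed, 205L))
  sex <- ifelse(stats::runif(np) < 0.55, 1L, 2L)
  first_arr <- as.Date(vapply(arr_list, function(a) as.numeric(a[1]),
                              numeric(1)), origin = "1970-01-01")
  birth <- first_arr - round(stats::runif(np, 40, 95) * 365.25)
  died <- stats::runif(np) < config$death_probability
  last_row <- cumsum(nv)
  death_date <- as.Date(rep(NA_real_, np), origin = "1970-01-01")
  death_date[died] <- discharge[last_row[died]]
  patients <- data.frame(patient_id = pid, birth_date = birth, sex = sex,
                         death_date = death_date, stringsAsFactors = FALSE)

  # diagnoses: guaranteed HF entry per patient, plus condition/procedure rows
  set.seed(sub_seed(config$seed, 206L))
  hf_visit <- vapply(split(seq_len(n), patient), function(idx)
    idx[sample.int(length(idx), 1L)], integer(1))[pid]
  dx <- list(data.frame(visit_id = visits$visit_id[hf_visit],
                        code = sample(hf_code_list()$codes, np,
                                      replace = TRUE),
                        history = 0L, stringsAsFactors = FALSE))
  ki <- 210L
  visit_idx_in_patient <- sequence(nv)
  for (nm in names(config$condition_prevalence)) {
    ki <- ki + 1L
    set.seed(sub_seed(config$seed, ki))
    has <- stats::runif(np) < config$condition_prevalence[[nm]]
    onset <- if (config$condition_onset == "first_visit") rep(1L, np) else
      ceiling(stats::runif(np) * nv)
    eligible <- rep(has, nv) & visit_idx_in_patient >= onset[rep(seq_len(np), nv)]
    rec <- which(eligible & stats::runif(n) < config$condition_recording)
    if (length(rec))
      dx[[length(dx) + 1L]] <-
        data.frame(visit_id = visits$visit_id[rec],
                   code = sample(ICD9_CODES[[nm]], length(rec),
                                 replace = TRUE),
                   history = ifelse(nm %in% c("echocardiogram", "alcohol_use",
                                              "smoking_status"), 0L, 1L),
                   stringsAsFactors = FALSE)
  }
  diagnoses <- do.call(rbind, dx)

  # drugs at their ceiling monthly probability; inject_temporal_patterns()
  # thins them down to the configured trend
  set.seed(sub_seed(config$seed, 230L))
  dr <- list()
  for (nm in names(config$medication_base)) {
    tmax <- months_since(win[2], win[1])
    pmax_ <- min(1, max(config$medication_base[[nm]],
                        config$medication_base[[nm]] +
                          config$medication_slope[[nm]] * tmax))
    hit <- stats::runif(n) < pmax_
    if (any(hit))
      dr[[length(dr) + 1L]] <-
        data.frame(patient_id = patient[hit], date = arrival[hit],
                   atc = sample(ATC_CODES[[nm]], sum(hit), replace = TRUE),
                   stringsAsFactors = FALSE)
  }
  drugs <- do.call(rbind, dr)

  # measures attach to (patient, date); a second discordant weight on some
  # dates seeds the duplicate-visit-ID mechanism downstream
  set.seed(sub_seed(config$seed, 240L))
  measured <- stats::runif(n) < config$measure_prob
  h <- pmin(pmax(stats::rnorm(n, 165, 10), 145), 200)
  w <- pmin(pmax(stats::rnorm(n, 75, 15), 45), 130)
  mh <- data.frame(patient_id = patient[measured], date = arrival[measured],
                   name = "height", value = round(h[measured], 1),
                   stringsAsFactors = FALSE)
  mw <- data.frame(patient_id = patient[measured], date = arrival[measured],
                   name = "weight", value = round(w[measured], 1),
                   stringsAsFactors = FALSE)
  dupm <- measured & stats::runif(n) < config$duplicate_measure_rate
  truth_dupm <- empty_ledger()
  if (any(dupm)) {
    m2 <- data.frame(patient_id = patient[dupm], date = arrival[dupm],
                     name = "weight", value = round(w[dupm] + 1.3, 1),
                     stringsAsFactors = FALSE)
    mw <- rbind(mw, m2)
    truth_dupm <- ledger_row("duplicate_measure", which(dupm),
                             visits$visit_id[which(dupm)], "weight",
                             round(w[dupm], 1))
  }
  measures <- rbind(mh, mw)
  rownames(measures) <- NULL

  truth_death <- if (any(died))
    ledger_row("in_visit_death", last_row[died],
               visits$visit_id[last_row[died]], "date_of_death",
               format(death_date[died], "%Y-%m-%d")) else empty_ledger()

  list(source = list(patients = patients, visits = visits,
                     diagnoses = diagnoses, drugs = drugs,
                     measures = measures),
       truth = rbind(truth_sameday, truth_dupm, truth_death))
}

#' Apply temporal documentation patterns to a relational source
#'
#' Thins history-of-condition diagnosis rows from the regime-shift date
#' onward by the configured multiplier (emulating an abrupt change in
#' coding practice) and thins drug rows so the monthly recording probability
#' follows the configured linear per-drug trend (the generator emits drugs at
#' the trend's ceiling). A shift date outside the window, a multiplier of 1
#' and zero slopes all leave the source unchanged. Deterministic under the
#' configuration seed.
#'
#' @param source The `source` element of [generate_source()].
#' @param config A [generator_config()].
#' @return The modified source list.
#' @export
inject_temporal_patterns <- function(source, config) {
  stopifnot(inherits(config, "generator_config"))
  win <- config$window
  rs <- config$regime_shift
  if (!is.null(rs) && !is.null(rs$date) && rs$multiplier < 1) {
    sd <- as.Date(rs$date)
    if (sd >= win[1] && sd <= win[2]) {
      set.seed(sub_seed(config$seed, 301L))
      varr <- source$visits$arrival[match(source$diagnoses$visit_id,
                                          source$visits$visit_id)]
      affected <- source$diagnoses$history == 1L & varr >= sd
      drop <- affected & stats::runif(nrow(source$diagnoses)) >= rs$multiplier
      source$diagnoses <- source$diagnoses[!drop, , drop = FALSE]
      rownames(source$diagnoses) <- NULL
    }
  }
  if (nrow(source$drugs)) {
    set.seed(sub_seed(config$seed, 302L))
    tmax <- months_since(win[2], win[1])
    keep <- rep(TRUE, nrow(source$drugs))
    for (nm in names(config$medication_base)) {
      base <- config$medication_base[[nm]]
      slope <- config$medication_slope[[nm]]
      pmax_ <- min(1, max(base, base + slope * tmax))
      sel <- code_matches(source$drugs$atc, default_code_lists()[[nm]])
      if (!any(sel) || pmax_ <= 0) next
      t <- months_since(source$drugs$date[sel], win[1])
      p <- pmin(pmax(base + slope * t, 0), 1) / pmax_
      keep[sel] <- stats::runif(sum(sel)) < p
    }
    source$drugs <- source$drugs[keep, , drop = FALSE]
    rownames(source$drugs) <- NULL
  }
  source
}
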