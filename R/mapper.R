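# Relational-to-flat mapping: the successive left-outer-join, date-matched
# merge that produces the visit-centered ICHOM table — including the
# zero-coding and partial-duplication artifacts that merge creates.

check_referential_integrity <- function(source) {
  bad_v <- setdiff(source$visits$patient_id, source$patients$patient_id)
  bad_d <- setdiff(source$diagnoses$visit_id, source$visits$visit_id)
  if (length(bad_v) || length(bad_d))
    stop("referential integrity error: ",
         if (length(bad_v)) paste0("visits reference unknown patients [",
                                   paste(utils::head(bad_v, 5), collapse = ", "),
                                   "] "),
         if (length(bad_d)) paste0("diagnoses reference unknown visits [",
                                   paste(utils::head(bad_d, 5), collapse = ", "),
                                   "]"),
         call. = FALSE)
  invisible(TRUE)
}

#' Select the heart-failure cohort from a relational source
#'
#' Keeps exactly the patients (and all their rows across the five tables)
#' having at least one diagnosis entry matching the heart-failure code list
#' on a visit arriving within the window.
#'
#' @param source A relational source as from [generate_source()].
#' @param hf_codes A [code_list()]; defaults to the built-in ICD-9 428
#'   family.
#' @param window Length-2 date window; defaults to the full pilot window.
#' @return The filtered source list (warns if no patient qualifies).
#' @export
select_cohort <- function(source, hf_codes = hf_code_list(),
                          window = c("2006-01-01", "2017-11-07")) {
  stopifnot(inherits(hf_codes, "code_list"))
  window <- as.Date(window)
  check_referential_integrity(source)
  dx <- source$diagnoses
  varr <- source$visits$arrival[match(dx$visit_id, source$visits$visit_id)]
  vpid <- source$visits$patient_id[match(dx$visit_id,
                                         source$visits$visit_id)]
  hit <- code_matches(dx$code, hf_codes) & varr >= window[1] &
    varr <= window[2]
  keep <- unique(vpid[hit])
  if (length(keep) == 0L)
    warning("no patients match the heart-failure code list", call. = FALSE)
  vkeep <- source$visits$patient_id %in% keep
  kept_visits <- source$visits$visit_id[vkeep]
  list(patients = source$patients[source$patients$patient_id %in% keep, ,
                                  drop = FALSE],
       visits = source$visits[vkeep, , drop = FALSE],
       diagnoses = source$diagnoses[source$diagnoses$visit_id %in%
                                      kept_visits, , drop = FALSE],
       drugs = source$drugs[source$drugs$patient_id %in% keep, ,
                            drop = FALSE],
       measures = source$measures[source$measures$patient_id %in% keep, ,
                                  drop = FALSE])
}

#' Map a relational source to the flat visit-centered ICHOM table
#'
#' Reproduces the extraction pipeline of a hospital data warehouse: patient
#' and visit identifiers form the left spine; diagnoses join on visit ID;
#' drugs and measures join on (patient ID, arrival date) — so two same-day
#' visits of one patient both receive that day's clinical data, and two
#' discordant same-day weight measurements yield two partially duplicated
#' rows sharing the visit ID. Height/weight missing on a visit date are
#' written as `0`, because the target format accepts only numeric values.
#' Baseline-health, lifestyle and procedure flags are set to 1 when any
#' matching diagnosis row up to and including the visit exists and 0
#' otherwise — never 999, deliberately modelling the inability of coded EHR
#' data to distinguish "absent" from "not recorded" (`strict_history = TRUE`
#' emits 999 instead of 0, for contrast experiments). Treatment flags come
#' from ATC prefix matches on the arrival date. Hospital admissions and
#' appointments count the patient's overnight and same-day visits in the 365
#' days before arrival. Date of death is written only when the patient died
#' during the visit. Output rows are stably sorted by (patient ID, arrival
#' date, visit ID).
#'
#' @param source A relational source (five tables, referentially intact).
#' @param dict A [data_dictionary()].
#' @param code_lists Named list of [code_list()]s per flag variable;
#'   defaults to [default_code_lists()].
#' @param strict_history Emit 999 instead of 0 for unobserved condition
#'   flags.
#' @param window Extraction window recorded on the output table.
#' @return A [visit_table()].
#' @export
map_to_ichom <- function(source, dict = default_dictionary(),
                         code_lists = default_code_lists(),
                         strict_history = FALSE,
                         window = c("2006-01-01", "2017-11-07")) {
  check_referential_integrity(source)
  v <- source$visits
  ord <- order(v$patient_id, v$arrival, v$visit_id)
  v <- v[ord, , drop = FALSE]
  p <- source$patients[match(v$patient_id, source$patients$patient_id), ,
                       drop = FALSE]
  nvis <- nrow(v)

  # earliest matching diagnosis date per patient per flag variable, then
  # flag = 1 iff that date <= this visit's arrival
  dx <- source$diagnoses
  dx_arr <- source$visits$arrival[match(dx$visit_id,
                                        source$visits$visit_id)]
  dx_pid <- source$visits$patient_id[match(dx$visit_id,
                                           source$visits$visit_id)]
  absent <- if (strict_history) "999" else "0"
  flag_cols <- list()
  flag_vars <- c("atrial_fibrillation", "prior_mi", "hypertension",
                 "diabetes_mellitus", "echocardiogram", "alcohol_use",
                 "smoking_status")
  for (nm in flag_vars) {
    hit <- code_matches(dx$code, code_lists[[nm]])
    flag <- rep(absent, nvis)
    if (any(hit)) {
      earliest <- tapply(as.numeric(dx_arr[hit]), dx_pid[hit], min)
      e <- earliest[v$patient_id]
      flag[!is.na(e) & as.numeric(v$arrival) >= e] <- "1"
    }
    flag_cols[[nm]] <- flag
  }

  # treatment flags: ATC prefix match on the arrival date
  dr <- source$drugs
  drug_cols <- list()
  for (nm in c("beta_blocker", "calcium_channel_blocker", "digoxin",
               "diuretics")) {
    flag <- rep(absent, nvis)
    if (nrow(dr)) {
      hit <- code_matches(dr$atc, code_lists[[nm]])
      key <- paste(dr$patient_id[hit], dr$date[hit], sep = SEP)
      flag[paste(v$patient_id, v$arrival, sep = SEP) %in% key] <- "1"
    }
    drug_cols[[nm]] <- flag
  }

  counts <- visit_burden_counts(v$patient_id, v$arrival, v$discharge)
  death <- ifelse(!is.na(p$death_date) & p$death_date >= v$arrival &
                    p$death_date <= v$discharge,
                  fmt_date(p$death_date), "")

  base <- data.frame(
    patient_id = v$patient_id, visit_id = v$visit_id,
    date_of_birth = fmt_date(p$birth_date), sex = as.character(p$sex),
    atrial_fibrillation = flag_cols$atrial_fibrillation,
    prior_mi = flag_cols$prior_mi,
    hypertension = flag_cols$hypertension,
    diabetes_mellitus = flag_cols$diabetes_mellitus,
    echocardiogram = flag_cols$echocardiogram,
    height = "0", weight = "0",
    alcohol_use = flag_cols$alcohol_use,
    smoking_status = flag_cols$smoking_status,
    beta_blocker = drug_cols$beta_blocker,
    calcium_channel_blocker = drug_cols$calcium_channel_blocker,
    digoxin = drug_cols$digoxin,
    diuretics = drug_cols$diuretics,
    date_of_arrival = fmt_date(v$arrival),
    date_of_discharge = fmt_date(v$discharge),
    hospital_admissions = as.character(counts$admissions),
    hospital_appointments = as.character(counts$appointments),
    date_of_death = death,
    stringsAsFactors = FALSE)

  # measures join on (patient, date): one output row per height x weight
  # combination on that date; none measured -> zero-coded
  m <- source$measures
  mkey <- paste(m$patient_id, m$date, sep = SEP)
  vkey <- paste(v$patient_id, v$arrival, sep = SEP)
  hmap <- split(m$value[m$name == "height"], mkey[m$name == "height"])
  wmap <- split(m$value[m$name == "weight"], mkey[m$name == "weight"])
  hs <- hmap[vkey]; ws <- wmap[vkey]
  hu <- lapply(hs, function(x) if (is.null(x) || !length(x)) 0
               else unique(sort(x)))
  wu <- lapply(ws, function(x) if (is.null(x) || !length(x)) 0
               else unique(sort(x)))
  reps <- lengths(hu) * lengths(wu)
  out <- base[rep(seq_len(nvis), reps), , drop = FALSE]
  hvals <- unlist(lapply(seq_len(nvis), function(i)
    rep(hu[[i]], each = length(wu[[i]]))))
  wvals <- unlist(lapply(seq_len(nvis), function(i)
    rep(wu[[i]], times = length(hu[[i]]))))
  out$height <- fmt_num(hvals)
  out$weight <- fmt_num(wvals)
  rownames(out) <- NULL

  visit_table(out, dict, source = "mapped relational source",
              window = window)
}
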