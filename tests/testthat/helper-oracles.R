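# Independent brute-force oracles. These deliberately use naive per-record
# scans (full pairwise comparison, per-patient loops) so they share no code
# path with the vectorised checks they verify.

oracle_uniqueness1 <- function(raw) {
  n <- nrow(raw)
  m <- as.matrix(raw[setdiff(names(raw), "visit_id")])
  id <- raw$visit_id
  viol <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (id[j] != id[i]) next
      if (any(m[j, ] != m[i, ])) { viol[i] <- TRUE; break }
    }
  }
  sum(viol)
}

oracle_uniqueness2 <- function(raw) {
  n <- nrow(raw)
  m <- as.matrix(raw[setdiff(names(raw), "visit_id")])
  id <- raw$visit_id
  viol <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (id[j] == id[i]) next
      if (all(m[j, ] == m[i, ])) { viol[i] <- TRUE; break }
    }
  }
  sum(viol)
}

# scalar re-check of one raw value against a spec kind, written without
# parse_value()
oracle_value_ok <- function(x, spec) {
  x <- trimws(x)
  if (x == "") return(NA) # missing
  switch(spec$value_kind,
    identifier = TRUE,
    numeric = !is.na(suppressWarnings(as.numeric(x))) &&
      grepl("^-?[0-9.eE+-]+$", x),
    categorical = grepl("^-?[0-9]+$", x),
    count = grepl("^-?[0-9]+$", x),
    date = {
      if (!is.null(spec$unknown_code) &&
          x == as.character(spec$unknown_code)) TRUE
      else !is.na(as.Date(x, format = "%d/%m/%Y")) ||
        (grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x) &&
           !is.na(as.Date(x, format = "%Y-%m-%d")))
    })
}

oracle_type_counts <- function(table) {
  nms <- dictionary_names(table$dictionary)
  sapply(nms, function(nm) {
    oks <- vapply(table$raw[[nm]], oracle_value_ok, logical(1),
                  spec = table$dictionary[[nm]], USE.NAMES = FALSE)
    sum(!oks, na.rm = TRUE)
  })
}

oracle_completeness_counts <- function(raw) {
  sapply(raw, function(col) sum(trimws(col) == ""))
}

# per-patient scan of one condition flag in arrival order
oracle_history_violations <- function(raw, variable) {
  arr <- as.Date(raw$date_of_arrival, format = "%d/%m/%Y")
  total <- 0L
  for (p in unique(raw$patient_id)) {
    idx <- which(raw$patient_id == p)
    idx <- idx[order(arr[idx], raw$visit_id[idx])]
    seen <- FALSE
    for (i in idx) {
      v <- raw[[variable]][i]
      if (v == "1") seen <- TRUE
      else if (v == "0" && seen) total <- total + 1L
    }
  }
  total
}

# small random raw table exercising identifier collisions, clones, unknown
# codes and malformed values
random_raw_table <- function(n, seed) {
  set.seed(seed)
  dict <- default_dictionary()
  dates <- format(as.Date("2006-01-01") + sample(0:4000, 30), "%d/%m/%Y")
  raw <- data.frame(
    patient_id = sample(sprintf("P%02d", 1:12), n, replace = TRUE),
    visit_id = sample(sprintf("V%03d", 1:(n + 20)), n, replace = TRUE),
    date_of_birth = sample(c("01/01/1950", "15/06/1942", ""), n, TRUE),
    sex = sample(c("1", "2", "3", ""), n, TRUE, prob = c(.45, .45, .05, .05)),
    atrial_fibrillation = sample(c("0", "1", "999", ""), n, TRUE),
    prior_mi = sample(c("0", "1", "999"), n, TRUE),
    hypertension = sample(c("0", "1", "999", "x"), n, TRUE,
                          prob = c(.4, .4, .15, .05)),
    diabetes_mellitus = sample(c("0", "1"), n, TRUE),
    echocardiogram = sample(c("0", "1", "999"), n, TRUE),
    height = sample(c("170", "0", "165.5", "abc", ""), n, TRUE,
                    prob = c(.4, .3, .2, .05, .05)),
    weight = sample(c("70", "0", "80.2", ""), n, TRUE),
    alcohol_use = sample(c("0", "1", "999"), n, TRUE),
    smoking_status = sample(c("0", "1", "999"), n, TRUE),
    beta_blocker = sample(c("0", "1"), n, TRUE),
    calcium_channel_blocker = sample(c("0", "1"), n, TRUE),
    digoxin = sample(c("0", "1"), n, TRUE),
    diuretics = sample(c("0", "1"), n, TRUE),
    date_of_arrival = sample(dates, n, TRUE),
    date_of_discharge = sample(c(dates, ""), n, TRUE),
    hospital_admissions = sample(c("0", "1", "2", "999", "-1"), n, TRUE,
                                 prob = c(.4, .3, .15, .1, .05)),
    hospital_appointments = sample(c("0", "1", "999"), n, TRUE),
    date_of_death = sample(c("", "", "", "05/05/2012", "999"), n, TRUE),
    stringsAsFactors = FALSE)
  # clone some rows to provoke same-day duplicates and exact duplicates
  k <- max(1L, n %/% 10L)
  src <- sample(n, k, replace = TRUE)
  dst <- sample(n, k, replace = TRUE)
  for (i in seq_len(k)) {
    raw[dst[i], ] <- raw[src[i], ]
    if (stats::runif(1) < 0.5)
      raw$visit_id[dst[i]] <- sample(sprintf("V%03d", 1:(n + 20)), 1)
  }
  raw
}
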