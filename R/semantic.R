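# Temporal-stability profiling and correctness checks.

month_seq <- function(from, to) {
  seq(as.Date(format(from, "%Y-%m-01")), as.Date(format(to, "%Y-%m-01")),
      by = "month")
}

#' Monthly relative frequency of a binary indicator
#'
#' Bins records by the calendar month of the arrival date and computes, per
#' month, the fraction of records with indicator value 1 out of all records
#' that month (values 0 and 999 count in the denominator only). Every month
#' of the extraction window is present; months with no records have an
#' undefined (`NA`) frequency, and months whose denominator falls below
#' `threshold` are flagged as low support. Records with an unparseable or
#' missing arrival date are excluded from the denominators and their count is
#' reported.
#'
#' @param table A [visit_table()].
#' @param variable Name of a 0/1/999-coded variable.
#' @param threshold Minimum records per month for a supported estimate
#'   (default 10).
#' @return An object of class `monthly_series`: a data.frame with columns
#'   `month` (Date, first of month), `numerator`, `denominator`, `frequency`,
#'   `low_support`; attributes `variable`, `threshold`, `n_excluded`.
#' @export
monthly_frequency <- function(table, variable, threshold = 10) {
  stopifnot(inherits(table, "visit_table"),
            variable %in% names(table$typed))
  arr <- table$typed$date_of_arrival
  ok <- table$status[, "date_of_arrival"] == "ok" & !is.na(arr)
  v <- table$typed[[variable]]
  vok <- table$status[, variable] == "ok"
  months <- month_seq(table$provenance$window_start,
                      table$provenance$window_end)
  key <- factor(format(arr[ok], "%Y-%m-01"),
                levels = format(months, "%Y-%m-01"))
  den <- as.integer(table(key))
  sel <- v[ok] == 1L & vok[ok]
  sel[is.na(sel)] <- FALSE
  num <- as.integer(table(key[sel]))
  freq <- ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(month = months, numerator = num, denominator = den,
                    frequency = freq, low_support = den < threshold)
  structure(out, variable = variable, threshold = threshold,
            n_excluded = sum(!ok), class = c("monthly_series", "data.frame"))
}

#' Detect an abrupt shift in a monthly frequency series
#'
#' Convenience change-point scan over a [monthly_frequency()] series: for
#' each candidate month, the mean frequency over the `window` supported
#' months before is compared with the mean over the `window` supported
#' months from the candidate onward; the candidate maximising the absolute
#' gap is returned if its relative change `|after - before| /
#' max(before, after)` exceeds `min_rel_change`, else `NULL`. Low-support
#' months are excluded from both means. Ties break to the earliest month.
#' This scan is an explicit extension of the qualitative visual reading of
#' the trend plots and is off by default in reports.
#'
#' @param series A `monthly_series`.
#' @param window Months in each comparison window (default 12).
#' @param min_rel_change Minimum relative change to report (default 0.5).
#' @return `NULL`, or a list with `month` (first month of the post-shift
#'   regime), `before_mean`, `after_mean`, `gap`.
#' @export
detect_shift <- function(series, window = 12, min_rel_change = 0.5) {
  stopifnot(inherits(series, "monthly_series"))
  sup <- which(!series$low_support & !is.na(series$frequency))
  if (length(sup) < 2 * window) return(NULL)
  f <- series$frequency
  best <- NULL
  for (k in seq(2L, length(sup))) {
    pre <- sup[sup < sup[k]]
    post <- sup[sup >= sup[k]]
    if (length(pre) < window || length(post) < window) next
    m1 <- mean(f[utils::tail(pre, window)])
    m2 <- mean(f[utils::head(post, window)])
    gap <- abs(m2 - m1)
    if (is.null(best) || gap > best$gap)
      best <- list(month = series$month[sup[k]], before_mean = m1,
                   after_mean = m2, gap = gap)
  }
  if (is.null(best)) return(NULL)
  rel <- best$gap / max(best$before_mean, best$after_mean)
  if (!is.finite(rel) || rel < min_rel_change) return(NULL)
  best
}

#' Body mass index
#'
#' @param height_cm Height in centimetres (> 0).
#' @param weight_kg Weight in kilograms (> 0).
#' @return BMI in kg/m^2; `NA` where either input is non-positive or missing
#'   (zero-coded measurements are excluded, not treated as data).
#' @export
#' @examples
#' bmi(170, 65)
bmi <- function(height_cm, weight_kg) {
  out <- ifelse(!is.na(height_cm) & !is.na(weight_kg) &
                  height_cm > 0 & weight_kg > 0,
                weight_kg / (height_cm / 100)^2, NA_real_)
  unname(out)
}

#' BMI plausibility check
#'
#' Counts records whose computable BMI is strictly below `low` or strictly
#' above `high`. The denominator is all records, matching the convention of
#' reporting probable errors as a share of all patient visit records; records
#' with zero, missing or unparseable height or weight have no computable BMI
#' and are skipped and tallied separately (`n_skipped`).
#'
#' @param table A [visit_table()].
#' @param low,high Plausibility bounds in kg/m^2 (defaults 10 and 70).
#' @return A [check_result()] (`check_id = "bmi_plausibility"`) with counts
#'   `n_low`, `n_high`, `n_skipped` attached as attribute `counts`.
#' @export
bmi_plausibility <- function(table, low = 10, high = 70) {
  stopifnot(inherits(table, "visit_table"), low < high)
  h <- table$typed$height; w <- table$typed$weight
  ok <- table$status[, "height"] == "ok" & table$status[, "weight"] == "ok"
  b <- bmi(ifelse(ok, h, NA), ifelse(ok, w, NA))
  computable <- !is.na(b)
  lo <- computable & b < low
  hi <- computable & b > high
  findings <- rbind(
    new_findings(which(lo), "weight", "bmi_plausibility",
                 sprintf("suspiciously low BMI %.1f kg/m2", b[lo])),
    new_findings(which(hi), "weight", "bmi_plausibility",
                 sprintf("implausibly high BMI %.1f kg/m2", b[hi])))
  res <- check_result("bmi_plausibility", numerator = sum(lo) + sum(hi),
                      denominator = n_visits(table), findings = findings)
  attr(res, "counts") <- c(n_low = sum(lo), n_high = sum(hi),
                           n_skipped = sum(!computable))
  res
}

#' Height/weight inversion candidates
#'
#' Flags records whose weight (kg) exceeds their height (cm), both positive —
#' points below the main diagonal of the height-weight scatter, which are
#' very unlikely to be true. Candidates whose swapped values would give a
#' plausible BMI within `[low, high]` are additionally labelled
#' swap-plausible (hypothesised value inversion at data entry).
#'
#' @param table A [visit_table()].
#' @param low,high BMI plausibility bounds used for the swap test.
#' @return A data.frame with columns `record`, `height`, `weight`,
#'   `swapped_bmi`, `swap_plausible`.
#' @export
inversion_candidates <- function(table, low = 10, high = 70) {
  stopifnot(inherits(table, "visit_table"))
  h <- table$typed$height; w <- table$typed$weight
  ok <- table$status[, "height"] == "ok" & table$status[, "weight"] == "ok" &
    !is.na(h) & !is.na(w)
  cand <- which(ok & h > 0 & w > 0 & w > h)
  sb <- bmi(w[cand], h[cand]) # swapped: weight plays height and vice versa
  data.frame(record = cand, height = h[cand], weight = w[cand],
             swapped_bmi = sb,
             swap_plausible = !is.na(sb) & sb >= low & sb <= high)
}

#' Temporal-order violations of past-medical-condition flags
#'
#' Once a visit record states a history of a condition (flag 1), every
#' subsequent visit of that patient should state it too; a later flag 0 is an
#' impossible regression and marks that record as violating. Visits are
#' ordered by arrival date with ties broken by visit identifier; the unknown
#' code 999 neither violates nor resets the seen-history state. Violations
#' are counted per visit record; the per-condition rate divides by all
#' records, and the per-condition score is `100 - rate`.
#'
#' @param table A [visit_table()].
#' @param condition_variables Flag variables to assess (default: the four
#'   past-condition items).
#' @return A [check_result()] (`check_id = "history_order"`,
#'   method `variable_mean` over conditions) with per-condition breakdown.
#' @export
history_order_violations <- function(table,
                                     condition_variables = c(
                                       "atrial_fibrillation", "hypertension",
                                       "diabetes_mellitus", "prior_mi")) {
  stopifnot(inherits(table, "visit_table"))
  n <- n_visits(table)
  ord <- order(table$raw$patient_id, table$typed$date_of_arrival,
               table$raw$visit_id)
  pid <- table$raw$patient_id[ord]
  new_patient <- c(TRUE, pid[-1] != pid[-length(pid)])
  rows <- list(); findings <- list()
  for (nm in condition_variables) {
    v <- table$typed[[nm]][ord]
    vok <- table$status[, nm][ord] == "ok"
    seen <- logical(n)
    state <- FALSE
    for (i in seq_len(n)) {
      if (new_patient[i]) state <- FALSE
      seen[i] <- state
      if (vok[i] && !is.na(v[i]) && v[i] == 1L) state <- TRUE
    }
    viol_sorted <- vok & !is.na(v) & v == 0L & seen
    viol <- integer(0)
    if (any(viol_sorted)) viol <- sort(ord[viol_sorted])
    rows[[length(rows) + 1L]] <-
      data.frame(variable = nm, numerator = length(viol), denominator = n,
                 stringsAsFactors = FALSE)
    if (length(viol))
      findings[[length(findings) + 1L]] <-
        new_findings(viol, nm, "history_order",
                     "'no history' recorded after an earlier 'history'")
  }
  variable_mean_result("history_order", do.call(rbind, rows),
                       do.call(rbind, c(findings, list(empty_findings()))))
}

#' Overall correctness score
#'
#' Unweighted mean over the correctness checks: the BMI-plausibility score
#' and the per-condition temporal-order scores. The aggregation rule is
#' configurable because no single convention reproduces all published
#' aggregate conventions; the component scores are always reported.
#'
#' @param bmi_result A `check_result` from [bmi_plausibility()].
#' @param history_result A `check_result` from [history_order_violations()].
#' @return Numeric scalar score in percent (mean over 1 + n-conditions
#'   component scores, rounded half-up to 2 decimals).
#' @export
correctness_overall <- function(bmi_result, history_result) {
  scores <- c(bmi_result$score, history_result$per_variable$score)
  round_half_up(mean(scores), 2)
}
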