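# Structural data-quality checks: uniqueness, consistency, completeness.
# All operate on raw values (verbatim field comparison) except where a check
# is defined on typed values (range, rules); all are row-order invariant.

SEP <- "\x1f"

row_patterns <- function(raw_df, cols) {
  if (length(cols) == 1L) return(raw_df[[cols]])
  do.call(paste, c(raw_df[cols], sep = SEP))
}

#' Uniqueness result 1: identical visit identifiers, differing content
#'
#' A record violates when its visit identifier is shared with at least one
#' other record whose values differ in one or more non-identifier fields
#' (partial row duplicates from repeated within-visit measurements). Records
#' that agree with every same-identifier record on all fields are exact full
#' duplicates; they are excluded from the numerator and reported as a
#' separate informational finding. The denominator counts all records.
#'
#' @param table A [visit_table()].
#' @return A [check_result()] (`check_id = "uniqueness_result1"`), with
#'   exact-duplicate counts in its findings.
#' @export
uniqueness_result1 <- function(table) {
  stopifnot(inherits(table, "visit_table"))
  raw <- table$raw
  n <- nrow(raw)
  other_cols <- setdiff(names(raw), "visit_id")
  id <- raw$visit_id
  pat <- row_patterns(raw, other_cols)
  # per visit-ID group: does the group contain >= 2 distinct field patterns?
  grp_size <- stats::ave(seq_len(n), id, FUN = length)
  grp_npat <- stats::ave(pat, id, FUN = function(p) length(unique(p)))
  violating <- grp_size >= 2 & as.integer(grp_npat) >= 2
  exact_dup <- grp_size >= 2 & as.integer(grp_npat) == 1
  findings <- rbind(
    new_findings(which(violating), "visit_id", "uniqueness_result1",
                 "visit ID shared with a record holding different values"),
    new_findings(which(exact_dup), "visit_id", "uniqueness_exact_duplicate",
                 "exact full-row duplicate (informational)"))
  check_result("uniqueness_result1", numerator = sum(violating),
               denominator = n, findings = findings)
}

#' Uniqueness result 2: same-day records with identical clinical data
#'
#' A record violates when at least one other record for the same patient and
#' arrival date carries identical values on every field except the visit
#' identifier, under a different visit identifier — the signature of
#' date-matched clinical data attached to each of several same-day visits.
#' The denominator counts all records.
#'
#' @param table A [visit_table()].
#' @return A [check_result()] (`check_id = "uniqueness_result2"`).
#' @export
uniqueness_result2 <- function(table) {
  stopifnot(inherits(table, "visit_table"))
  raw <- table$raw
  n <- nrow(raw)
  clin_cols <- setdiff(names(raw), "visit_id")
  pat <- row_patterns(raw, clin_cols)  # includes patient_id + arrival date
  nid <- stats::ave(raw$visit_id, pat, FUN = function(v) length(unique(v)))
  grp_size <- stats::ave(seq_len(n), pat, FUN = length)
  violating <- grp_size >= 2 & as.integer(nid) >= 2
  findings <- new_findings(which(violating), NA_character_,
                           "uniqueness_result2",
                           "same-day record with identical clinical data under another visit ID")
  check_result("uniqueness_result2", numerator = sum(violating),
               denominator = n, findings = findings)
}

#' Consistency by data type
#'
#' Per variable, the fraction of non-missing fields whose raw text does not
#' parse as the declared kind (status `type_failure`); the variable score is
#' `100 * (1 - fraction)` and the check score is the unweighted mean over
#' variables. Variables with no assessable fields score 100 and raise a
#' `vacuous_denominator` flag.
#'
#' @param table A [visit_table()].
#' @return A [check_result()] with per-variable breakdown.
#' @export
consistency_by_type <- function(table) {
  stopifnot(inherits(table, "visit_table"))
  nms <- dictionary_names(table$dictionary)
  st <- table$status
  num <- den <- integer(length(nms))
  findings <- list()
  for (i in seq_along(nms)) {
    s <- st[, nms[i]]
    den[i] <- sum(s != "missing")
    bad <- which(s == "type_failure")
    num[i] <- length(bad)
    if (length(bad))
      findings[[length(findings) + 1L]] <-
        new_findings(bad, nms[i], "consistency_by_type",
                     paste0("value '", table$raw[[nms[i]]][bad],
                            "' is not a valid ",
                            table$dictionary[[nms[i]]]$value_kind))
  }
  variable_mean_result("consistency_by_type",
                       data.frame(variable = nms, numerator = num,
                                  denominator = den,
                                  stringsAsFactors = FALSE),
                       do.call(rbind, c(findings, list(empty_findings()))))
}

# Per-variable range/domain violation mask over typed values; NULL means the
# variable has no range semantics. Denominator = fields parsed ok.
range_violations <- function(table, nm) {
  spec <- table$dictionary[[nm]]
  v <- table$typed[[nm]]
  ok <- table$status[, nm] == "ok"
  viol <- rep(FALSE, length(ok))
  if (spec$value_kind == "numeric" && !is.null(spec$numeric_range)) {
    viol[ok] <- v[ok] < spec$numeric_range[1] | v[ok] > spec$numeric_range[2]
  } else if (spec$value_kind == "categorical") {
    viol[ok] <- !(v[ok] %in% spec$allowed_codes)
  } else if (spec$value_kind == "count") {
    legal <- v[ok] >= 0 |
      (!is.null(spec$unknown_code) & v[ok] == spec$unknown_code)
    viol[ok] <- !legal
  } else if (spec$value_kind == "date") {
    rng <- spec$date_range
    if (is.null(rng))
      rng <- c(table$provenance$window_start, table$provenance$window_end)
    # typed NA with status ok = legal unknown code (999): not a violation
    in_range <- !is.na(v[ok]) & (v[ok] < rng[1] | v[ok] > rng[2])
    viol[ok] <- in_range
  } else {
    return(NULL) # identifiers: no range semantics, excluded from the check
  }
  viol
}

#' Consistency by value range
#'
#' Numeric fields outside their plausibility range (zero-coded height/weight
#' falls here by default), event dates outside the extraction window, birth
#' dates outside their plausible span, categorical values outside the
#' response options, and negative counts are violations. Denominator per
#' variable = fields that parsed ok; identifier variables carry no range
#' semantics and are excluded. Scores aggregate by unweighted mean over
#' variables.
#'
#' @param table A [visit_table()].
#' @return A [check_result()] with per-variable breakdown; findings carry the
#'   offending raw values.
#' @export
consistency_by_range <- function(table) {
  stopifnot(inherits(table, "visit_table"))
  nms <- dictionary_names(table$dictionary)
  rows <- list(); findings <- list()
  for (nm in nms) {
    viol <- range_violations(table, nm)
    if (is.null(viol)) next
    ok <- table$status[, nm] == "ok"
    bad <- which(viol)
    rows[[length(rows) + 1L]] <-
      data.frame(variable = nm, numerator = length(bad),
                 denominator = sum(ok), stringsAsFactors = FALSE)
    if (length(bad))
      findings[[length(findings) + 1L]] <-
        new_findings(bad, nm, "consistency_by_range",
                     paste0("value '", table$raw[[nm]][bad],
                            "' out of range/domain"))
  }
  variable_mean_result("consistency_by_range", do.call(rbind, rows),
                       do.call(rbind, c(findings, list(empty_findings()))))
}

#' Default multivariate consistency rules
#'
#' Two date-order rules: arrival must not follow discharge, and discharge
#' must not follow the date of death.
#'
#' @return List of rules, each `list(lhs, op, rhs)` over typed variables.
#' @export
default_rules <- function() {
  list(list(lhs = "date_of_arrival", op = "<=", rhs = "date_of_discharge"),
       list(lhs = "date_of_discharge", op = "<=", rhs = "date_of_death"))
}

#' Consistency by multivariate rules
#'
#' Each rule compares two typed fields (`lhs op rhs`) and is evaluable on a
#' record only when both fields parsed ok with non-missing values (the legal
#' unknown code on a date makes the rule non-evaluable). The numerator counts
#' records violating at least one rule; the denominator counts records where
#' at least one rule is evaluable.
#'
#' @param table A [visit_table()].
#' @param rules List of rules as in [default_rules()]; `op` one of
#'   `"<="`, `"<"`, `"=="`, `">="`, `">"`.
#' @return A [check_result()].
#' @export
consistency_by_rules <- function(table, rules = default_rules()) {
  stopifnot(inherits(table, "visit_table"))
  n <- n_visits(table)
  evaluable <- violating <- rep(FALSE, n)
  findings <- list()
  for (r in rules) {
    a <- table$typed[[r$lhs]]; b <- table$typed[[r$rhs]]
    e <- table$status[, r$lhs] == "ok" & table$status[, r$rhs] == "ok" &
      !is.na(a) & !is.na(b)
    v <- e & !do.call(r$op, list(a, b))
    evaluable <- evaluable | e
    violating <- violating | v
    if (any(v))
      findings[[length(findings) + 1L]] <-
        new_findings(which(v), r$lhs, "consistency_by_rules",
                     sprintf("rule violated: %s %s %s", r$lhs, r$op, r$rhs))
  }
  check_result("consistency_by_rules", numerator = sum(violating),
               denominator = sum(evaluable),
               findings = do.call(rbind, c(findings,
                                           list(empty_findings()))))
}

#' Overall consistency score
#'
#' Unweighted mean of the type, range and rules scores, rounded half-up to
#' two decimals.
#'
#' @param results List of exactly three `check_result`s (type, range, rules),
#'   or three numeric scores.
#' @return Numeric scalar score in percent.
#' @export
consistency_overall <- function(results) {
  stopifnot(length(results) == 3L)
  scores <- vapply(results, function(r)
    if (inherits(r, "check_result")) r$score else as.numeric(r), numeric(1))
  round_half_up(mean(scores), 2)
}

#' Completeness
#'
#' Per variable, the fraction of non-empty fields. A variable carrying a
#' valid-incompleteness rule (date of death: only recorded when the patient
#' died during the visit) is scored on the subset of records where the field
#' is expected to exist; its raw unconditional rate is reported alongside in
#' the per-variable breakdown. The overall score is the unweighted mean over
#' variables. A separate per-variable unknown rate — the fraction of legal
#' unknown codes (999) among non-empty fields — is reported and does not
#' lower completeness.
#'
#' @param table A [visit_table()].
#' @param exclusions Optional named list of logical masks (one per
#'   valid-incompleteness variable) marking the records where the field is
#'   expected to be present, e.g. the generator's ground-truth in-visit death
#'   indicator. By default the mask is inferred from the data: records whose
#'   recorded death date lies within `[arrival, discharge]`.
#' @return A [check_result()]; `per_variable` gains columns `raw_rate`
#'   (unconditional completeness, percent) and `unknown_rate` (percent).
#' @export
completeness <- function(table, exclusions = list()) {
  stopifnot(inherits(table, "visit_table"))
  nms <- dictionary_names(table$dictionary)
  n <- n_visits(table)
  rows <- list(); findings <- list()
  for (nm in nms) {
    spec <- table$dictionary[[nm]]
    present <- table$status[, nm] != "missing"
    raw_rate <- if (n > 0) 100 * sum(present) / n else 100
    expected <- rep(TRUE, n)
    if (!is.null(spec$valid_incompleteness)) {
      if (!is.null(exclusions[[nm]])) {
        expected <- as.logical(exclusions[[nm]])
        stopifnot(length(expected) == n, !anyNA(expected))
      } else {
        expected <- died_during_visit(table)
      }
    }
    num <- sum(expected & !present)
    den <- sum(expected)
    unk <- if (!is.null(spec$unknown_code) && sum(present) > 0) {
      raw_u <- trimws(table$raw[[nm]])
      100 * sum(present & raw_u == as.character(spec$unknown_code)) /
        sum(present)
    } else 0
    rows[[length(rows) + 1L]] <-
      data.frame(variable = nm, numerator = num, denominator = den,
                 raw_rate = round_half_up(raw_rate, 2),
                 unknown_rate = round_half_up(unk, 2),
                 stringsAsFactors = FALSE)
    bad <- which(expected & !present)
    if (length(bad))
      findings[[length(findings) + 1L]] <-
        new_findings(bad, nm, "completeness", "expected field is empty")
  }
  per <- do.call(rbind, rows)
  variable_mean_result("completeness",
                       per[c("variable", "numerator", "denominator")],
                       do.call(rbind, c(findings, list(empty_findings()))),
                       extra = per[c("raw_rate", "unknown_rate")])
}

#' Records where the patient died during the visit
#'
#' The default expected-present mask for the date-of-death
#' valid-incompleteness rule: records whose recorded death date lies within
#' `[arrival, discharge]`. From the flat table alone this is the only
#' observable signal of an in-visit death; pass an explicit mask to
#' [completeness()] to audit against external ground truth instead.
#'
#' @param table A [visit_table()].
#' @return Logical vector, one element per record.
#' @export
died_in_visit_mask <- function(table) {
  stopifnot(inherits(table, "visit_table"))
  died_during_visit(table)
}

died_during_visit <- function(table) {
  d <- table$typed$date_of_death
  a <- table$typed$date_of_arrival
  dis <- table$typed$date_of_discharge
  !is.na(d) & !is.na(a) & !is.na(dis) & d >= a & d <= dis
}
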