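#' Visit-centered table of ICHOM heart-failure records
#'
#' Container for a flat table with one row per hospital visit. Raw values are
#' kept verbatim (character; empty string = missing) so writing and re-reading
#' is lossless; typed values and per-field parse statuses are held alongside.
#' Row order carries no meaning: every check is row-order invariant.
#'
#' @param raw A data.frame of character columns, one per dictionary variable.
#' @param dict A [data_dictionary()]; defaults to [default_dictionary()].
#' @param source Provenance label for the table.
#' @param window Length-2 extraction window (start, end), coercible to
#'   `Date`; start must not exceed end. Used as the default plausibility
#'   window for event dates and as the span of stability series.
#' @return An object of class `visit_table`: a list with elements `raw`
#'   (character data.frame), `typed` (named list of typed vectors), `status`
#'   (character matrix, `ok`/`missing`/`type_failure`), `dictionary`,
#'   `provenance`.
#' @export
visit_table <- function(raw, dict = default_dictionary(),
                        source = "unspecified",
                        window = c("2006-01-01", "2017-11-07")) {
  stopifnot(is.data.frame(raw), inherits(dict, "data_dictionary"))
  nms <- dictionary_names(dict)
  missing_cols <- setdiff(nms, names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  raw <- raw[nms]
  for (nm in nms) {
    raw[[nm]] <- as.character(raw[[nm]])
    raw[[nm]][is.na(raw[[nm]])] <- ""
  }
  window <- as.Date(window)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  parsed <- parse_table(raw, dict)
  structure(
    list(raw = raw, typed = parsed$typed, status = parsed$status,
         dictionary = dict,
         provenance = list(source = source, window_start = window[1],
                           window_end = window[2])),
    class = "visit_table")
}

#' @export
print.visit_table <- function(x, ...) {
  cat(sprintf("<visit_table> %d visit records, %d variables (%s)\n",
              nrow(x$raw), ncol(x$raw), attr(x$dictionary, "version")))
  cat(sprintf("  source: %s; extraction window %s .. %s\n",
              x$provenance$source, x$provenance$window_start,
              x$provenance$window_end))
  st <- table(factor(x$status, levels = c("ok", "missing", "type_failure")))
  cat(sprintf("  fields: %d ok, %d missing, %d type failures\n",
              st[["ok"]], st[["missing"]], st[["type_failure"]]))
  invisible(x)
}

#' Number of visit records
#' @param table A `visit_table`.
#' @return Integer row count.
#' @export
n_visits <- function(table) {
  stopifnot(inherits(table, "visit_table"))
  nrow(table$raw)
}

#' Read a flat ICHOM visit table from CSV
#'
#' The header row must contain every dictionary variable (order-insensitive).
#' Empty cells are missing values; nothing is interpreted as `NA` so raw
#' values survive a write/read round trip verbatim.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param dict A [data_dictionary()].
#' @param extra_columns `"error"` (strict, default) fails on columns not in
#'   the dictionary; `"ignore"` drops them with a warning.
#' @inheritParams visit_table
#' @return A [visit_table()].
#' @export
read_visit_table <- function(path, dict = default_dictionary(),
                             extra_columns = c("error", "ignore"),
                             source = path,
                             window = c("2006-01-01", "2017-11-07")) {
  extra_columns <- match.arg(extra_columns)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(0), fileEncoding = "UTF-8")
  nms <- dictionary_names(dict)
  missing_cols <- setdiff(nms, names(raw))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(raw), nms)
  if (length(extra)) {
    if (extra_columns == "error")
      stop("schema error: unknown column(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    raw <- raw[nms]
  }
  visit_table(raw, dict, source = source, window = window)
}

#' Write a flat ICHOM visit table to CSV
#'
#' Raw values are written verbatim; reading the file back with
#' [read_visit_table()] reproduces them exactly.
#'
#' @param table A `visit_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_visit_table <- function(table, path) {
  stopifnot(inherits(table, "visit_table"))
  ok <- tryCatch({
    utils::write.csv(table$raw, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write file: ", path, " (", conditionMessage(ok), ")",
         call. = FALSE)
  invisible(path)
}

#' Code list
#'
#' A labelled set of diagnosis or medication codes with an exact or prefix
#' match mode. ICD-9 codes are kept as dotted strings (`"428.31"`).
#'
#' @param label Short label.
#' @param codes Non-empty character vector of non-empty code strings.
#' @param match `"exact"` or `"prefix"` (ATC-style hierarchical matching).
#' @return An object of class `code_list`.
#' @export
code_list <- function(label, codes, match = c("exact", "prefix")) {
  match <- match.arg(match)
  codes <- as.character(codes)
  if (length(codes) == 0L || any(!nzchar(codes)) || anyNA(codes))
    stop("code list must be a non-empty set of non-empty codes",
         call. = FALSE)
  structure(list(label = label, codes = unique(codes), match = match),
            class = "code_list")
}

#' @export
print.code_list <- function(x, ...) {
  cat(sprintf("<code_list> %s: %d codes (%s match)\n", x$label,
              length(x$codes), x$match))
  invisible(x)
}

#' Match codes against a code list
#' @param x Character vector of codes.
#' @param cl A `code_list`.
#' @return Logical vector: does each code belong to (or, in prefix mode,
#'   start with) a list entry?
#' @export
code_matches <- function(x, cl) {
  stopifnot(inherits(cl, "code_list"))
  x <- as.character(x)
  if (cl$match == "exact") return(x %in% cl$codes)
  out <- rep(FALSE, length(x))
  for (p in cl$codes) out <- out | startsWith(x, p)
  out
}

#' Read a code list from disk
#'
#' Accepts either plain text (one code per line, `#` comments allowed) or a
#' two-column CSV (`code, description`); the format is chosen by content.
#'
#' @param path File path.
#' @param label Label for the list; defaults to the file name.
#' @param match Match mode, see [code_list()].
#' @return A [code_list()].
#' @export
read_code_list <- function(path, label = basename(path),
                           match = c("exact", "prefix")) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl(",", lines[1])) {
    df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                          header = FALSE, colClasses = "character")
    codes <- trimws(df[[1]])
    if (tolower(codes[1]) %in% c("code", "codes")) codes <- codes[-1]
  } else {
    codes <- lines
  }
  code_list(label, codes, match = match)
}

#' Write a code list to disk (one code per line)
#' @param cl A `code_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_code_list <- function(cl, path) {
  stopifnot(inherits(cl, "code_list"))
  writeLines(cl$codes, path)
  invisible(path)
}

#' Built-in ICD-9 heart-failure cohort code list
#'
#' The 19 ICD-9 codes of the 428 family used to select the congestive
#' heart-failure cohort.
#'
#' @return A [code_list()] with exact matching.
#' @export
hf_code_list <- function() {
  code_list("icd9-heart-failure",
            c("428", "428.0", "428.1", "428.2", "428.20", "428.21", "428.22",
              "428.23", "428.3", "428.30", "428.31", "428.32", "428.33",
              "428.4", "428.40", "428.41", "428.42", "428.43", "428.9"),
            match = "exact")
}

#' Default condition and medication code lists
#'
#' Stand-in code lists for the baseline-health and treatment mappings. The
#' comorbidity, procedure and medication code lists used in the original
#' assessment are not published, so these are documented synthetic defaults:
#' ICD-9 427.31 (atrial fibrillation), 410/412 (myocardial infarction), 401
#' (hypertension), 250 (diabetes), 88.72 (echocardiography), 303/305.0
#' (alcohol), 305.1/V15.82 (tobacco); ATC prefixes C07 (beta blockers), C08
#' (calcium channel blockers), C01AA05 (digoxin), C03 (diuretics). Supply
#' site-specific lists via [read_code_list()] to replace them.
#'
#' @return Named list of [code_list()] objects keyed by flat-table variable.
#' @export
default_code_lists <- function() {
  list(
    atrial_fibrillation = code_list("icd9-af", "427.31", match = "prefix"),
    prior_mi = code_list("icd9-mi", c("410", "412"), match = "prefix"),
    hypertension = code_list("icd9-htn", "401", match = "prefix"),
    diabetes_mellitus = code_list("icd9-dm", "250", match = "prefix"),
    echocardiogram = code_list("icd9-echo", "88.72", match = "prefix"),
    alcohol_use = code_list("icd9-alcohol", c("303", "305.0"),
                            match = "prefix"),
    smoking_status = code_list("icd9-smoking", c("305.1", "V15.82"),
                               match = "prefix"),
    beta_blocker = code_list("atc-beta-blocker", "C07", match = "prefix"),
    calcium_channel_blocker = code_list("atc-ccb", "C08", match = "prefix"),
    digoxin = code_list("atc-digoxin", "C01AA05", match = "prefix"),
    diuretics = code_list("atc-diuretics", "C03", match = "prefix")
  )
}
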