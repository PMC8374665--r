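#' Parse one raw value against a variable specification
#'
#' Total function: every `(text, spec)` pair yields exactly one parse status.
#' Empty text is `missing`; text matching the spec's kind and format yields a
#' typed value with status `ok`; anything else is a `type_failure`. Never
#' raises for ordinary text.
#'
#' Conventions baked in here (and relied on downstream): the unknown sentinel
#' `999` parses as a legal value, not as missing — missingness is the empty
#' field only; a height/weight of `0` parses as a valid numeric (it is the
#' range check's job to flag it); dates are accepted both in the DD/MM/YYYY
#' dictionary dialect and in ISO 8601.
#'
#' @param raw Character scalar as read from the file (`NA` treated as empty).
#' @param spec A [variable_spec()].
#' @return A list with elements `value` (typed value, or `NA`) and `status`
#'   (one of `"ok"`, `"missing"`, `"type_failure"`).
#' @export
#' @examples
#' parse_value("07/11/2017", default_dictionary()[["date_of_arrival"]])
#' parse_value("", default_dictionary()[["height"]])$status
#' parse_value("abc", default_dictionary()[["height"]])$status
parse_value <- function(raw, spec) {
  stopifnot(inherits(spec, "variable_spec"))
  col <- parse_column(as.character(raw)[1], spec)
  list(value = col$value[[1]], status = col$status[1])
}

# Vectorised parser for one column. Returns list(value = typed vector,
# status = character vector). Typed vector is Date for date kinds (the
# unknown code, when legal, maps to NA value with status "ok"), numeric for
# numeric, integer for categorical/count, character for identifiers.
parse_column <- function(raw, spec) {
  raw <- as.character(raw)
  raw[is.na(raw)] <- ""
  txt <- trimws(raw)
  n <- length(txt)
  status <- rep("ok", n)
  status[txt == ""] <- "missing"

  int_re <- "^-?[0-9]+$"
  num_re <- "^-?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"

  if (spec$value_kind == "identifier") {
    value <- ifelse(status == "missing", NA_character_, txt)
  } else if (spec$value_kind == "date") {
    value <- as.Date(rep(NA_real_, n), origin = "1970-01-01")
    idx <- which(status == "ok")
    if (length(idx)) {
      sub <- txt[idx]
      d <- as.Date(sub, format = spec$date_format)
      iso <- is.na(d) & grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", sub)
      if (any(iso)) d[iso] <- as.Date(sub[iso], format = "%Y-%m-%d")
      # round-trip guard: as.Date("31/02/2010", "%d/%m/%Y") is NA already,
      # but "7/11/2017" (no zero padding) is legal; keep it.
      ok <- !is.na(d)
      unk <- if (is.null(spec$unknown_code)) rep(FALSE, length(sub)) else
        !ok & sub == as.character(spec$unknown_code)
      status[idx][!ok & !unk] <- "type_failure"
      value[idx[ok]] <- d[ok]
    }
  } else if (spec$value_kind == "numeric") {
    value <- rep(NA_real_, n)
    idx <- which(status == "ok")
    if (length(idx)) {
      ok <- grepl(num_re, txt[idx])
      status[idx][!ok] <- "type_failure"
      value[idx[ok]] <- as.numeric(txt[idx][ok])
    }
  } else { # categorical, count
    value <- rep(NA_integer_, n)
    idx <- which(status == "ok")
    if (length(idx)) {
      ok <- grepl(int_re, txt[idx])
      v <- suppressWarnings(as.integer(txt[idx][ok]))
      ok2 <- ok
      ok2[ok] <- !is.na(v)          # overflow guard
      status[idx][!ok2] <- "type_failure"
      value[idx[ok2]] <- v[!is.na(v)]
    }
  }
  list(value = value, status = status)
}

# Parse every dictionary column of a raw character data.frame.
parse_table <- function(raw_df, dict) {
  nms <- dictionary_names(dict)
  typed <- vector("list", length(nms))
  names(typed) <- nms
  status <- matrix("missing", nrow = nrow(raw_df), ncol = length(nms),
                   dimnames = list(NULL, nms))
  for (nm in nms) {
    col <- parse_column(raw_df[[nm]], dict[[nm]])
    typed[[nm]] <- col$value
    status[, nm] <- col$status
  }
  list(typed = typed, status = status)
}
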