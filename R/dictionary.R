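#' Variable specification
#'
#' One entry of the ICHOM heart-failure data dictionary: the variable's name,
#' area, value kind and, depending on the kind, its code domain, plausibility
#' range or date format.
#'
#' @param name Variable identifier (unique within a dictionary).
#' @param label Human-readable item label as printed on case report forms.
#' @param area One of `"identifiers"`, `"demographic"`, `"baseline_health"`,
#'   `"treatment"`, `"burden_of_care"`, `"mortality"`.
#' @param value_kind One of `"identifier"`, `"date"`, `"numeric"`,
#'   `"categorical"`, `"count"`.
#' @param allowed_codes Integer vector of legal codes for categorical
#'   variables (e.g. `c(0, 1, 999)`); for count variables, codes accepted in
#'   addition to any non-negative integer (the unknown code).
#' @param numeric_range Length-2 numeric `c(min, max)` plausibility range, or
#'   `NULL`.
#' @param units Measurement units for numeric variables (`"cm"`, `"kg"`).
#' @param date_format Input date pattern; `"%d/%m/%Y"` is the ICHOM dialect.
#'   ISO 8601 (`YYYY-MM-DD`) is always accepted as well.
#' @param date_range Length-2 `Date` (or coercible) plausibility window for
#'   date variables, or `NULL` meaning "use the table's extraction window"
#'   for event dates / unchecked for identifiers.
#' @param unknown_code Integer sentinel meaning "unknown" (999), or `NULL`.
#'   When present it must belong to `allowed_codes` for coded variables, and
#'   is accepted as a legal raw value for date/count variables.
#' @param valid_incompleteness Name of a rule under which emptiness of this
#'   field is valid (currently `"only_if_died_during_visit"`), or `NULL`.
#'
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, label = name, area, value_kind,
                          allowed_codes = NULL, numeric_range = NULL,
                          units = NULL, date_format = "%d/%m/%Y",
                          date_range = NULL, unknown_code = NULL,
                          valid_incompleteness = NULL) {
  areas <- c("identifiers", "demographic", "baseline_health", "treatment",
             "burden_of_care", "mortality")
  kinds <- c("identifier", "date", "numeric", "categorical", "count")
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  area <- match.arg(area, areas)
  value_kind <- match.arg(value_kind, kinds)
  if (!is.null(allowed_codes)) {
    allowed_codes <- as.integer(allowed_codes)
    stopifnot(!anyNA(allowed_codes))
  }
  if (!is.null(numeric_range)) {
    numeric_range <- as.numeric(numeric_range)
    stopifnot(length(numeric_range) == 2L, numeric_range[1] < numeric_range[2])
  }
  if (!is.null(date_range)) {
    date_range <- as.Date(date_range)
    stopifnot(length(date_range) == 2L, date_range[1] <= date_range[2])
  }
  if (!is.null(unknown_code)) {
    unknown_code <- as.integer(unknown_code)
    if (value_kind == "categorical" && !unknown_code %in% allowed_codes)
      stop("unknown_code must be a member of allowed_codes", call. = FALSE)
  }
  structure(
    list(name = name, label = label, area = area, value_kind = value_kind,
         allowed_codes = allowed_codes, numeric_range = numeric_range,
         units = units, date_format = date_format, date_range = date_range,
         unknown_code = unknown_code,
         valid_incompleteness = valid_incompleteness),
    class = "variable_spec")
}

#' Data dictionary
#'
#' Ordered collection of [variable_spec()] entries with a version label.
#'
#' @param specs List of `variable_spec` objects; names must be unique.
#' @param version Version label.
#' @return An object of class `data_dictionary` (a named list of specs with a
#'   `version` attribute).
#' @export
data_dictionary <- function(specs, version = "0") {
  stopifnot(is.list(specs), length(specs) > 0L,
            all(vapply(specs, inherits, logical(1), "variable_spec")))
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate variable names in dictionary: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(specs) <- nms
  structure(specs, version = version, class = "data_dictionary")
}

#' @export
print.data_dictionary <- function(x, ...) {
  cat(sprintf("<data_dictionary> version %s, %d variables\n",
              attr(x, "version"), length(x)))
  for (s in x)
    cat(sprintf("  %-24s %-15s %s\n", s$name, s$area, s$value_kind))
  invisible(x)
}

#' Variable names of a dictionary
#' @param dict A `data_dictionary`.
#' @return Character vector of variable names, in dictionary order.
#' @export
dictionary_names <- function(dict) {
  stopifnot(inherits(dict, "data_dictionary"))
  vapply(dict, `[[`, character(1), "name")
}

cat01999 <- function(name, label, area = "baseline_health") {
  variable_spec(name, label, area = area, value_kind = "categorical",
                allowed_codes = c(0L, 1L, 999L), unknown_code = 999L)
}

#' Default ICHOM heart-failure pilot dictionary
#'
#' The 22-variable schema of the pilot assessment: the 21 selected ICHOM
#' heart-failure items organised in six areas, plus a visit identifier used to
#' distinguish visit records. Yes/no items use codes 0=No, 1=Yes, 999=Unknown;
#' sex uses 1=Male, 2=Female; dates are DD/MM/YYYY. Plausibility ranges for
#' height (100-230 cm), weight (20-300 kg) and date of birth are package
#' defaults, configurable via [apply_dictionary_config()]; event dates default
#' to the table's extraction window.
#'
#' @return A `data_dictionary` of 22 variables. Date of death carries unknown
#'   code 999 and the `only_if_died_during_visit` valid-incompleteness rule.
#' @export
#' @examples
#' d <- default_dictionary()
#' length(d)
#' d[["sex"]]$allowed_codes
default_dictionary <- function() {
  specs <- list(
    variable_spec("patient_id", "Patient ID", area = "identifiers",
                  value_kind = "identifier"),
    variable_spec("visit_id", "Visit ID", area = "identifiers",
                  value_kind = "identifier"),
    variable_spec("date_of_birth", "Age", area = "demographic",
                  value_kind = "date",
                  date_range = c("1900-01-01", "2017-11-07")),
    variable_spec("sex", "Sex", area = "demographic",
                  value_kind = "categorical", allowed_codes = c(1L, 2L)),
    cat01999("atrial_fibrillation", "Atrial fibrillation"),
    cat01999("prior_mi", "Prior myocardial infarction"),
    cat01999("hypertension", "Hypertension"),
    cat01999("diabetes_mellitus", "Diabetes mellitus"),
    cat01999("echocardiogram", "Echocardiogram performed"),
    variable_spec("height", "Height", area = "baseline_health",
                  value_kind = "numeric", numeric_range = c(100, 230),
                  units = "cm"),
    variable_spec("weight", "Weight", area = "baseline_health",
                  value_kind = "numeric", numeric_range = c(20, 300),
                  units = "kg"),
    cat01999("alcohol_use", "Alcohol use"),
    cat01999("smoking_status", "Smoking status"),
    cat01999("beta_blocker", "Beta blocker", area = "treatment"),
    cat01999("calcium_channel_blocker", "Calcium channel blocker",
             area = "treatment"),
    cat01999("digoxin", "Digoxin", area = "treatment"),
    cat01999("diuretics", "Diuretics", area = "treatment"),
    variable_spec("date_of_arrival", "Date of arrival",
                  area = "burden_of_care", value_kind = "date"),
    variable_spec("date_of_discharge", "Date of discharge",
                  area = "burden_of_care", value_kind = "date"),
    variable_spec("hospital_admissions", "Hospital admissions",
                  area = "burden_of_care", value_kind = "count",
                  unknown_code = 999L),
    variable_spec("hospital_appointments", "Hospital appointments",
                  area = "burden_of_care", value_kind = "count",
                  unknown_code = 999L),
    variable_spec("date_of_death", "Date of death", area = "mortality",
                  value_kind = "date", unknown_code = 999L,
                  valid_incompleteness = "only_if_died_during_visit")
  )
  data_dictionary(specs, version = "ichom-hf-pilot-1")
}

#' Override dictionary entries from a configuration file
#'
#' Reads a YAML file with one key per variable; supported sub-keys are
#' `range` (length-2 numeric), `date_range` (length-2 dates), `codes`
#' (integer vector) and `format` (date pattern). Unknown variables are an
#' error.
#'
#' @param dict A `data_dictionary` to modify.
#' @param path Path to the YAML configuration file.
#' @return The modified `data_dictionary`.
#' @export
apply_dictionary_config <- function(dict, path) {
  stopifnot(inherits(dict, "data_dictionary"))
  cfg <- yaml::read_yaml(path)
  for (nm in names(cfg)) {
    if (!nm %in% names(dict))
      stop("dictionary config names unknown variable: ", nm, call. = FALSE)
    spec <- dict[[nm]]
    ov <- cfg[[nm]]
    if (!is.null(ov$range)) {
      rng <- as.numeric(ov$range)
      stopifnot(length(rng) == 2L, rng[1] < rng[2])
      spec$numeric_range <- rng
    }
    if (!is.null(ov$date_range)) spec$date_range <- as.Date(unlist(ov$date_range))
    if (!is.null(ov$codes)) spec$allowed_codes <- as.integer(unlist(ov$codes))
    if (!is.null(ov$format)) spec$date_format <- ov$format
    dict[[nm]] <- spec
  }
  dict
}
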