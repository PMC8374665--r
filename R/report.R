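# Dimension-level aggregation and machine/human-readable quality reports.

#' Aggregate component scores into a dimension score
#'
#' Unweighted arithmetic mean, rounded half-up to two decimals (trailing
#' zeros are dropped in text output, so a uniqueness pair of 98.8 and 97.2
#' reports as 98).
#'
#' @param component_scores Numeric vector of at least one component score.
#' @return Numeric scalar in percent.
#' @export
#' @examples
#' aggregate_dimension(c(98.8, 97.2))
#' aggregate_dimension(c(100, 100, 91.21))
aggregate_dimension <- function(component_scores) {
  stopifnot(length(component_scores) >= 1, is.numeric(component_scores))
  round_half_up(mean(component_scores), 2)
}

ALL_CHECKS <- c("uniqueness", "consistency", "completeness", "correctness",
                "stability")

#' Run the full data-quality assessment and build a report
#'
#' Executes the selected checks against one visit table and assembles a
#' `quality_report`: per-dimension scores with component breakdowns, the
#' bundle of monthly stability series (stability carries no scalar score —
#' it is read qualitatively), findings counts and provenance. Checks that
#' were not requested are marked `not computed`.
#'
#' @param table A [visit_table()].
#' @param checks Character subset of
#'   `c("uniqueness", "consistency", "completeness", "correctness",
#'   "stability")`.
#' @param rules Multivariate rules for [consistency_by_rules()].
#' @param exclusions Valid-incompleteness masks for [completeness()].
#' @param bmi_bounds Length-2 BMI plausibility bounds.
#' @param min_month_support Low-support threshold for stability series.
#' @param stability_variables Indicator variables profiled over time
#'   (default: the four medications and four past conditions).
#' @param shift_detection Run [detect_shift()] on each stability series
#'   (off by default; the scan is an extension of the qualitative reading).
#' @param seed Seed recorded in provenance (for synthetic inputs).
#' @return An object of class `quality_report`.
#' @export
build_report <- function(table, checks = ALL_CHECKS,
                         rules = default_rules(), exclusions = list(),
                         bmi_bounds = c(10, 70), min_month_support = 10,
                         stability_variables = c(
                           "beta_blocker", "calcium_channel_blocker",
                           "digoxin", "diuretics", "atrial_fibrillation",
                           "hypertension", "diabetes_mellitus", "prior_mi"),
                         shift_detection = FALSE, seed = NULL) {
  stopifnot(inherits(table, "visit_table"))
  checks <- match.arg(checks, ALL_CHECKS, several.ok = TRUE)
  dims <- list()
  results <- list()
  findings <- list()

  if ("uniqueness" %in% checks) {
    u1 <- uniqueness_result1(table)
    u2 <- uniqueness_result2(table)
    results$uniqueness_result1 <- u1
    results$uniqueness_result2 <- u2
    dims$uniqueness <- list(
      score = aggregate_dimension(c(u1$score, u2$score)),
      components = list(result1 = u1$score, result2 = u2$score))
    findings <- c(findings, list(u1$findings, u2$findings))
  } else dims$uniqueness <- list(score = NA, not_computed = TRUE)

  if ("consistency" %in% checks) {
    ct <- consistency_by_type(table)
    cr <- consistency_by_range(table)
    cu <- consistency_by_rules(table, rules)
    results$consistency_by_type <- ct
    results$consistency_by_range <- cr
    results$consistency_by_rules <- cu
    dims$consistency <- list(
      score = consistency_overall(list(ct, cr, cu)),
      components = list(type = ct$score, range = cr$score,
                        rules = cu$score))
    findings <- c(findings, list(ct$findings, cr$findings, cu$findings))
  } else dims$consistency <- list(score = NA, not_computed = TRUE)

  if ("completeness" %in% checks) {
    cm <- completeness(table, exclusions)
    results$completeness <- cm
    dims$completeness <- list(
      score = cm$score,
      components = stats::setNames(as.list(cm$per_variable$score),
                                   cm$per_variable$variable))
    findings <- c(findings, list(cm$findings))
  } else dims$completeness <- list(score = NA, not_computed = TRUE)

  if ("correctness" %in% checks) {
    bp <- bmi_plausibility(table, bmi_bounds[1], bmi_bounds[2])
    ho <- history_order_violations(table)
    inv <- inversion_candidates(table, bmi_bounds[1], bmi_bounds[2])
    results$bmi_plausibility <- bp
    results$history_order <- ho
    results$inversion_candidates <- inv
    dims$correctness <- list(
      score = correctness_overall(bp, ho),
      components = c(list(bmi_plausibility = bp$score),
                     stats::setNames(as.list(ho$per_variable$score),
                                     ho$per_variable$variable)),
      n_inversion_candidates = nrow(inv),
      n_swap_plausible = sum(inv$swap_plausible))
    findings <- c(findings, list(bp$findings, ho$findings))
  } else dims$correctness <- list(score = NA, not_computed = TRUE)

  stability <- NULL
  if ("stability" %in% checks) {
    stability <- lapply(stability_variables, function(nm)
      monthly_frequency(table, nm, threshold = min_month_support))
    names(stability) <- stability_variables
    if (shift_detection)
      attr(stability, "shifts") <-
        lapply(stability, detect_shift)
  } else dims$stability <- list(not_computed = TRUE)

  all_findings <- do.call(rbind, c(findings, list(empty_findings())))
  structure(
    list(dimensions = dims, stability = stability, results = results,
         findings = all_findings,
         findings_summary = if (nrow(all_findings))
           as.list(table(all_findings$check)) else list(),
         provenance = list(
           source = table$provenance$source,
           window = c(format(table$provenance$window_start),
                      format(table$provenance$window_end)),
           dictionary_version = attr(table$dictionary, "version"),
           n_records = n_visits(table), seed = seed,
           checks = checks),
         tool_version = as.character(utils::packageVersion("ichomdq"))),
    class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>", x$provenance$n_records, "visit records from",
      x$provenance$source, "\n")
  for (nm in c("uniqueness", "consistency", "completeness", "correctness")) {
    d <- x$dimensions[[nm]]
    if (isTRUE(d$not_computed)) {
      cat(sprintf("  %-13s not computed\n", nm))
    } else {
      comp <- paste(sprintf("%s=%s", names(d$components),
                            vapply(d$components, format, character(1))),
                    collapse = ", ")
      cat(sprintf("  %-13s %s%%  (%s)\n", nm, format(d$score), comp))
    }
  }
  if (!is.null(x$stability))
    cat(sprintf("  %-13s %d monthly series (qualitative; no scalar score)\n",
                "stability", length(x$stability)))
  if (length(x$findings_summary)) {
    cat("  findings:",
        paste(sprintf("%s=%s", names(x$findings_summary),
                      unlist(x$findings_summary)), collapse = ", "), "\n")
  }
  invisible(x)
}

report_to_list <- function(report) {
  ser_series <- function(s) list(
    variable = attr(s, "variable"), threshold = attr(s, "threshold"),
    n_excluded = attr(s, "n_excluded"),
    month = format(s$month), numerator = s$numerator,
    denominator = s$denominator, frequency = s$frequency,
    low_support = s$low_support)
  list(dimensions = report$dimensions,
       stability = if (is.null(report$stability)) NULL else
         lapply(report$stability, ser_series),
       findings_summary = report$findings_summary,
       provenance = report$provenance,
       tool_version = report$tool_version)
}

#' Write a quality report to JSON
#'
#' Serialises the dimension scores, component breakdowns, stability series
#' and provenance (not the record-level findings; export those with
#' [write_findings()]). The written file round-trips through
#' [read_report()].
#'
#' @param report A `quality_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "quality_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON quality report
#' @param path Path written by [write_report()].
#' @return The report as a plain list (scores, series, provenance).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export record-level findings to CSV
#' @param report A `quality_report` (or a `check_result`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_findings <- function(report, path) {
  f <- if (inherits(report, "quality_report")) report$findings
       else report$findings
  utils::write.csv(f, path, row.names = FALSE)
  invisible(path)
}

#' Plot monthly stability series
#'
#' Relative-frequency trend lines per indicator, low-support months marked.
#'
#' @param series_list Named list of `monthly_series` (e.g.
#'   `report$stability`).
#' @return A ggplot object.
#' @export
plot_stability <- function(series_list) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- do.call(rbind, lapply(names(series_list), function(nm) {
    s <- series_list[[nm]]
    data.frame(variable = nm, month = s$month, frequency = s$frequency,
               low_support = s$low_support)
  }))
  ggplot2::ggplot(df[!is.na(df$frequency), ],
                  ggplot2::aes(x = month, y = frequency,
                               colour = variable)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = function(d) d[d$low_support, ],
                        shape = 1) +
    ggplot2::labs(x = "month", y = "monthly relative frequency",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Height-weight scatter for correctness review
#'
#' Bivariate height/weight plot with the main diagonal; points below it
#' (weight exceeding height) are inversion candidates.
#'
#' @param table A [visit_table()].
#' @return A ggplot object.
#' @export
plot_height_weight <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ok <- table$status[, "height"] == "ok" & table$status[, "weight"] == "ok"
  df <- data.frame(height = table$typed$height[ok],
                   weight = table$typed$weight[ok])
  df <- df[df$height > 0 & df$weight > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = height, y = weight)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "height (cm)", y = "weight (kg)") +
    ggplot2::theme_minimal()
}
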