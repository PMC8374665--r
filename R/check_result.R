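# Round half away from zero to `digits` decimals. Reported scores use
# half-up rounding; base round() is round-half-even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Result of one data-quality check
#'
#' Holds the violating-record count (numerator), the assessable-record count
#' (denominator), the reported score in percent and record-level findings.
#' Checks that score each variable separately (type, range, completeness)
#' aggregate by unweighted mean over variables; for those the per-variable
#' breakdown carries the numerator/denominator pairs from which each variable
#' score is `100 * (1 - numerator/denominator)`, and the pooled counts are
#' stored for reference.
#'
#' @param check_id Check identifier, e.g. `"uniqueness_result1"`.
#' @param numerator,denominator Pooled violating / assessable counts.
#' @param per_variable Optional data.frame with columns `variable`,
#'   `numerator`, `denominator`, `score` (and check-specific extras).
#' @param findings Data.frame of record-level findings (`record`, `variable`,
#'   `check`, `detail`), possibly empty.
#' @param method `"pooled"`: score from the pooled counts;
#'   `"variable_mean"`: unweighted mean of per-variable scores.
#' @param flags Character vector of warnings, e.g. `"vacuous_denominator"`.
#' @return An object of class `check_result` with fields above plus `score`
#'   (rounded half-up to 2 decimals) and `fraction` (unrounded violation
#'   fraction for pooled checks).
#' @export
check_result <- function(check_id, numerator, denominator,
                         per_variable = NULL, findings = empty_findings(),
                         method = c("pooled", "variable_mean"),
                         flags = character(0)) {
  method <- match.arg(method)
  stopifnot(numerator >= 0, denominator >= 0, numerator <= denominator ||
              denominator == 0)
  if (method == "pooled") {
    fraction <- if (denominator > 0) numerator / denominator else 0
    if (denominator == 0) flags <- union(flags, "vacuous_denominator")
    score <- round_half_up(100 * (1 - fraction), 2)
  } else {
    stopifnot(is.data.frame(per_variable), nrow(per_variable) > 0)
    fraction <- if (denominator > 0) numerator / denominator else 0
    score <- round_half_up(mean(per_variable$score), 2)
  }
  structure(
    list(check_id = check_id, numerator = numerator,
         denominator = denominator, fraction = fraction, score = score,
         method = method, per_variable = per_variable, findings = findings,
         flags = flags),
    class = "check_result")
}

empty_findings <- function() {
  data.frame(record = integer(0), variable = character(0),
             check = character(0), detail = character(0),
             stringsAsFactors = FALSE)
}

new_findings <- function(record, variable, check, detail) {
  if (length(record) == 0) return(empty_findings())
  data.frame(record = as.integer(record),
             variable = rep_len(as.character(variable), length(record)),
             check = rep_len(check, length(record)),
             detail = rep_len(as.character(detail), length(record)),
             stringsAsFactors = FALSE)
}

#' @export
print.check_result <- function(x, ...) {
  cat(sprintf("<check_result> %s: score %.2f%% (%d/%d violating, %s)\n",
              x$check_id, x$score, x$numerator, x$denominator, x$method))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  if (!is.null(x$per_variable)) {
    bad <- x$per_variable[x$per_variable$numerator > 0, , drop = FALSE]
    if (nrow(bad))
      for (i in seq_len(nrow(bad)))
        cat(sprintf("  %-24s %.2f%% (%d/%d)\n", bad$variable[i], bad$score[i],
                    bad$numerator[i], bad$denominator[i]))
  }
  invisible(x)
}

# Variable-mean result assembled from per-variable counts. Vacuous variables
# (denominator 0) score 100 and raise a flag.
variable_mean_result <- function(check_id, per_counts, findings,
                                 extra = NULL) {
  score <- ifelse(per_counts$denominator > 0,
                  round_half_up(100 * (1 - per_counts$numerator /
                                         per_counts$denominator), 2),
                  100)
  per <- cbind(per_counts, score = score)
  if (!is.null(extra)) per <- cbind(per, extra)
  flags <- if (any(per_counts$denominator == 0)) "vacuous_denominator"
           else character(0)
  check_result(check_id, numerator = sum(per_counts$numerator),
               denominator = sum(per_counts$denominator),
               per_variable = per, findings = findings,
               method = "variable_mean", flags = flags)
}
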