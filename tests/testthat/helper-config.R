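# Generator configuration with every error class disabled: the clean study
# table onto which tests plant exactly the defects they need.
zero_errors <- function(...) {
  z <- list(zero_height_weight = err_plan(n = 0),
            out_of_range_height = err_plan(n = 0),
            out_of_range_weight = err_plan(n = 0),
            early_arrival_dates = err_plan(n = 0),
            hw_inversion = err_plan(n = 0),
            low_bmi = err_plan(n = 0),
            high_bmi = err_plan(n = 0),
            duplicate_id = err_plan(n = 0),
            same_day_duplicate = err_plan(n = 0),
            history_flip = err_plan(n = 0))
  override <- list(...)
  z[names(override)] <- override
  z
}

clean_config <- function(n_patients = 200, seed = 1, ...) {
  generator_config(n_patients = n_patients, seed = seed,
                   regime_shift = NULL, thin_months = NULL,
                   errors = zero_errors(), ...)
}

# exact-size clean table: generate a little extra and truncate
clean_table_of_size <- function(n_rows, seed, ...) {
  np <- ceiling(n_rows / 3.2)
  cfg <- clean_config(n_patients = np, seed = seed, ...)
  tb <- generate_visit_table(cfg)
  while (n_visits(tb) < n_rows) {
    np <- ceiling(np * 1.5)
    cfg <- clean_config(n_patients = np, seed = seed, ...)
    tb <- generate_visit_table(cfg)
  }
  visit_table(tb$raw[seq_len(n_rows), , drop = FALSE], tb$dictionary,
              source = tb$provenance$source,
              window = c(tb$provenance$window_start,
                         tb$provenance$window_end))
}
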