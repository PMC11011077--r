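# Internal helpers: argument checks and reproducible seed derivation.

stop_bad_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "gbmsize_input_error")
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bad_input("`%s` must be a single finite number", name)
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop_bad_input("`%s` = %g is outside its allowed range", name, x)
  }
  invisible(x)
}

assert_prob_vector <- function(p, name, len) {
  if (!is.numeric(p) || length(p) != len || any(!is.finite(p)) ||
      any(p < 0) || any(p > 1)) {
    stop_bad_input("`%s` must be %d probabilities in [0, 1]", name, len)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop_bad_input("`%s` must sum to 1 (got %.12f)", name, sum(p))
  }
  invisible(p)
}

assert_cohort <- function(table, require_outcome = TRUE) {
  cols <- c("age", "sex", "surgery", "oncology", "mgmt",
            "diameter_cm", "cv_cm3", "wv_cm3")
  if (require_outcome) cols <- c(cols, "time_months", "event")
  missing_cols <- setdiff(cols, names(table))
  if (!is.data.frame(table) || length(missing_cols) > 0) {
    stop_bad_input("cohort table is missing column(s): %s",
                   paste(missing_cols, collapse = ", "))
  }
  if (nrow(table) == 0L) stop_bad_input("cohort table has no rows")
  invisible(table)
}

# Deterministic 31-bit seed derived from a master seed and a label path.
# A polynomial string hash keeps substreams (covariates / survival /
# censoring / per-repetition) reproducible and independent of call order.
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), ...), collapse = "/")
  h <- 0
  for (k in utf8ToInt(key)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Cheap arithmetic substream for per-repetition seeding inside hot loops
# (exact in double precision for rep < 2^22).
shift_seed <- function(seed, rep) {
  as.integer((as.numeric(seed) + as.numeric(rep) * 2654435761) %% 2147483647)
}
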