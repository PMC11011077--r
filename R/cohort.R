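# Synthetic cohort generation: covariates via quartile-matched marginals
# joined by a Gaussian copula, outcome via a Weibull proportional-hazards
# model, censoring via a uniform potential-censoring window.

#' Draw patient covariates for a synthetic cohort
#'
#' Draws age (truncated normal matched to the configured median, IQR and
#' range), sex, the three tumour size variables (Gaussian copula with the
#' configured correlation matrix and quartile-matched marginals), surgery
#' (proportional-odds model whose intercepts reproduce `surgery_probs` at
#' mean size and whose slope is `surgery_size_assoc`), adjuvant oncology and
#' MGMT status. MGMT is drawn as a latent true status for every patient and
#' masked as `"unknown"` with probability `p_mgmt_missing`; the latent truth
#' is returned in the `mgmt_true` column (used by [generate_cohort()] for
#' the outcome model and dropped from the final table).
#'
#' @param config A [cohort_config()].
#' @param seed Optional override of the substream seed; by default a
#'   `"covariates"` substream is derived from `config$seed`.
#' @return A tibble with one row per patient and columns `age`, `sex`,
#'   `surgery`, `oncology`, `mgmt`, `mgmt_true`, `diameter_cm`, `cv_cm3`,
#'   `wv_cm3`.
#' @export
sample_covariates <- function(config, seed = NULL) {
  validate_cohort_config(config)
  set.seed(seed %||% derive_seed(config$seed, "covariates"))
  n <- config$n_patients
  marg <- cohort_marginals(config)

  age <- qdist(marg$age, runif(n))
  sex <- factor(ifelse(runif(n) < config$p_female, "female", "male"),
                levels = SEX_LEVELS)

  sizes <- draw_sizes(n, config, marg)
  surgery <- draw_surgery(sizes$z_size, config)
  oncology <- factor(
    ONCOLOGY_LEVELS[draw_categorical(n, config$oncology_probs)],
    levels = ONCOLOGY_LEVELS
  )
  mgmt_true <- factor(
    ifelse(runif(n) < config$p_mgmt_methylated_given_known,
           "methylated", "unmethylated"),
    levels = MGMT_LEVELS
  )
  mgmt <- mgmt_true
  mgmt[runif(n) < config$p_mgmt_missing] <- "unknown"

  tibble(
    age = age, sex = sex, surgery = surgery, oncology = oncology,
    mgmt = mgmt, mgmt_true = mgmt_true,
    diameter_cm = sizes$diameter, cv_cm3 = sizes$cv, wv_cm3 = sizes$wv
  )
}

# Correlated size triple through a Gaussian copula. `z_size` is the
# standardised average of the three latent normals: the single "how large
# is this tumour" score that drives the surgery-size association.
draw_sizes <- function(n, config, marg) {
  cc <- chol(config$size_copula_corr)
  draw <- function(m) {
    z <- matrix(rnorm(m * 3), m, 3) %*% cc
    dimnames(z) <- NULL
    list(
      diameter = qdist(marg$diameter, pnorm(z[, 1])),
      cv = qdist(marg$cv, pnorm(z[, 2])),
      wv = qdist(marg$wv, pnorm(z[, 3])),
      z_size = rowSums(z) / sqrt(sum(config$size_copula_corr))
    )
  }
  out <- draw(n)
  if (config$enforce_nesting) {
    for (iter in seq_len(100)) {
      bad <- which(out$wv <= out$cv)
      if (length(bad) == 0) break
      redo <- draw(length(bad))
      for (f in names(out)) out[[f]][bad] <- redo[[f]]
    }
  }
  out
}

# Proportional-odds draw over resection completeness. Categories are
# ordered from most to least complete; a positive slope pushes larger
# tumours toward less-complete resection, and the intercepts reproduce the
# configured category probabilities at z = 0 (mean size).
draw_surgery <- function(z_size, config) {
  completeness_order <- c("resection_100", "resection_90",
                          "resection_lt90", "biopsy")
  p <- config$surgery_probs[completeness_order]
  theta <- qlogis(cumsum(p)[1:3])
  cum <- plogis(outer(-config$surgery_size_assoc * z_size, theta, `+`))
  idx <- 1L + rowSums(runif(length(z_size)) > cum)
  factor(completeness_order[idx], levels = SURGERY_LEVELS)
}

draw_categorical <- function(n, probs) {
  1L + rowSums(runif(n) > matrix(cumsum(probs)[-length(probs)],
                                 n, length(probs) - 1L, byrow = TRUE))
}

#' Draw uncensored event times from a Weibull proportional-hazards model
#'
#' Inverse-transform sampling:
#' `T = scale * (-log(U) / exp(lp))^(1/shape)` with `U ~ Uniform(0, 1)`,
#' so the hazard of a patient with linear predictor `lp` is the Weibull
#' baseline hazard multiplied by `exp(lp)`. With `lp = 0` the median event
#' time is `scale * log(2)^(1/shape)`.
#'
#' @param linear_predictor Numeric vector of per-patient log relative
#'   hazards.
#' @param baseline_shape,baseline_scale Weibull parameters, both `> 0`
#'   (time in months).
#' @return Numeric vector of event times in months.
#' @export
sample_survival_times <- function(linear_predictor, baseline_shape,
                                  baseline_scale) {
  assert_number(baseline_shape, "baseline_shape", 0, strict_lower = TRUE)
  assert_number(baseline_scale, "baseline_scale", 0, strict_lower = TRUE)
  u <- runif(length(linear_predictor))
  baseline_scale * (-log(u) / exp(linear_predictor))^(1 / baseline_shape)
}

#' Apply a uniform potential-censoring window
#'
#' Each patient receives a potential censoring time
#' `C ~ Uniform(censor_lo, censor_hi)`; the observed time is `min(T, C)`
#' and the event indicator is 1 iff death occurs first (`T <= C`). No
#' observed time can exceed `censor_hi`.
#'
#' @param event_times Uncensored death times (months).
#' @param censor_lo,censor_hi Window bounds, `0 <= censor_lo < censor_hi`.
#' @return A tibble with columns `time_months` and `event`.
#' @export
apply_censoring <- function(event_times, censor_lo, censor_hi) {
  assert_number(censor_lo, "censor_lo", 0)
  if (!(censor_lo < censor_hi)) {
    stop_bad_input("`censor_lo` must be strictly below `censor_hi`")
  }
  cens <- runif(length(event_times), censor_lo, censor_hi)
  tibble(
    time_months = pmin(event_times, cens),
    event = as.integer(event_times <= cens)
  )
}

# Centred linear predictor of the configured proportional-hazards model.
linear_predictor <- function(covariates, config,
                             marginals = cohort_marginals(config)) {
  betas <- config$betas
  if (length(betas) == 0) return(rep(0, nrow(covariates)))
  centres <- beta_term_expectations(config, marginals)
  mgmt <- if ("mgmt_true" %in% names(covariates)) {
    covariates$mgmt_true
  } else {
    covariates$mgmt
  }
  columns <- list(
    age = covariates$age,
    sex_female = as.numeric(covariates$sex == "female"),
    surgery_resection_100 = as.numeric(covariates$surgery == "resection_100"),
    surgery_resection_90 = as.numeric(covariates$surgery == "resection_90"),
    surgery_resection_lt90 = as.numeric(covariates$surgery == "resection_lt90"),
    oncology_full_stupp = as.numeric(covariates$oncology == "full_stupp"),
    oncology_partial_stupp = as.numeric(covariates$oncology == "partial_stupp"),
    mgmt_methylated = as.numeric(mgmt == "methylated"),
    diameter = covariates$diameter_cm,
    cv = covariates$cv_cm3,
    wv = covariates$wv_cm3,
    log_diameter = log(covariates$diameter_cm),
    log_cv = log(covariates$cv_cm3),
    log_wv = log(covariates$wv_cm3)
  )
  lp <- rep(0, nrow(covariates))
  for (nm in names(betas)) {
    lp <- lp + betas[[nm]] * (columns[[nm]] - centres[[nm]])
  }
  lp
}

#' Generate a complete synthetic cohort
#'
#' Composes [sample_covariates()], the configured proportional-hazards
#' outcome model ([sample_survival_times()]) and [apply_censoring()] into a
#' full survival table. With all `betas` zero the outcome is independent of
#' every covariate; with the default `"paper_like"` configuration, cohort
#' summaries match the published cohort within Monte-Carlo tolerance.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `age`, `sex`, `surgery`, `oncology`,
#'   `mgmt`, `diameter_cm`, `cv_cm3`, `wv_cm3`, `time_months`, `event`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 100, seed = 7))
#' table(cohort$event)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  marg <- cohort_marginals(config)
  covs <- sample_covariates(config)
  lp <- linear_predictor(covs, config, marg)
  set.seed(derive_seed(config$seed, "survival"))
  death <- sample_survival_times(lp, config$baseline_shape,
                                 config$baseline_scale)
  set.seed(derive_seed(config$seed, "censoring"))
  outcome <- apply_censoring(death, config$censor_lo, config$censor_hi)
  dplyr::bind_cols(dplyr::select(covs, -"mgmt_true"), outcome)
}

#' Summarise a cohort in the layout of a demographics table
#'
#' Medians and IQRs for age and the three size variables, counts and
#' percentages for the categorical variables, the event count, the
#' Kaplan-Meier median overall survival with 95% CI and the reverse
#' Kaplan-Meier median follow-up.
#'
#' @param table A cohort table (from [generate_cohort()] or
#'   [read_cohort()]).
#' @return An object of class `cohort_summary`: a list with elements `n`,
#'   `n_events`, `km_median_os` (with `ci_lo`/`ci_hi`), `followup_median`,
#'   `max_followup`, `continuous` (tibble of median/q1/q3/mean) and
#'   `categorical` (tibble of level counts and percentages).
#' @export
summarize_cohort <- function(table) {
  assert_cohort(table)
  sf <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                          data = table)
  km <- summary(sf)$table
  rev_sf <- survival::survfit(
    survival::Surv(time_months, 1 - event) ~ 1, data = table
  )
  cont <- purrr::map_dfr(
    c(age = "age", diameter_cm = "diameter_cm",
      cv_cm3 = "cv_cm3", wv_cm3 = "wv_cm3"),
    function(col) {
      tibble(
        median = median(table[[col]]),
        q1 = unname(quantile(table[[col]], 0.25)),
        q3 = unname(quantile(table[[col]], 0.75)),
        mean = mean(table[[col]])
      )
    },
    .id = "variable"
  )
  cat_tbl <- purrr::map_dfr(
    c("sex", "surgery", "oncology", "mgmt"),
    function(col) {
      counts <- base::table(factor(table[[col]]))
      tibble(
        variable = col, level = names(counts),
        n = as.integer(counts),
        pct = 100 * as.integer(counts) / nrow(table)
      )
    }
  )
  structure(
    list(
      n = nrow(table),
      n_events = sum(table$event),
      km_median_os = unname(km["median"]),
      km_median_ci_lo = unname(km["0.95LCL"]),
      km_median_ci_hi = unname(km["0.95UCL"]),
      followup_median = unname(summary(rev_sf)$table["median"]),
      max_followup = max(table$time_months),
      continuous = cont,
      categorical = cat_tbl
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients, %d deaths\n", x$n, x$n_events))
  cat(sprintf("  KM median OS %.1f months (95%% CI %.1f-%.1f); median follow-up %.1f (max %.1f)\n",
              x$km_median_os, x$km_median_ci_lo, x$km_median_ci_hi,
              x$followup_median, x$max_followup))
  print(x$continuous)
  print(x$categorical, n = Inf)
  invisible(x)
}

#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) {
  dplyr::bind_rows(
    tidyr::pivot_longer(x$continuous, -"variable", names_to = "statistic",
                        values_to = "value"),
    dplyr::transmute(
      x$categorical,
      variable = paste(.data$variable, .data$level, sep = "_"),
      statistic = "pct", value = .data$pct
    ),
    tibble(variable = c("os", "followup", "events"),
           statistic = c("km_median", "rev_km_median", "count"),
           value = c(x$km_median_os, x$followup_median, x$n_events))
  )
}

#' Write or read a cohort table as CSV
#'
#' One header row with columns
#' `age,sex,surgery,oncology,mgmt,diameter_cm,cv_cm3,wv_cm3,time_months,event`;
#' `mgmt` uses the literal `unknown` for a missing result. Reading restores
#' the factor levels used throughout the package and validates every
#' column, naming offending rows.
#'
#' @param table A cohort table.
#' @param path CSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a cohort tibble.
#' @export
write_cohort <- function(table, path) {
  assert_cohort(table)
  readr::write_csv(
    table[, c("age", "sex", "surgery", "oncology", "mgmt",
              "diameter_cm", "cv_cm3", "wv_cm3", "time_months", "event")],
    path
  )
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_bad_input("cohort file not found: %s", path)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      age = "d", sex = "c", surgery = "c", oncology = "c", mgmt = "c",
      diameter_cm = "d", cv_cm3 = "d", wv_cm3 = "d",
      time_months = "d", event = "d"
    )
  )
  assert_cohort(raw)
  check_levels <- function(col, levels) {
    bad <- which(!raw[[col]] %in% levels)
    if (length(bad) > 0) {
      stop_bad_input("column `%s` has invalid value '%s' at row %d",
                     col, raw[[col]][bad[1]], bad[1])
    }
    factor(raw[[col]], levels = levels)
  }
  raw$sex <- check_levels("sex", SEX_LEVELS)
  raw$surgery <- check_levels("surgery", SURGERY_LEVELS)
  raw$oncology <- check_levels("oncology", ONCOLOGY_LEVELS)
  raw$mgmt <- check_levels("mgmt", MGMT_LEVELS)
  bad_event <- which(!raw$event %in% c(0, 1))
  if (length(bad_event) > 0) {
    stop_bad_input("column `event` must be 0 or 1 (row %d)", bad_event[1])
  }
  raw$event <- as.integer(raw$event)
  bad_time <- which(!is.finite(raw$time_months) | raw$time_months <= 0)
  if (length(bad_time) > 0) {
    stop_bad_input("column `time_months` must be positive (row %d)",
                   bad_time[1])
  }
  raw
}
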