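# Cox proportional-hazards fitting: univariable and multivariable models
# of tumour size, Wald tests, concordance, and the full model suite.

#' Fit a Cox proportional-hazards model for a tumour size variable
#'
#' Maximises the Cox partial likelihood (Efron tie handling) for the model
#' described by `spec`. Categorical covariates are dummy-coded against the
#' fixed reference levels male / biopsy / no Stupp / unmethylated; when
#' `"mgmt"` is adjusted for, patients with an unknown result are excluded
#' first. Covariate columns that are constant in the (filtered) data are
#' dropped and reported in `dropped_terms`; a constant size variable makes
#' the model unanswerable and is refused. A fit that hits the iteration cap
#' is returned with `converged = FALSE`, never silently.
#'
#' @param table A cohort table.
#' @param spec A [model_spec()].
#' @return An object of class `gbm_cox_fit` with broom-style [tidy()] and
#'   [glance()] methods. Key fields: `terms` (per-term tibble with
#'   coefficient, SE, HR, 95% CI, Wald p), `concordance`,
#'   `overall_wald_p`, `n_used`, `n_events`, `converged`, `dropped_terms`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 120, seed = 3))
#' fit <- fit_cox(cohort, model_spec("wv", "log"))
#' tidy(fit)
#' glance(fit)
#' @export
fit_cox <- function(table, spec) {
  if (!inherits(spec, "model_spec")) stop_bad_input("`spec` must be a model_spec")
  design <- build_design(table, spec)
  if (design$n_events < 2L) {
    stop_bad_input("need at least 2 events to fit a Cox model (got %d)",
                   design$n_events)
  }
  constant <- apply(design$x, 2, function(col) diff(range(col)) == 0)
  if (constant[[design$size_term]]) {
    stop_bad_input("size variable `%s` is constant; no prognostic information",
                   design$size_term)
  }
  dropped <- colnames(design$x)[constant]
  x <- design$x[, !constant, drop = FALSE]
  if (ncol(x) == 0L) stop_bad_input("all model terms are constant")

  df <- as.data.frame(x)
  df$.time <- design$time
  df$.event <- design$event
  fml <- stats::as.formula(
    paste("survival::Surv(.time, .event) ~",
          paste(colnames(x), collapse = " + "))
  )
  warnings_seen <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)
  vcv <- stats::vcov(fit)
  se <- sqrt(diag(vcv))
  converged <- all(is.finite(beta)) && all(is.finite(se)) &&
    !any(grepl("converge|infinite|out of iterations", warnings_seen,
               ignore.case = TRUE))
  terms <- tibble(
    term = names(beta),
    estimate = unname(beta),
    std_error = unname(se),
    hr = exp(unname(beta)),
    conf_low = exp(unname(beta) - 1.96 * unname(se)),
    conf_high = exp(unname(beta) + 1.96 * unname(se)),
    p_value = wald_p(unname(beta), unname(se))
  )
  overall <- tryCatch({
    stat <- drop(t(beta) %*% solve(vcv, beta))
    pchisq(stat, df = length(beta), lower.tail = FALSE)
  }, error = function(e) NA_real_)
  structure(
    list(
      spec = spec, fit = fit, terms = terms,
      size_term = design$size_term,
      concordance = unname(fit$concordance["concordance"]),
      concordance_se = unname(fit$concordance["std"]),
      overall_wald_p = overall,
      n_used = design$n_used, n_events = design$n_events,
      converged = converged, dropped_terms = dropped,
      warnings = warnings_seen
    ),
    class = "gbm_cox_fit"
  )
}

#' @export
print.gbm_cox_fit <- function(x, ...) {
  cat(sprintf("<gbm_cox_fit: %s; n = %d, events = %d, C = %.3f%s>\n",
              spec_label(x$spec), x$n_used, x$n_events, x$concordance,
              if (x$converged) "" else "; DID NOT CONVERGE"))
  print(x$terms)
  invisible(x)
}

#' @method tidy gbm_cox_fit
#' @export
tidy.gbm_cox_fit <- function(x, ...) x$terms

#' @method glance gbm_cox_fit
#' @export
glance.gbm_cox_fit <- function(x, ...) {
  size_row <- x$terms[x$terms$term == x$size_term, ]
  tibble(
    size_variable = x$spec$size_variable,
    transform = x$spec$transform,
    adjustment = spec_adjustment_label(x$spec),
    hr = size_row$hr, conf_low = size_row$conf_low,
    conf_high = size_row$conf_high, p_value = size_row$p_value,
    concordance = x$concordance,
    overall_wald_p = x$overall_wald_p,
    n_used = x$n_used, n_events = x$n_events,
    converged = x$converged,
    n_dropped_terms = length(x$dropped_terms)
  )
}

spec_adjustment_label <- function(spec) {
  if (length(spec$adjustment) == 0) return("none")
  if (setequal(spec$adjustment, ADJUSTMENT_VARIABLES)) return("all")
  paste(spec$adjustment, collapse = "+")
}

#' Two-sided Wald p-value for a coefficient
#'
#' `p = 2 * (1 - Phi(|beta| / se))`; symmetric in the sign of `beta`.
#' Vectorised over both arguments.
#'
#' @param coefficient Estimated coefficient(s).
#' @param se Standard error(s), strictly positive.
#' @return p-value(s) in `[0, 1]`.
#' @export
wald_p <- function(coefficient, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop_bad_input("`se` must be strictly positive")
  }
  2 * pnorm(-abs(coefficient) / se)
}

#' Harrell's concordance index for censored survival data
#'
#' Probability, over usable (comparable under censoring) patient pairs,
#' that the patient with the higher risk score dies earlier; ties in the
#' risk score count 1/2. `C = 0.5` means no discrimination.
#'
#' @param table A cohort table providing `time_months` and `event`.
#' @param risk_scores Numeric vector, higher = predicted shorter survival.
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(table, risk_scores) {
  assert_cohort(table)
  if (length(risk_scores) != nrow(table) || any(!is.finite(risk_scores))) {
    stop_bad_input("`risk_scores` must be finite, one per patient")
  }
  d <- data.frame(time = table$time_months, event = table$event,
                  risk = risk_scores)
  cfit <- survival::concordance(
    survival::Surv(time, event) ~ risk, data = d, reverse = TRUE
  )
  counts <- cfit$count
  comparable <- sum(counts[c("concordant", "discordant", "tied.x")])
  if (!is.finite(comparable) || comparable < 1) {
    stop_bad_input("no comparable pairs under censoring")
  }
  unname(cfit$concordance)
}

#' Fit the full univariable and multivariable model suite
#'
#' Fits, for each of the three size variables on both the identity and log
#' scale: the univariable model, the five single-adjustment models (age,
#' sex, surgery, oncology, MGMT in turn) and the all-adjusted model -
#' 6 + 36 = 42 fits. MGMT-containing fits use only patients with a known
#' MGMT result.
#'
#' @param table A cohort table.
#' @return A `model_suite` tibble with one row per fit: the glance columns
#'   of each fit plus a `fit` list-column holding the `gbm_cox_fit`.
#' @export
build_model_suite <- function(table) {
  assert_cohort(table)
  adjustments <- c(
    list(character()),
    as.list(ADJUSTMENT_VARIABLES),
    list(ADJUSTMENT_VARIABLES)
  )
  grid <- tidyr::expand_grid(
    size_variable = names(SIZE_VARIABLES),
    transform = c("identity", "log"),
    adjustment = adjustments
  )
  fits <- purrr::pmap(grid, function(size_variable, transform, adjustment) {
    fit_cox(table, model_spec(size_variable, transform, adjustment))
  })
  out <- dplyr::bind_cols(
    purrr::map_dfr(fits, glance),
    tibble(fit = fits)
  )
  class(out) <- c("model_suite", class(out))
  out
}

#' Export a model suite in the layout of published summary tables
#'
#' `suite_univariable_table()` mirrors the univariable summary (one column
#' per size/transform: concordance with CI, HR with CI, p);
#' `suite_multivariable_table()` mirrors the multivariable summary (one row
#' per adjustment, HR/CI/p of the size term per size/transform).
#'
#' @param suite A `model_suite` from [build_model_suite()].
#' @return A tibble.
#' @export
suite_univariable_table <- function(suite) {
  uni <- dplyr::filter(as_tibble(suite), .data$adjustment == "none")
  dplyr::transmute(
    uni,
    model = purrr::map_chr(.data$fit, ~ spec_label(.x$spec)),
    C = round(.data$concordance, 2),
    C_ci = purrr::map_chr(.data$fit, function(f) {
      sprintf("%.2f-%.2f", f$concordance - 1.96 * f$concordance_se,
              f$concordance + 1.96 * f$concordance_se)
    }),
    HR = signif(.data$hr, 3),
    HR_ci = sprintf("%.3g-%.3g", .data$conf_low, .data$conf_high),
    p = signif(.data$p_value, 3)
  )
}

#' @rdname suite_univariable_table
#' @export
suite_multivariable_table <- function(suite) {
  multi <- dplyr::filter(as_tibble(suite), .data$adjustment != "none")
  long <- dplyr::transmute(
    multi,
    adjustment = .data$adjustment,
    model = paste0(
      ifelse(.data$transform == "log", paste0("log_", .data$size_variable),
             .data$size_variable)
    ),
    cell = sprintf("%.3g (%.3g-%.3g) p=%.3g", .data$hr, .data$conf_low,
                   .data$conf_high, .data$p_value)
  )
  tidyr::pivot_wider(long, names_from = "model", values_from = "cell")
}
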