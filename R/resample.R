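# Bootstrap resampling experiment: how sample size and log transformation
# change the probability of detecting a prognostic effect of tumour size.

#' Configuration of the resampling experiment
#'
#' @param sample_sizes Strictly increasing bootstrap sample sizes. The
#'   default grid runs from 50 to the full cohort of 279.
#' @param repetitions Bootstrap repetitions per (sample size, model) cell.
#'   The published experiment used 1e6; the default 1e4 is a desk scale
#'   whose Monte-Carlo error on a percentage is under half a point.
#' @param thresholds Significance thresholds at which percentages of
#'   significant models are reported (strict `p < alpha`).
#' @param model_specs List of [model_spec()] objects; defaults to the six
#'   univariable models (3 sizes x identity/log).
#' @param master_seed Seed from which every per-repetition substream is
#'   derived (keyed by sample size, model and repetition index, so results
#'   do not depend on execution order).
#' @param store_pvalues Keep the full p-value collections (needed for
#'   [compare_extremes()] and p-value boxplots), not just exceedance
#'   counts.
#' @return An object of class `resampling_config`.
#' @export
resampling_config <- function(sample_sizes = c(50, 100, 150, 200, 250, 258, 279),
                              repetitions = 10000,
                              thresholds = c(0.05, 0.01, 0.001),
                              model_specs = NULL,
                              master_seed = 1L,
                              store_pvalues = TRUE) {
  if (length(sample_sizes) < 1 || any(sample_sizes < 1) ||
      any(diff(sample_sizes) <= 0)) {
    stop_bad_input("`sample_sizes` must be strictly increasing positive integers")
  }
  if (repetitions < 1) stop_bad_input("`repetitions` must be >= 1")
  if (any(thresholds <= 0) || any(thresholds >= 1)) {
    stop_bad_input("`thresholds` must lie strictly between 0 and 1")
  }
  if (is.null(model_specs)) {
    grid <- tidyr::expand_grid(size = names(SIZE_VARIABLES),
                               tr = c("identity", "log"))
    model_specs <- purrr::map2(grid$size, grid$tr, model_spec)
  }
  if (inherits(model_specs, "model_spec")) model_specs <- list(model_specs)
  ok <- vapply(model_specs, inherits, logical(1), "model_spec")
  if (!all(ok)) stop_bad_input("`model_specs` must be a list of model_spec objects")
  structure(
    list(
      sample_sizes = as.integer(sample_sizes),
      repetitions = as.integer(repetitions),
      thresholds = sort(thresholds, decreasing = TRUE),
      model_specs = model_specs,
      master_seed = as.integer(master_seed),
      store_pvalues = isTRUE(store_pvalues)
    ),
    class = "resampling_config"
  )
}

#' Draw a bootstrap resample of a cohort
#'
#' `m` rows drawn i.i.d. uniformly with replacement from `table` (row
#' identity preserved); `m` may exceed the source size. Uses the current
#' RNG state, so wrap in `set.seed()` for reproducibility.
#'
#' @param table A non-empty cohort table.
#' @param m Resample size.
#' @return A cohort tibble with `m` rows.
#' @export
bootstrap_sample <- function(table, m) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop_bad_input("`table` must be a non-empty data frame")
  }
  if (m < 1) stop_bad_input("`m` must be a positive integer")
  table[sample.int(nrow(table), m, replace = TRUE), , drop = FALSE]
}

# One fast Cox fit on a pre-built design matrix. Returns the two-sided
# Wald p-value for the size coefficient (always column 1) or NA on any
# failure (too few events, constant size, non-convergence, singularity).
cox_fit_fast <- function(x, y, control) {
  warned <- FALSE
  fit <- withCallingHandlers(
    tryCatch(
      survival::coxph.fit(x, y, strata = NULL, offset = NULL, init = NULL,
                          control = control, weights = NULL,
                          method = "efron", rownames = NULL),
      error = function(e) NULL
    ),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (is.null(fit)) return(NA_real_)
  beta <- fit$coefficients[1]
  se <- sqrt(fit$var[1, 1])
  if (warned || !is.finite(beta) || !is.finite(se) || se <= 0) {
    return(NA_real_)
  }
  2 * pnorm(-abs(beta) / se)
}

#' Run the bootstrap resampling experiment
#'
#' For every model in the configuration and every sample size, draws
#' `repetitions` bootstrap resamples of the cohort, fits the Cox model and
#' records the two-sided Wald p-value of the tumour-size coefficient (for
#' a univariable model this equals the overall model Wald p). For models
#' adjusted for MGMT, patients with an unknown result are excluded from
#' the source first and sample sizes above the number of known results are
#' capped at that count. Resamples in which an adjustment dummy is
#' constant are fitted without it; failed or non-converged fits are
#' counted in `n_failed` and excluded from percentage denominators, never
#' aborting the run.
#'
#' @param table The source cohort.
#' @param config A [resampling_config()].
#' @return An object of class `resampling_result` with a `cells` tibble
#'   (one row per sample size x model: counts, per-threshold percentages
#'   and, if requested, the p-value collection) plus the configuration.
#'   Use [tidy()], [percent_significant()], [compare_extremes()] and
#'   [autoplot()] on it.
#' @export
run_resampling <- function(table, config) {
  if (!inherits(config, "resampling_config")) {
    stop_bad_input("`config` must be a resampling_config")
  }
  assert_cohort(table)
  control <- survival::coxph.control()
  cells <- list()
  for (spec in config$model_specs) {
    label <- spec_label(spec)
    design <- build_design(table, spec)
    n_source <- design$n_used
    x_all <- design$x
    y_all <- survival::Surv(design$time, design$event)
    sizes <- unique(pmin(config$sample_sizes, n_source))
    for (n in sizes) {
      cell_seed <- derive_seed(config$master_seed, label, n)
      pvals <- rep(NA_real_, config$repetitions)
      for (rep_i in seq_len(config$repetitions)) {
        set.seed(shift_seed(cell_seed, rep_i))
        idx <- sample.int(n_source, n, replace = TRUE)
        xs <- x_all[idx, , drop = FALSE]
        keep_col <- colSums(xs != rep(xs[1, ], each = n)) > 0
        if (!keep_col[1]) next # constant size variable: failed fit
        pvals[rep_i] <- cox_fit_fast(xs[, keep_col, drop = FALSE],
                                     y_all[idx, ], control)
      }
      counted <- sum(!is.na(pvals))
      pct <- vapply(config$thresholds, function(a) {
        if (counted == 0) NA_real_ else 100 * sum(pvals < a, na.rm = TRUE) / counted
      }, numeric(1))
      names(pct) <- vapply(config$thresholds, function(a) {
        paste0("pct_", sub("^0\\.", "", format(a)))
      }, character(1))
      cells[[length(cells) + 1L]] <- dplyr::bind_cols(
        tibble(
          spec_id = label,
          size_variable = spec$size_variable,
          transform = spec$transform,
          adjustment = spec_adjustment_label(spec),
          n = n,
          effective_max_n = n_source,
          n_counted = counted,
          n_failed = config$repetitions - counted
        ),
        as_tibble(as.list(pct)),
        tibble(pvalues = if (config$store_pvalues) list(pvals[!is.na(pvals)]) else list(NULL))
      )
    }
  }
  structure(
    list(cells = dplyr::bind_rows(cells), config = config),
    class = "resampling_result"
  )
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("<resampling_result: %d models x sample sizes, R = %d>\n",
              length(x$config$model_specs), x$config$repetitions))
  print(dplyr::select(x$cells, -"pvalues"), n = Inf)
  invisible(x)
}

#' Percentage of significant results at a threshold
#'
#' `100 * #\{p < alpha\} / n_counted` with a strict inequality, the
#' convention of the resampling experiment. The method for a
#' `resampling_result` evaluates every cell.
#'
#' @param x A numeric vector of p-values, or a `resampling_result`.
#' @param alpha Significance threshold in (0, 1).
#' @param ... Unused.
#' @return A percentage (numeric method), or a tibble with one row per
#'   cell (result method).
#' @examples
#' percent_significant(c(0.01, 0.04, 0.2), 0.05)
#' @export
percent_significant <- function(x, alpha = 0.05, ...) {
  UseMethod("percent_significant")
}

#' @export
percent_significant.numeric <- function(x, alpha = 0.05, ...) {
  assert_number(alpha, "alpha", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  x <- x[!is.na(x)]
  if (length(x) == 0) stop_bad_input("no counted repetitions")
  100 * sum(x < alpha) / length(x)
}

#' @export
percent_significant.resampling_result <- function(x, alpha = 0.05, ...) {
  assert_number(alpha, "alpha", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  if (!x$config$store_pvalues) {
    stop_bad_input("p-values were not stored; rerun with `store_pvalues = TRUE` or use the pct_ columns")
  }
  dplyr::mutate(
    dplyr::select(x$cells, "spec_id", "size_variable", "transform",
                  "adjustment", "n", "n_counted", "n_failed", "pvalues"),
    pct_significant = purrr::map_dbl(.data$pvalues, percent_significant,
                                     alpha = alpha),
    alpha = alpha,
    pvalues = NULL
  )
}

#' @method tidy resampling_result
#' @export
tidy.resampling_result <- function(x, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(x$cells, -"pvalues"),
    dplyr::starts_with("pct_"),
    names_to = "threshold", values_to = "pct_significant"
  )
  long$threshold <- as.numeric(paste0("0.", sub("^pct_", "", long$threshold)))
  long
}

#' @method glance resampling_result
#' @export
glance.resampling_result <- function(x, ...) {
  tibble(
    n_models = length(x$config$model_specs),
    n_cells = nrow(x$cells),
    repetitions = x$config$repetitions,
    total_failed = sum(x$cells$n_failed),
    master_seed = x$config$master_seed
  )
}

#' Two-sided Kolmogorov-Smirnov comparison of two p-value collections
#'
#' `D` is the supremum absolute difference of the two empirical CDFs; the
#' p-value is the asymptotic two-sided one.
#'
#' @param pvals_a,pvals_b Non-empty numeric vectors.
#' @return An object of class `ks_result` with fields `d`, `p_value`,
#'   `n1`, `n2`.
#' @examples
#' ks_compare(c(0.1, 0.5, 0.9), c(0.2, 0.6))
#' @export
ks_compare <- function(pvals_a, pvals_b) {
  pvals_a <- pvals_a[!is.na(pvals_a)]
  pvals_b <- pvals_b[!is.na(pvals_b)]
  if (length(pvals_a) == 0 || length(pvals_b) == 0) {
    stop_bad_input("both p-value collections must be non-empty")
  }
  kt <- suppressWarnings(ks.test(pvals_a, pvals_b, exact = FALSE))
  structure(
    list(d = unname(kt$statistic), p_value = unname(kt$p.value),
         n1 = length(pvals_a), n2 = length(pvals_b)),
    class = "ks_result"
  )
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result: D = %.4f, p = %.4g (n1 = %d, n2 = %d)>\n",
              x$d, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' @method tidy ks_result
#' @export
tidy.ks_result <- function(x, ...) {
  tibble(d = x$d, p_value = x$p_value, n1 = x$n1, n2 = x$n2)
}

#' Compare the p-value distributions at the extreme sample sizes
#'
#' Runs [ks_compare()] on the p-value collections of the smallest and
#' largest sample-size cells of one model of a [run_resampling()] result -
#' the check used to show that sample size shifts the p-value distribution.
#'
#' @param result A `resampling_result` run with `store_pvalues = TRUE`.
#' @param spec A [model_spec()] (or its [spec_label()] string) identifying
#'   the model; may be omitted when the result holds a single model.
#' @return A `ks_result`.
#' @export
compare_extremes <- function(result, spec = NULL) {
  if (!inherits(result, "resampling_result")) {
    stop_bad_input("`result` must come from run_resampling()")
  }
  if (!result$config$store_pvalues) {
    stop_bad_input(paste(
      "p-values were not stored in this result;",
      "rerun run_resampling() with `store_pvalues = TRUE`"
    ))
  }
  label <- if (is.null(spec)) {
    ids <- unique(result$cells$spec_id)
    if (length(ids) > 1) {
      stop_bad_input("result holds %d models; pass `spec`", length(ids))
    }
    ids
  } else if (inherits(spec, "model_spec")) {
    spec_label(spec)
  } else {
    as.character(spec)
  }
  cells <- result$cells[result$cells$spec_id == label, ]
  if (nrow(cells) < 2) {
    stop_bad_input("model '%s' has fewer than two sample-size cells", label)
  }
  lo <- cells[which.min(cells$n), ]
  hi <- cells[which.max(cells$n), ]
  out <- ks_compare(lo$pvalues[[1]], hi$pvalues[[1]])
  out$n_lo <- lo$n
  out$n_hi <- hi$n
  out
}

#' Wald p-values of the size test under freshly simulated cohorts
#'
#' Draws `repetitions` independent cohorts of `sample_size` patients from
#' `config`, fits the Cox model of `spec` to each, and returns the Wald
#' p-value of the size coefficient. With a null configuration (all betas
#' zero) the returned p-values are uniform and the rejection rate at any
#' `alpha` is the nominal level - the calibration check of the testing
#' machinery. (Bootstrap resamples of one fixed cohort do *not* have this
#' property: they are re-centred on that cohort's empirical coefficient;
#' see the methods vignette.)
#'
#' @param config A [cohort_config()]; its `n_patients` is overridden by
#'   `sample_size`.
#' @param sample_size Patients per simulated cohort.
#' @param repetitions Number of cohorts.
#' @param spec A [model_spec()]; default univariable whole volume.
#' @param seed Master seed for the simulation stream.
#' @return Numeric vector of p-values (NA-free; failed fits are dropped).
#' @export
simulate_wald_pvalues <- function(config, sample_size, repetitions,
                                  spec = model_spec("wv"), seed = 1L) {
  validate_cohort_config(config)
  base_seed <- derive_seed(seed, "fresh-cohorts", spec_label(spec), sample_size)
  control <- survival::coxph.control()
  cfg <- config
  cfg$n_patients <- as.integer(sample_size)
  pvals <- rep(NA_real_, repetitions)
  for (rep_i in seq_len(repetitions)) {
    cfg$seed <- shift_seed(base_seed, rep_i)
    cohort <- generate_cohort(cfg)
    design <- build_design(cohort, spec)
    if (design$n_events < 2L) next
    keep <- apply(design$x, 2, function(col) diff(range(col)) > 0)
    if (!keep[1]) next
    pvals[rep_i] <- cox_fit_fast(
      design$x[, keep, drop = FALSE],
      survival::Surv(design$time, design$event), control
    )
  }
  pvals[!is.na(pvals)]
}

#' Table of percent-significant cells in the published layout
#'
#' Rows are sample sizes, columns the models, cells the percentage of
#' resamples significant at `alpha`.
#'
#' @param result A `resampling_result`.
#' @param alpha Threshold; must be one of the configured thresholds.
#' @return A wide tibble.
#' @export
resampling_table <- function(result, alpha = 0.05) {
  long <- tidy(result)
  long <- long[abs(long$threshold - alpha) < 1e-12, ]
  if (nrow(long) == 0) {
    stop_bad_input("alpha = %g was not among the configured thresholds", alpha)
  }
  tidyr::pivot_wider(
    dplyr::select(long, "n", "spec_id", "pct_significant"),
    names_from = "spec_id", values_from = "pct_significant"
  )
}

#' Long-format p-value export for figure-style boxplots
#'
#' @param result A `resampling_result` with stored p-values.
#' @return Tibble with columns `spec_id`, `size_variable`, `transform`,
#'   `adjustment`, `n`, `repetition`, `p`.
#' @export
pvalues_long <- function(result) {
  if (!inherits(result, "resampling_result") || !result$config$store_pvalues) {
    stop_bad_input("`result` must be a resampling_result with stored p-values")
  }
  tidyr::unnest_longer(
    dplyr::select(result$cells, "spec_id", "size_variable", "transform",
                  "adjustment", "n", "pvalues"),
    "pvalues", values_to = "p", indices_to = "repetition"
  )
}

#' @describeIn run_resampling Plot the experiment: `type = "power"` draws
#'   percent-significant against sample size per model; `type = "pvalues"`
#'   draws the per-cell p-value distributions as boxplots.
#' @param object A `resampling_result`.
#' @param type `"power"` or `"pvalues"`.
#' @param alpha Threshold used for the power curves.
#' @param ... Unused.
#' @method autoplot resampling_result
#' @export
autoplot.resampling_result <- function(object, type = c("power", "pvalues"),
                                       alpha = 0.05, ...) {
  type <- match.arg(type)
  if (type == "power") {
    long <- tidy(object)
    long <- long[abs(long$threshold - alpha) < 1e-12, ]
    ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$pct_significant,
                                       colour = .data$spec_id)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "bootstrap sample size",
                    y = sprintf("%% of resamples with p < %g", alpha),
                    colour = "model") +
      ggplot2::theme_minimal()
  } else {
    long <- pvalues_long(object)
    ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$n), y = .data$p,
                                       fill = .data$transform)) +
      ggplot2::geom_boxplot(outlier.shape = NA) +
      ggplot2::geom_hline(yintercept = 0.05, linetype = "dotted") +
      ggplot2::facet_wrap(~ .data$size_variable) +
      ggplot2::labs(x = "bootstrap sample size", y = "Wald p-value") +
      ggplot2::theme_minimal()
  }
}
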