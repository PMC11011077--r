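# Penalised-spline exploration of the size-vs-log-hazard relationship.

#' Penalised-spline Cox model for one size variable
#'
#' Fits a Cox model with a penalised smooth term in the chosen size
#' variable (the `survival` package's `pspline`, smoothing chosen by its
#' AIC criterion, so no knots or degrees of freedom need pre-specifying)
#' and returns the fitted log relative hazard over a grid, centred so the
#' curve is exactly 0 at the sample median size, with pointwise 95% bounds
#' and the effective degrees of freedom. An approximately straight curve
#' with `edf` near 1 indicates that a plain linear term suffices.
#'
#' @param table A cohort table with at least 20 events.
#' @param size_variable `"diameter"`, `"cv"` or `"wv"`.
#' @param transform `"identity"` or `"log"` scale for the size axis.
#' @param n_grid Number of grid points across the observed size range.
#' @return An object of class `spline_curve`: a list with `curve` (tibble
#'   of `size`, `log_hr`, `ci_lo`, `ci_hi`), `edf`, `reference` (the
#'   centring size) and `size_variable`; plot with [autoplot()].
#' @export
fit_penalized_spline <- function(table,
                                 size_variable = c("diameter", "cv", "wv"),
                                 transform = c("identity", "log"),
                                 n_grid = 100) {
  size_variable <- match.arg(size_variable)
  transform <- match.arg(transform)
  assert_cohort(table)
  if (sum(table$event) < 20L) {
    stop_bad_input("need at least 20 events for a stable penalised spline (got %d)",
                   sum(table$event))
  }
  x <- table[[SIZE_VARIABLES[[size_variable]]]]
  if (transform == "log") x <- log(x)
  df <- data.frame(x = x, time = table$time_months, event = table$event)
  fit <- survival::coxph(
    survival::Surv(time, event) ~ survival::pspline(x, df = 0), data = df
  )
  reference <- median(x)
  grid <- sort(unique(c(seq(min(x), max(x), length.out = n_grid), reference)))
  pred <- stats::predict(fit, newdata = data.frame(x = grid),
                         type = "terms", se.fit = TRUE)
  term <- unname(drop(as.matrix(pred$fit)))
  se <- unname(drop(as.matrix(pred$se.fit)))
  at_ref <- term[which.min(abs(grid - reference))]
  structure(
    list(
      curve = tibble(
        size = grid,
        log_hr = term - at_ref,
        ci_lo = term - 1.96 * se - at_ref,
        ci_hi = term + 1.96 * se - at_ref
      ),
      edf = sum(fit$df),
      reference = reference,
      size_variable = size_variable,
      transform = transform,
      n_events = sum(table$event)
    ),
    class = "spline_curve"
  )
}

#' @export
print.spline_curve <- function(x, ...) {
  cat(sprintf("<spline_curve: %s%s, edf = %.2f, reference size = %.3g>\n",
              x$size_variable,
              if (x$transform == "log") " (log scale)" else "",
              x$edf, x$reference))
  invisible(x)
}

#' @method tidy spline_curve
#' @export
tidy.spline_curve <- function(x, ...) x$curve

#' @describeIn fit_penalized_spline Plot the centred log-hazard curve with
#'   its pointwise 95% band and the zero reference line.
#' @param object A `spline_curve`.
#' @param ... Unused.
#' @method autoplot spline_curve
#' @export
autoplot.spline_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$size, y = .data$log_hr)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("%s%s", object$size_variable,
                  if (object$transform == "log") " (log scale)" else ""),
      y = "log hazard ratio (vs median size)",
      subtitle = sprintf("penalised spline, edf = %.2f", object$edf)
    ) +
    ggplot2::theme_minimal()
}
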