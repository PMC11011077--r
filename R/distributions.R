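# Quartile-matched marginal distributions for tumour size and age.
#
# Published cohort summaries report median (IQR) only, so each continuous
# marginal is pinned down by two parameters: a lognormal for the positively
# skewed volumes and a truncated normal for diameter and age.

Z75 <- qnorm(0.75) # standard-normal upper quartile, ~0.67449

new_size_distribution <- function(family, mu, sigma, lower = -Inf,
                                  upper = Inf, degenerate = FALSE) {
  structure(
    list(family = family, mu = mu, sigma = sigma,
         lower = lower, upper = upper, degenerate = degenerate),
    class = "size_distribution"
  )
}

#' Lognormal distribution matched to a printed median and IQR
#'
#' Solves for the lognormal whose theoretical median and quartiles equal the
#' published summary, so synthetic cohorts reproduce `median (q1-q3)` lines
#' exactly in expectation: `mu = log(median)` and
#' `sigma = (log(q3) - log(q1)) / (2 * qnorm(0.75))`.
#'
#' @param median,q1,q3 Positive reals with `q1 < median < q3` (a fully
#'   degenerate `q1 == median == q3` is accepted and flagged as a point mass).
#' @return A `size_distribution` object with fields `family`, `mu`, `sigma`
#'   and a `degenerate` flag.
#' @examples
#' lognormal_from_quartiles(28.1, 12.6, 50.3)
#' @export
lognormal_from_quartiles <- function(median, q1, q3) {
  assert_number(median, "median", lower = 0, strict_lower = TRUE)
  assert_number(q1, "q1", lower = 0, strict_lower = TRUE)
  assert_number(q3, "q3", lower = 0, strict_lower = TRUE)
  if (q1 == median && q3 == median) {
    return(new_size_distribution("lognormal", log(median), 0, degenerate = TRUE))
  }
  if (!(q1 < median && median < q3)) {
    stop_bad_input("quartiles must satisfy q1 < median < q3 (got %g, %g, %g)",
                   q1, median, q3)
  }
  new_size_distribution("lognormal", log(median), (log(q3) - log(q1)) / (2 * Z75))
}

#' Truncated normal matched to a median, IQR and support
#'
#' Numerically solves for the location and scale of a normal distribution
#' truncated to `(lower, upper)` whose quartiles equal the published
#' `median (q1-q3)` summary. Used for age (truncated to the observed range)
#' and for tumour diameter (truncated away from zero).
#'
#' @param median,q1,q3 Target quartiles, `q1 < median < q3`.
#' @param lower,upper Truncation bounds (may be infinite).
#' @return A `size_distribution` object with `family = "truncated-normal"`.
#' @export
truncnorm_from_quantiles <- function(median, q1, q3, lower = -Inf, upper = Inf) {
  assert_number(median, "median")
  assert_number(q1, "q1")
  assert_number(q3, "q3")
  if (!(q1 < median && median < q3)) {
    stop_bad_input("quantiles must satisfy q1 < median < q3")
  }
  if (!(lower < q1 && q3 < upper)) {
    stop_bad_input("truncation bounds must bracket the quartiles")
  }
  # Two parameters cannot pin down three asymmetric quantiles, so solve
  # exactly for the median and the IQR width (nested root finding; the
  # truncated median is increasing in mu, the width in sigma).
  sigma0 <- (q3 - q1) / (2 * Z75)
  mu_for <- function(sigma) {
    # +-8 sigma brackets the target median and keeps pnorm() away from
    # its numerically flat tails
    uniroot(function(mu) {
      qtrunc_normal(0.5, mu, sigma, lower, upper) - median
    }, interval = median + c(-8, 8) * sigma, tol = 1e-12)$root
  }
  fit <- tryCatch(
    uniroot(function(sigma) {
      mu <- mu_for(sigma)
      diff(qtrunc_normal(c(0.25, 0.75), mu, sigma, lower, upper)) - (q3 - q1)
    }, interval = sigma0 * c(0.4, 8), tol = 1e-12),
    error = function(e) {
      stop_bad_input("cannot match the requested quantiles within (%g, %g)",
                     lower, upper)
    }
  )
  new_size_distribution("truncated-normal", mu_for(fit$root), fit$root,
                        lower = lower, upper = upper)
}

qtrunc_normal <- function(p, mu, sigma, lower, upper) {
  plo <- pnorm(lower, mu, sigma)
  phi <- pnorm(upper, mu, sigma)
  qnorm(plo + p * (phi - plo), mu, sigma)
}

# Quantile function of a fitted marginal; maps copula uniforms to sizes.
qdist <- function(dist, p) {
  switch(dist$family,
    "lognormal" = exp(dist$mu + dist$sigma * qnorm(p)),
    "truncated-normal" = qtrunc_normal(p, dist$mu, dist$sigma,
                                       dist$lower, dist$upper),
    stop_bad_input("unknown distribution family '%s'", dist$family)
  )
}

# Theoretical mean (used to centre linear-predictor contributions).
dist_mean <- function(dist) {
  switch(dist$family,
    "lognormal" = exp(dist$mu + dist$sigma^2 / 2),
    "truncated-normal" = {
      a <- (dist$lower - dist$mu) / dist$sigma
      b <- (dist$upper - dist$mu) / dist$sigma
      dist$mu + dist$sigma * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
    }
  )
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution: %s, mu = %.4f, sigma = %.4f%s>\n",
              x$family, x$mu, x$sigma,
              if (x$degenerate) ", degenerate point mass" else ""))
  invisible(x)
}
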