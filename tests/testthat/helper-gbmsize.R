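# Shared fixtures: all cohorts are built in code, nothing is stored.

# Hand-built deterministic cohort (no randomness, no ties).
tiny_cohort <- function() {
  tibble::tibble(
    age = c(55, 62, 70, 48, 66, 59),
    sex = factor(c("male", "female", "male", "female", "male", "female"),
                 levels = c("male", "female")),
    surgery = factor(
      c("biopsy", "resection_100", "resection_90", "resection_lt90",
        "biopsy", "resection_90"),
      levels = c("biopsy", "resection_100", "resection_90", "resection_lt90")
    ),
    oncology = factor(
      c("no_stupp", "full_stupp", "partial_stupp", "no_stupp",
        "full_stupp", "no_stupp"),
      levels = c("no_stupp", "full_stupp", "partial_stupp")
    ),
    mgmt = factor(
      c("methylated", "unmethylated", "unknown", "methylated",
        "unmethylated", "unmethylated"),
      levels = c("unmethylated", "methylated", "unknown")
    ),
    diameter_cm = c(3.2, 4.4, 5.1, 2.8, 6.0, 4.0),
    cv_cm3 = c(12, 28, 55, 9, 80, 30),
    wv_cm3 = c(40, 100, 170, 35, 220, 110),
    time_months = c(5, 9, 14, 22, 31, 47),
    event = c(1L, 1L, 1L, 1L, 1L, 0L)
  )
}

# Random all-events dataset for partial-likelihood oracle checks.
random_small_cohort <- function(n, seed) {
  set.seed(seed)
  co <- tiny_cohort()[rep_len(1:6, n), ]
  co$wv_cm3 <- exp(rnorm(n, log(100), 0.8))
  co$cv_cm3 <- co$wv_cm3 * runif(n, 0.2, 0.5)
  co$diameter_cm <- runif(n, 2, 7)
  co$time_months <- sort(sample(seq(1, 60, by = 1), n)) + runif(n, 0, 0.5)
  co$event <- 1L
  co
}

# Grid-search maximiser of the hand-written Efron partial likelihood: the
# independent oracle for fit_cox on one-coefficient models.
grid_maximise_pll <- function(table, spec) {
  best <- 0
  for (setup in list(c(-10, 10, 0.05), c(NA, NA, 0.002), c(NA, NA, 1e-4))) {
    lo <- if (is.na(setup[1])) best - 25 * setup[3] else setup[1]
    hi <- if (is.na(setup[2])) best + 25 * setup[3] else setup[2]
    grid <- seq(lo, hi, by = setup[3])
    vals <- vapply(grid, function(b) {
      partial_log_likelihood(b, table, spec, ties = "efron")
    }, numeric(1))
    best <- grid[which.max(vals)]
  }
  best
}
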