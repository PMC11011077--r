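test_that("bootstrap_sample draws i.i.d. rows with replacement", {
  one <- tiny_cohort()[2, ]
  expect_identical(bootstrap_sample(one, 1), one)
  co <- generate_cohort(cohort_config(n_patients = 279, seed = 51))
  # expected fraction of distinct source rows: 1 - (1 - 1/n)^n ~ 0.632
  set.seed(52)
  frac <- mean(vapply(1:200, function(i) {
    idx <- bootstrap_sample(dplyr::mutate(co, .row = dplyr::row_number()),
                            279)$.row
    length(unique(idx)) / 279
  }, numeric(1)))
  expect_equal(frac, 1 - (1 - 1 / 279)^279, tolerance = 0.01)
  # resample size may exceed the source size
  expect_equal(nrow(bootstrap_sample(co, 400)), 400L)
  set.seed(7); a <- bootstrap_sample(co, 50)
  set.seed(7); b <- bootstrap_sample(co, 50)
  expect_identical(a, b)
  expect_error(bootstrap_sample(co[0, ], 5), "non-empty")
})

test_that("percent_significant uses a strict threshold and is monotone", {
  expect_equal(percent_significant(c(0.01, 0.04, 0.2), 0.05), 200 / 3)
  expect_equal(percent_significant(rep(0.05, 10), 0.05), 0) # strict <
  expect_error(percent_significant(numeric(0), 0.05), "no counted")
  expect_error(percent_significant(c(0.1, 0.2), 1.5), "allowed range")
  set.seed(53)
  p <- runif(500)^2
  pcts <- vapply(c(0.001, 0.01, 0.05), percent_significant, numeric(1), x = p)
  expect_true(all(diff(pcts) >= 0))
})

test_that("ks_compare matches hand-computed ECDF sup-differences", {
  same <- ks_compare(c(0.1, 0.4, 0.8), c(0.1, 0.4, 0.8))
  expect_equal(same$d, 0)
  expect_equal(same$p_value, 1)
  disjoint <- ks_compare(c(0.1, 0.2), c(0.7, 0.8))
  expect_equal(disjoint$d, 1)
  hand <- ks_compare(c(0.1, 0.5, 0.9), c(0.2, 0.6))
  expect_equal(hand$d, 1 / 3, tolerance = 1e-12)
  expect_equal(tidy(hand)$n1, 3L)
  expect_error(ks_compare(numeric(0), c(0.5)), "non-empty")
})

test_that("a single-repetition run yields exactly one p-value or failure", {
  co <- generate_cohort(cohort_config(n_patients = 60, seed = 54))
  cfg <- resampling_config(sample_sizes = 30, repetitions = 1,
                           model_specs = model_spec("wv"), master_seed = 1)
  res <- run_resampling(co, cfg)
  expect_equal(nrow(res$cells), 1L)
  expect_equal(res$cells$n_counted + res$cells$n_failed, 1L)
  expect_lte(length(res$cells$pvalues[[1]]), 1L)
})

test_that("resampling results are reproducible and order-independent", {
  co <- generate_cohort(cohort_config(n_patients = 80, seed = 55))
  spec <- model_spec("cv", "log")
  cfg <- resampling_config(sample_sizes = c(30, 60), repetitions = 40,
                           model_specs = spec, master_seed = 99)
  r1 <- run_resampling(co, cfg)
  r2 <- run_resampling(co, cfg)
  expect_identical(r1$cells, r2$cells)
  # per-repetition substreams are keyed by (model, n, repetition):
  # running one sample size alone reproduces the same cell
  solo <- run_resampling(co, resampling_config(
    sample_sizes = 60, repetitions = 40, model_specs = spec, master_seed = 99
  ))
  expect_equal(solo$cells$pvalues[[1]],
               r1$cells$pvalues[[which(r1$cells$n == 60)]])
})

test_that("repetition accounting always balances", {
  co <- generate_cohort(cohort_config(n_patients = 40, seed = 56))
  cfg <- resampling_config(sample_sizes = c(5, 10, 40), repetitions = 60,
                           model_specs = list(model_spec("diameter"),
                                              model_spec("wv", "log",
                                                         "surgery")),
                           master_seed = 2)
  res <- run_resampling(co, cfg)
  expect_true(all(res$cells$n_counted + res$cells$n_failed == 60L))
  # tiny resamples of a multivariable model do fail occasionally and are
  # reported rather than dropped
  expect_true(all(res$cells$n_failed >= 0L))
  td <- tidy(res)
  expect_true(all(sort(unique(td$threshold)) == c(0.001, 0.01, 0.05)))
})

test_that("MGMT-adjusted models cap sample sizes at the known-result count", {
  co <- generate_cohort(cohort_config(n_patients = 279, seed = 57))
  n_known <- sum(co$mgmt != "unknown")
  cfg <- resampling_config(sample_sizes = c(50, n_known, 279),
                           repetitions = 5,
                           model_specs = model_spec("wv", "log", "mgmt"),
                           master_seed = 3)
  res <- run_resampling(co, cfg)
  expect_equal(max(res$cells$n), n_known)
  expect_equal(sort(unique(res$cells$n)), c(50, n_known))
  expect_true(all(res$cells$effective_max_n == n_known))
})

test_that("compare_extremes needs stored p-values and picks the extremes", {
  co <- generate_cohort(cohort_config(n_patients = 100, seed = 58))
  cfg <- resampling_config(sample_sizes = c(20, 50, 100), repetitions = 30,
                           model_specs = model_spec("diameter"),
                           master_seed = 4, store_pvalues = FALSE)
  res <- run_resampling(co, cfg)
  expect_error(compare_extremes(res), "store_pvalues")
  cfg2 <- resampling_config(sample_sizes = c(20, 50, 100), repetitions = 30,
                            model_specs = model_spec("diameter"),
                            master_seed = 4)
  res2 <- run_resampling(co, cfg2)
  ks <- compare_extremes(res2)
  expect_equal(ks$n_lo, 20L)
  expect_equal(ks$n_hi, 100L)
  expect_true(ks$d >= 0 && ks$d <= 1)
})

test_that("bootstrap p-values re-centre on the source cohort's coefficient", {
  # Resamples at n = n_source test H0: beta = 0 while centred on the
  # cohort's empirical beta_hat ~ N(0, se^2) under a null generator, so the
  # long-run rejection rate is P(|Z1 + Z2| > 1.96) = 2 * Phi(-1.96/sqrt(2))
  # ~ 16.6%, not the nominal 5%. This is a property of the bootstrap
  # design, and the implementation must reproduce it.
  oracle <- 100 * 2 * pnorm(-1.96 / sqrt(2))
  pcts <- vapply(1:60, function(seed) {
    co <- generate_cohort(cohort_config(preset = "null", n_patients = 120,
                                        seed = 2000 + seed))
    cfg <- resampling_config(sample_sizes = 120, repetitions = 150,
                             model_specs = model_spec("wv", "log"),
                             master_seed = seed, store_pvalues = FALSE)
    run_resampling(co, cfg)$cells$pct_05
  }, numeric(1))
  se <- sd(pcts) / sqrt(length(pcts))
  expect_lt(abs(mean(pcts) - oracle), 3 * se + 1)
})

test_that("fresh-cohort simulation is calibrated at the nominal level", {
  cfg <- cohort_config(preset = "null")
  p <- simulate_wald_pvalues(cfg, sample_size = 60, repetitions = 600,
                             spec = model_spec("cv"), seed = 61)
  expect_gt(length(p), 590)
  expect_equal(percent_significant(p, 0.05), 5, tolerance = 0.5)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("resampling_table and pvalues_long reshape the cells faithfully", {
  co <- generate_cohort(cohort_config(n_patients = 80, seed = 62))
  cfg <- resampling_config(sample_sizes = c(30, 80), repetitions = 25,
                           master_seed = 5) # default six univariable models
  res <- run_resampling(co, cfg)
  expect_equal(nrow(res$cells), 12L)
  wide <- resampling_table(res, 0.05)
  expect_equal(nrow(wide), 2L)
  expect_equal(ncol(wide), 7L) # n + six models
  long <- pvalues_long(res)
  expect_equal(nrow(long), sum(res$cells$n_counted))
  expect_error(resampling_table(res, 0.2), "thresholds")
})
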