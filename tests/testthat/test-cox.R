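test_that("partial log likelihood matches closed forms and tie-free identity", {
  co <- tiny_cohort()[1:3, ]
  co$event <- 1L
  spec <- model_spec("wv")
  # at beta = 0 with 3 distinct event times: -log(3!) over risk-set sizes
  expect_equal(partial_log_likelihood(0, co, spec), -log(6), tolerance = 1e-12)
  # no ties: Efron and Breslow agree at any beta
  co6 <- random_small_cohort(6, seed = 21)
  for (b in c(-0.4, 0, 0.015)) {
    expect_equal(
      partial_log_likelihood(b, co6, model_spec("wv", "log")),
      partial_log_likelihood(b, co6, model_spec("wv", "log"),
                             ties = "breslow"),
      tolerance = 1e-12
    )
  }
  expect_error(partial_log_likelihood(c(0, 1), co, spec), "length")
})

test_that("fit_cox maximises the hand-written Efron partial likelihood", {
  # spec example: 4 subjects, times 1..4 all events, x = (1, 0, 1, 0)
  co <- tiny_cohort()[1:4, ]
  co$time_months <- 1:4
  co$event <- 1L
  co$wv_cm3 <- c(1, 0.5, 1, 0.5) * 100
  spec <- model_spec("wv", "log")
  beta_hat <- tidy(fit_cox(co, spec))$estimate[1]
  beta_grid <- grid_maximise_pll(co, spec)
  expect_lt(abs(beta_hat - beta_grid), 1e-3)
  # fitted maximum dominates nearby perturbations
  ll_hat <- partial_log_likelihood(beta_hat, co, spec)
  expect_gte(ll_hat, partial_log_likelihood(beta_hat + 0.1, co, spec))
  expect_gte(ll_hat, partial_log_likelihood(beta_hat - 0.1, co, spec))
})

test_that("wald_p matches the normal-quantile oracle and is symmetric", {
  expect_equal(wald_p(0, 1), 1)
  expect_equal(wald_p(1.959964, 1), 0.05, tolerance = 1e-6)
  expect_equal(wald_p(0.7, 0.2), wald_p(-0.7, 0.2))
  expect_error(wald_p(1, 0), "positive")
  expect_error(wald_p(1, -1), "positive")
})

test_that("concordance index reproduces hand-enumerated pair counts", {
  co <- tiny_cohort()[1:3, ]
  co$time_months <- c(1, 2, 3)
  co$event <- 1L
  # risks (3, 1, 2): pairs (1,2) and (1,3) concordant, (2,3) discordant
  expect_equal(concordance_index(co, c(3, 1, 2)), 2 / 3)
  expect_equal(concordance_index(co, -co$time_months), 1)
  expect_equal(concordance_index(co, rep(1, 3)), 0.5)
  expect_error(concordance_index(co, c(1, 2)), "one per patient")
  co_censored <- co
  co_censored$event <- 0L
  expect_error(concordance_index(co_censored, c(3, 1, 2)), "comparable")
})

test_that("rescaling a size variable rescales beta but not p or C", {
  co <- generate_cohort(cohort_config(n_patients = 200, seed = 31))
  spec <- model_spec("cv")
  f1 <- fit_cox(co, spec)
  co_scaled <- co
  co_scaled$cv_cm3 <- co$cv_cm3 * 1000 # cm^3 -> mm^3
  f2 <- fit_cox(co_scaled, spec)
  t1 <- tidy(f1); t2 <- tidy(f2)
  expect_equal(t2$estimate[1], t1$estimate[1] / 1000, tolerance = 1e-6)
  expect_equal(t2$p_value[1], t1$p_value[1], tolerance = 1e-6)
  expect_equal(f2$concordance, f1$concordance, tolerance = 1e-12)
  # on the log scale a multiplicative rescaling changes nothing at all
  f3 <- fit_cox(co, model_spec("cv", "log"))
  f4 <- fit_cox(co_scaled, model_spec("cv", "log"))
  expect_equal(tidy(f4)$estimate[1], tidy(f3)$estimate[1], tolerance = 1e-6)
  expect_equal(tidy(f4)$p_value[1], tidy(f3)$p_value[1], tolerance = 1e-6)
  expect_equal(f4$concordance, f3$concordance, tolerance = 1e-12)
})

test_that("constant covariates are dropped and a constant size is refused", {
  co <- generate_cohort(cohort_config(n_patients = 80, seed = 32))
  co$sex <- factor("female", levels = levels(co$sex))
  f <- fit_cox(co, model_spec("wv", "log", c("age", "sex")))
  expect_true("sex_female" %in% f$dropped_terms)
  expect_false("sex_female" %in% tidy(f)$term)
  co$wv_cm3 <- 100
  expect_error(fit_cox(co, model_spec("wv")), "constant")
  # zero events is a validation error, not a crash
  co2 <- generate_cohort(cohort_config(n_patients = 40, seed = 33))
  co2$event <- 0L
  expect_error(fit_cox(co2, model_spec("wv")), "events")
})

test_that("overall Wald p equals the coefficient Wald p for one-term models", {
  co <- generate_cohort(cohort_config(n_patients = 150, seed = 34))
  f <- fit_cox(co, model_spec("diameter"))
  expect_equal(f$overall_wald_p, tidy(f)$p_value[1], tolerance = 1e-9)
})

test_that("MGMT adjustment drops unknown rows from the fit", {
  co <- generate_cohort(cohort_config(n_patients = 250, seed = 35))
  n_known <- sum(co$mgmt != "unknown")
  expect_lt(n_known, nrow(co))
  f <- fit_cox(co, model_spec("wv", "log", "mgmt"))
  expect_equal(f$n_used, n_known)
  f_all <- fit_cox(co, model_spec("wv", "log",
                                  c("age", "sex", "surgery", "oncology",
                                    "mgmt")))
  expect_equal(f_all$n_used, n_known)
})

test_that("the model suite holds all 42 fits in the published layout", {
  co <- generate_cohort(cohort_config(n_patients = 160, seed = 36))
  suite <- build_model_suite(co)
  expect_equal(nrow(suite), 42L)
  expect_equal(sum(suite$adjustment == "none"), 6L)
  expect_equal(sum(suite$adjustment == "all"), 6L)
  n_known <- sum(co$mgmt != "unknown")
  expect_true(all(suite$n_used[grepl("mgmt|all", suite$adjustment)] == n_known))
  expect_true(all(suite$n_used[suite$adjustment == "none"] == nrow(co)))
  uni <- suite_univariable_table(suite)
  expect_equal(nrow(uni), 6L)
  expect_true(all(c("model", "C", "HR", "p") %in% names(uni)))
  multi <- suite_multivariable_table(suite)
  expect_equal(nrow(multi), 6L) # age, sex, surgery, oncology, mgmt, all
})

test_that("penalised spline recovers a linear log-hazard with edf near 1", {
  # generate with a hazard exactly linear in log(WV)
  cfg <- cohort_config(preset = "null", n_patients = 500, seed = 37,
                       betas = c(log_wv = 0.6))
  co <- generate_cohort(cfg)
  sp <- fit_penalized_spline(co, "wv", transform = "log")
  expect_lt(sp$edf, 2.5)
  # centred at the sample median: exactly zero there
  expect_equal(sp$curve$log_hr[which.min(abs(sp$curve$size - sp$reference))],
               0, tolerance = 1e-12)
  # curve stays close to the best straight line relative to its CI width
  line <- stats::lm(log_hr ~ size, data = sp$curve)
  dev <- max(abs(stats::resid(line)))
  ci_width <- stats::median(sp$curve$ci_hi - sp$curve$ci_lo)
  expect_lt(dev, ci_width / 2)
  expect_error(fit_penalized_spline(co[1:10, ], "wv"), "20 events")
})

test_that("univariable fits recover a known coefficient at large n", {
  beta_true <- 0.5
  cfg <- cohort_config(preset = "null", n_patients = 2000, seed = 38,
                       betas = c(log_cv = beta_true))
  co <- generate_cohort(cfg)
  t1 <- tidy(fit_cox(co, model_spec("cv", "log")))
  expect_lt(abs(t1$estimate[1] - beta_true), 3 * t1$std_error[1])
})
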