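# Non-parametric bootstrap, goodness-of-fit tables, visual predictive
# check.

test_that("bootstrap of a deterministic clone cohort returns the point estimate", {
  # all patients identical, no variability: every resample is the same
  # dataset, so every refit lands on the point estimate
  dm <- degenerate_models()
  co <- simulate_cohort(cohort_spec(n_patients = 6, missing_npt0 = 0),
                        seed = 2, pk = dm$pk, npt = dm$npt, inr = dm$inr)
  # clone patient 1 into all slots
  co6 <- warfpkpd:::resample_cohort(co, rep(co$covariates$patient_id[1], 6))
  fit <- fit_stage_pk(co6, dm$pk, ctrl1())
  bs <- bootstrap_fit(co6, fit, n_resamples = 2, seed = 1,
                      control = ctrl1())
  expect_equal(bs$n_ok, 2)
  expect_equal(bs$summary$mean, bs$summary$point, tolerance = 1e-4)
})

test_that("bootstrap draws only source patients and is seed-reproducible", {
  co <- small_cohort(n = 12, seed = 7)
  fit <- fit_stage_pk(co, control = ctrl1())
  b1 <- bootstrap_fit(co, fit, n_resamples = 5, seed = 42,
                      control = ctrl1())
  b2 <- bootstrap_fit(co, fit, n_resamples = 5, seed = 42,
                      control = ctrl1())
  expect_identical(b1$draws, b2$draws)
  expect_equal(b1$n_ok + b1$n_fail, 5)
  # percentile columns follow the rank-order definition
  qs <- apply(b1$draws, 2, quantile, probs = c(0.025, 0.975), type = 1,
              names = FALSE)
  expect_equal(b1$summary$lower, unname(qs[1, ]))
  expect_equal(b1$summary$upper, unname(qs[2, ]))
})

test_that("rank percentile convention picks the 2.5th/97.5th ranked values", {
  x <- sample(1:200)
  expect_equal(quantile(x, 0.025, type = 1, names = FALSE), sort(x)[5])
  expect_equal(quantile(x, 0.975, type = 1, names = FALSE), sort(x)[195])
})

test_that("gof tables report identity-line slopes near one when well specified", {
  co <- small_cohort(n = 25, seed = 17)
  fit <- fit_stage_pk(co, control = ctrl1())
  g <- gof_tables(fit)
  expect_equal(nrow(g$table), fit$n_obs)
  expect_gt(g$slopes[["obs_vs_pred_ind"]], 0.9)
  expect_lt(g$slopes[["obs_vs_pred_ind"]], 1.1)
  # residual trend vanishes when residuals are pure noise (no random
  # effects, so INR-driven dose titration cannot feed exposure back
  # into the population prediction)
  om0 <- reference_popmodel("pk"); om0$omega[] <- 0
  c0 <- simulate_cohort(cohort_spec(n_patients = 40, missing_npt0 = 0),
                        seed = 19, pk = om0)
  ft <- fit_stage_pk(c0, om0, ctrl1())
  expect_lt(abs(gof_tables(ft)$slopes[["wres_trend"]]), 0.5)
  # zero-noise fit: observations equal individual predictions
  dm <- degenerate_models()
  co0 <- simulate_cohort(cohort_spec(n_patients = 8, missing_npt0 = 0),
                         seed = 3, pk = dm$pk, npt = dm$npt, inr = dm$inr)
  f0 <- fit_stage_pk(co0, dm$pk, ctrl1())
  g0 <- gof_tables(f0)
  expect_equal(g0$table$obs, g0$table$pred_ind, tolerance = 0.01)
})

test_that("vpc bands cover self-simulated data and collapse at n_sim = 1", {
  co <- small_cohort(n = 25, seed = 17)
  fit <- fit_stage_pk(co, control = ctrl1())
  v <- vpc(co, fit, n_sim = 30, seed = 5, n_bins = 5)
  expect_true(all(v$sim_p5 <= v$sim_p50 & v$sim_p50 <= v$sim_p95))
  cover <- mean(v$obs_p50 >= v$sim_p5 & v$obs_p50 <= v$sim_p95)
  expect_gte(cover, 0.8)
  v1 <- vpc(co, fit, n_sim = 1, seed = 5, n_bins = 4)
  expect_equal(nrow(v1), 4)
  # data with tripled noise fall outside the fitted bands at the extremes
  co_bad <- co
  cp_rows <- co_bad$observations$obs_type == "CP"
  set.seed(11)
  co_bad$observations$value[cp_rows] <-
    pmax(co_bad$observations$value[cp_rows] +
           rnorm(sum(cp_rows), 0, 2 * fit$sigma), 0)
  vb <- vpc(co_bad, fit, n_sim = 30, seed = 5, n_bins = 5)
  expect_gt(mean(vb$obs_p95 > v$sim_p95), 0.5)
})
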