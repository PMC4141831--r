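# Laplace/FOCE estimation machinery: objective correctness, empirical
# Bayes estimates, residuals, invariances, degenerate recovery.

test_that("OFV reduces to the closed-form normal -2LL without random effects", {
  p <- typical_params()
  reg <- dose_regimen(0, 5)
  obs_t <- 24
  f <- cp_profile(reg, p, obs_t)
  y <- f + 0.03
  sg <- 0.07
  ofv <- warfpkpd:::cpp_pk_laplace(0, 2.5, c(0L, 1L), obs_t, y, c(0L, 1L),
                                   240, 13.8, 2, 0, sg, 0, FALSE)$ofv
  expect_equal(ofv, log(2 * pi * sg^2) + 0.03^2 / sg^2, tolerance = 1e-10)
})

test_that("C++ Laplace equals an independent R Laplace implementation", {
  for (s in 1:4) {
    toy <- pk_toy(s, omega = 0.4, sigma = 0.07)
    expect_equal(toy$ofv, r_laplace_ofv(toy$q), tolerance = 1e-5)
  }
  for (s in 1:4) {
    toy <- inr_toy(s, omega = 0.241, sigma = 0.247)
    expect_equal(toy$ofv, r_laplace_ofv(toy$q), tolerance = 1e-5)
  }
})

test_that("Laplace matches adaptive Gauss-Hermite quadrature on 1-D toys", {
  # sharp-likelihood regime where the expansion is in its domain
  for (s in 1:5) {
    toy <- pk_toy(s, omega = 0.3, sigma = 0.02)
    expect_equal(toy$ofv, agq_ofv(toy$q), tolerance = 1e-3)
  }
  for (s in 1:5) {
    toy <- inr_toy(s, omega = 0.241, sigma = 0.02)
    expect_equal(toy$ofv, agq_ofv(toy$q), tolerance = 1e-3)
  }
})

test_that("OFV is invariant to patient ordering", {
  co <- small_cohort()
  f1 <- fit_stage_pk(co, control = ctrl1())
  perm <- rev(co$covariates$patient_id)
  co2 <- warfpkpd:::resample_cohort(co, perm)
  f2 <- fit_stage_pk(co2, control = ctrl1())
  expect_equal(f1$ofv, f2$ofv, tolerance = 1e-6)
})

test_that("degenerate simulate-fit cycle returns the generating values", {
  dm <- degenerate_models()
  co <- simulate_cohort(cohort_spec(n_patients = 15, missing_npt0 = 0),
                        seed = 23, pk = dm$pk, npt = dm$npt, inr = dm$inr)
  fpk <- fit_stage_pk(co, dm$pk, ctrl1())
  expect_equal(fpk$theta[["cl"]], 240, tolerance = 0.005)
  b <- warfpkpd:::cov_value(fpk, "bsa")
  expect_equal(b, 2.14, tolerance = 0.05)
  fn <- fit_stage_npt(co, fpk, dm$npt, ctrl1())
  expect_equal(fn$theta[["ic50"]], 0.0725, tolerance = 0.0725 * 0.03)
  expect_equal(fn$theta[["kout"]], 0.0136, tolerance = 0.0136 * 0.03)
  fi <- fit_stage_inr(co, fn, dm$inr, ctrl1())
  expect_equal(fi$theta[["lam"]], 3.48, tolerance = 3.48 * 0.03)
})

test_that("empirical Bayes estimates shrink to typical without data and track truth", {
  co <- small_cohort(n = 20, seed = 9)
  # drop one patient's Cp observations entirely
  drop_id <- co$covariates$patient_id[3]
  co$observations <- co$observations[!(co$observations$patient_id ==
    drop_id & co$observations$obs_type == "CP"), ]
  fit <- fit_stage_pk(co, control = ctrl1())
  expect_false(drop_id %in% fit$ids)
  allp <- individual_parameters(fit, co)
  tv <- warfpkpd:::apply_covariate_model(
    fit$model, co$covariates[co$covariates$patient_id == drop_id, ])
  expect_equal(allp$cl[allp$patient_id == drop_id], tv$cl)
  # recovered etas correlate with the generating ones
  eb <- ebe(fit)
  tr <- co$truth[match(eb$patient_id, co$truth$patient_id), ]
  expect_gt(cor(eb$eta_cl, tr$eta_cl), 0.8)
})

test_that("weighted residuals behave under correct and broken noise models", {
  # noise-free data at the generating parameters: raw residuals vanish
  dm <- degenerate_models()
  co0 <- simulate_cohort(cohort_spec(n_patients = 10, missing_npt0 = 0),
                         seed = 29, pk = dm$pk, npt = dm$npt,
                         inr = dm$inr)
  f0 <- fit_stage_pk(co0, dm$pk, ctrl1())
  p0 <- weighted_residuals(f0)
  expect_lt(max(abs(p0$obs - p0$pred_pop)), 1e-3)
  # well-specified simulation: standardised residuals ~ (0, 1)
  co <- small_cohort(n = 25, seed = 17)
  fit <- fit_stage_pk(co, control = ctrl1())
  w <- weighted_residuals(fit)$wres
  expect_lt(abs(mean(w)), 0.2)
  expect_gt(sd(w), 0.8)
  expect_lt(sd(w), 1.2)
  # without random effects the denominator is sigma itself, so halving
  # the assumed sigma doubles the spread
  om0 <- reference_popmodel("pk"); om0$omega[] <- 0
  con <- simulate_cohort(cohort_spec(n_patients = 12, missing_npt0 = 0),
                         seed = 31, pk = om0)
  fo <- fit_stage_pk(con, om0, ctrl1())
  wo <- weighted_residuals(fo)
  manual <- (wo$obs - wo$pred_pop) / fo$sigma
  expect_equal(wo$wres, manual, tolerance = 1e-10)
  expect_equal(sd((wo$obs - wo$pred_pop) / (fo$sigma / 2)), 2 * sd(wo$wres),
               tolerance = 1e-10)
})

test_that("adding a covariate never raises the minimised OFV", {
  co <- small_cohort(n = 20, seed = 9)
  base <- reference_popmodel("pk")
  base$covariates <- list()
  f0 <- fit_stage_pk(co, base, ctrl1())
  for (nm in c("bsa", "age")) {
    m1 <- warfpkpd:::add_term(f0$model, "cl", nm, "power",
                              median(co$covariates[[nm]]))
    f1 <- fit_stage_pk(co, m1, ctrl1())
    expect_lte(f1$ofv, f0$ofv + 0.05)
  }
})

test_that("model packing round-trips and validates its inputs", {
  m <- reference_popmodel("npt")
  par <- warfpkpd:::pack_model(m)
  m2 <- warfpkpd:::unpack_model(par, m)
  expect_equal(m2$theta, m$theta)
  expect_equal(m2$sigma, m$sigma)
  expect_equal(m2$covariates[[1]]$value, 2.07)
  expect_error(population_model("pk", theta = c(bogus = 1),
                                omega = c(bogus = 0.1), sigma = 1),
               "theta entries")
  expect_error(population_model("pk", theta = c(cl = 240),
                                omega = c(cl = 0.4), sigma = -1))
})

test_that("fits expose convergence metadata and exclusion accounting", {
  co <- simulate_cohort(cohort_spec(n_patients = 20, missing_npt0 = 0.1),
                        seed = 41)
  fpk <- fit_stage_pk(co, control = ctrl1())
  fn <- fit_stage_npt(co, fpk, control = ctrl1())
  expect_equal(fn$n_patients, 18)
  expect_equal(length(fn$excluded), 2)
  expect_true(is.numeric(fn$ofv) && is.finite(fn$ofv))
  out <- capture.output(print(fn))
  expect_true(any(grepl("NPT fit", out)))
})
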