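# Synthetic cohort generator: genotype frequencies, covariate
# distributions, dosing protocols, sampling design, residual noise,
# CSV round trips.

test_that("genotypes follow Hardy-Weinberg at the specified MAFs", {
  set.seed(11)
  cv <- sample_covariates(cohort_spec(n_patients = 8000))
  maf_hat <- mean(cv$cyp2c9_star3) / 2
  expect_lt(abs(maf_hat - 0.056), 0.01)
  expect_lt(abs(mean(cv$vkorc1_star1) / 2 - 0.096), 0.01)
  expect_lt(abs(mean(cv$cyp4f2_star3) / 2 - 0.278), 0.012)
  # HWE: heterozygote fraction ~ 2 p q for the commonest locus
  p <- 0.278
  expect_lt(abs(mean(cv$cyp4f2_star3 == 1) - 2 * p * (1 - p)), 0.02)
  # zero MAF -> all wild type
  cv0 <- sample_covariates(cohort_spec(
    n_patients = 200, maf = c(cyp2c9_star3 = 0, vkorc1_star1 = 0,
                              cyp4f2_star3 = 0)))
  expect_true(all(cv0$cyp2c9_star3 == 0))
  expect_true(all(cv0$cyp4f2_carrier == 0))
})

test_that("covariate marginals and correlations match the cohort summary", {
  set.seed(12)
  cv <- sample_covariates(cohort_spec(n_patients = 8000))
  expect_lt(abs(mean(cv$bsa) - 1.74), 0.02)
  expect_lt(abs(sd(cv$bsa) - 0.18), 0.015)
  expect_lt(abs(mean(cv$age) - 64.5), 1)
  expect_lt(abs(mean(cv$npt0) - 118.2), 1.5)
  expect_lt(abs(cor(cv$age, cv$weight) + 0.358), 0.05)
  expect_lt(abs(cor(cv$age, cv$bsa) + 0.397), 0.05)
  expect_lt(abs(cor(cv$age, cv$clcr) + 0.568), 0.05)
  expect_true(all(cv$bsa > 0))
  expect_true(all(cv$npt0 > 0))
})

test_that("individual parameters are log-normal around covariate values", {
  set.seed(13)
  cv <- sample_covariates(cohort_spec(n_patients = 6000))
  tr <- sample_individual_params(cv)
  tv_cl <- cl_from_covariates(240, 0.543, 2.14, cv$cyp2c9_star3, cv$bsa)
  expect_equal(sd(log(tr$cl / tv_cl)), 0.399, tolerance = 0.02)
  # median for wild-type, near-median-BSA patients ~ typical value
  sel <- cv$cyp2c9_star3 == 0 & abs(cv$bsa - 1.74) < 0.02
  expect_equal(median(tr$cl[sel]), 240, tolerance = 0.08 * 240)
  # omega = 0 gives the typical value exactly
  m0 <- reference_popmodel("pk"); m0$omega[] <- 0
  tr0 <- sample_individual_params(cv[1:50, ], pk = m0)
  expect_equal(tr0$cl, tv_cl[1:50], tolerance = 1e-12)
})

test_that("dose assignment follows protocol, loading and titration rules", {
  p <- typical_params()
  # standard protocol: three 7.5 mg loading days (1.5 x 5 mg)
  reg <- assign_regimen(p, "standard", days = 30)
  expect_equal(reg$dose_mg[1:3], rep(7.5, 3))
  expect_equal(reg$time[1:4], c(0, 24, 48, 72))
  # genotype-guided loading averages ~4.1 mg/day over a large cohort
  set.seed(14)
  cv <- sample_covariates(cohort_spec(n_patients = 400))
  lo <- mapply(function(v1, c3) {
    assign_regimen(p, "genotype", vkorc1_star1 = v1, cyp2c9_star3 = c3,
                   days = 4)$dose_mg[1]
  }, cv$vkorc1_star1, cv$cyp2c9_star3)
  expect_equal(mean(lo), 4.1, tolerance = 0.25)
  # an insensitive patient (huge IC50) stays below target: maintenance
  # doses escalate at every titration visit
  insens <- typical_params()
  insens$ic50 <- 50
  up <- assign_regimen(insens, "standard", days = 40)
  expect_true(all(diff(up$dose_mg[-(1:3)]) >= 0))
  expect_gt(up$dose_mg[40], up$dose_mg[4])
  # a hypersensitive patient gets stepped down
  sens <- typical_params()
  sens$ic50 <- 0.005; sens$cl_s <- 100
  dn <- assign_regimen(sens, "standard", days = 40)
  expect_lt(dn$dose_mg[40], dn$dose_mg[1])
})

test_that("residual error model matches the declared magnitudes", {
  n <- 30000
  tr <- data.frame(patient_id = 1, time_h = 1,
                   obs_type = rep(c("CP", "NPT", "INR"), each = n),
                   truth = rep(c(0.9, 110, 2.5), each = n))
  set.seed(15)
  ob <- generate_observations(tr)
  cp <- ob[ob$obs_type == "CP", ]
  npt <- ob[ob$obs_type == "NPT", ]
  inr <- ob[ob$obs_type == "INR", ]
  expect_equal(sd(cp$value - cp$truth), 0.0697, tolerance = 0.002)
  expect_equal(sd(npt$value - npt$truth), 12.2, tolerance = 0.3)
  expect_equal(sd(inr$value / inr$truth - 1), 0.247, tolerance = 0.005)
  expect_true(all(ob$value[ob$obs_type != "INR"] >= 0))
  # zero sigma reproduces the truth exactly
  ob0 <- generate_observations(tr[1:10, ], sigma_cp = 0, sigma_npt = 0,
                               sigma_inr = 0)
  expect_equal(ob0$value, ob0$truth)
})

test_that("simulated cohorts honour the sampling design and exclusions", {
  co <- simulate_cohort(seed = 31)
  obs <- co$observations
  expect_equal(nrow(co$covariates), 99)
  expect_equal(sum(is.na(co$covariates$npt0)), 3)
  cnt <- table(obs$obs_type, obs$patient_id)
  expect_true(all(cnt["INR", ] >= 8 & cnt["INR", ] <= 13))
  expect_true(all(cnt["CP", ] >= 1 & cnt["CP", ] <= 12))
  expect_true(all(cnt["NPT", ] >= 4 & cnt["NPT", ] <= 12))
  # roughly 99 x 11.1 INR rows
  expect_equal(sum(cnt["INR", ]), 99 * 11.1, tolerance = 0.08 * 1100)
  expect_true(all(obs$time_h >= 0 & obs$time_h <= 2160))
  expect_true(all(co$dosing$time_h >= 0))
  # five pre-treatment INR draws per patient
  pre <- obs[obs$obs_type == "INR" & obs$time_h <= 0, ]
  expect_true(all(table(pre$patient_id) == 5))
  # determinism under a fixed seed
  co2 <- simulate_cohort(seed = 31)
  expect_identical(co$observations$value, co2$observations$value)
  expect_identical(co$dosing$dose_mg, co2$dosing$dose_mg)
})

test_that("cohorts round-trip through the CSV representation", {
  co <- small_cohort()
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("dosing.csv",
                                               "observations.csv",
                                               "covariates.csv",
                                               "truth.csv")))))
  back <- read_dataset(dir)
  expect_equal(back$observations$value, co$observations$value,
               tolerance = 1e-12)
  expect_equal(back$dosing$dose_mg, co$dosing$dose_mg)
  expect_equal(back$covariates$bsa, co$covariates$bsa, tolerance = 1e-12)
})

test_that("dataset validation names offending ids and files", {
  co <- small_cohort()
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  obs <- utils::read.csv(file.path(dir, "observations.csv"))
  obs$patient_id[1] <- 999
  utils::write.csv(obs, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  expect_error(read_dataset(dir), "999")
  unlink(file.path(dir, "dosing.csv"))
  expect_error(read_dataset(dir), "dosing.csv")
})

test_that("missing baseline NPT excludes patients from the PD stages", {
  co <- simulate_cohort(cohort_spec(n_patients = 30, missing_npt0 = 0.1),
                        seed = 5)
  n_miss <- sum(is.na(co$covariates$npt0))
  expect_equal(n_miss, 3)
  cl <- setNames(rep(240, 30), co$covariates$patient_id)
  sdn <- warfpkpd:::npt_stage_data(co, cl, 2)
  expect_equal(length(sdn$ids), 27)
  expect_equal(length(sdn$excluded), 3)
})
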