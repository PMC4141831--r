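# Structural model chain: covariate submodels, one-compartment
# superposition, turnover integration, NPT -> INR link.

test_that("clearance submodel reproduces reference and worked values", {
  # reference patient: wild type, BSA at the 1.74 m^2 centering value
  expect_equal(cl_from_covariates(240, 0.543, 2.14, 0, 1.74), 240)
  # one *3 allele halves-ish clearance: 240 * 0.543
  expect_equal(cl_from_covariates(240, 0.543, 2.14, 1, 1.74), 130.32,
               tolerance = 1e-6)
  # allometric body-size scaling: 240 * (1.80/1.74)^2.14
  expect_equal(cl_from_covariates(240, 0.543, 2.14, 0, 1.80), 258.0589,
               tolerance = 1e-6)
  # the *3 multiplier is a 46% reduction
  expect_equal(1 - 0.543, 0.457, tolerance = 1e-12)
  expect_error(cl_from_covariates(-1, 0.543, 2.14, 0, 1.74), "positive")
  expect_error(cl_from_covariates(240, 0.543, 2.14, 0, -0.2), "positive")
})

test_that("IC50 submodel reproduces reference and worked values", {
  expect_equal(ic50_from_covariates(0.0725, 2.07, 1.30, 0, 0), 0.0725)
  expect_equal(ic50_from_covariates(0.0725, 2.07, 1.30, 1, 0), 0.150075,
               tolerance = 1e-9)
  expect_equal(ic50_from_covariates(0.0725, 2.07, 1.30, 1, 1), 0.1950975,
               tolerance = 1e-9)
  expect_error(ic50_from_covariates(0.0725, -2, 1.3, 0, 0), "positive")
})

test_that("lambda submodel reproduces reference and worked values", {
  expect_equal(lambda_from_covariates(3.48, 0.00588, 119), 3.48)
  expect_equal(lambda_from_covariates(3.48, 0.00588, 100),
               3.48 * exp(0.00588 * -19), tolerance = 1e-12)
  expect_equal(lambda_from_covariates(3.48, 0.00588, 100), 3.1124,
               tolerance = 1e-4)
  expect_equal(lambda_from_covariates(3.48, 0.00588, 140), 3.9372,
               tolerance = 1e-4)
})

test_that("covariate submodels return theta exactly at reference values", {
  for (m in list(reference_popmodel("pk"), reference_popmodel("npt"),
                 reference_popmodel("inr"))) {
    ref <- data.frame(cyp2c9_star3 = 0, bsa = 1.74, vkorc1_star1 = 0,
                      cyp4f2_carrier = 0, npt0 = 119)
    tv <- warfpkpd:::apply_covariate_model(m, ref)
    for (pn in names(m$theta))
      expect_equal(tv[[pn]], unname(m$theta[[pn]]))
  }
})

test_that("single-dose Cp profile matches the closed form", {
  p <- typical_params()
  reg <- dose_regimen(0, 5)
  expect_equal(cp_profile(reg, p, 0), 0)
  # 2.5 mg S-warfarin, CL 240 mL/h, Vd 13.8 L, Ka 2/h at 24 h
  ke <- 0.24 / 13.8
  manual <- 2.5 * 2 / (13.8 * (2 - ke)) * (exp(-ke * 24) - exp(-2 * 24))
  expect_equal(cp_profile(reg, p, 24), manual, tolerance = 1e-10)
  expect_equal(manual, 0.1204, tolerance = 1e-3)
  expect_error(cp_profile(reg, p, -1), "non-negative")
})

test_that("superposition agrees with ODE integration of the PK system", {
  p <- typical_params()
  set.seed(42)
  for (rep in 1:3) {
    times <- sort(c(0, runif(12, 1, 400)))
    dose_t <- seq(0, 360, by = 24)
    doses <- runif(length(dose_t), 1, 8)
    reg <- dose_regimen(dose_t, doses)
    closed <- cp_profile(reg, p, times)
    # independent oracle: stiff ODE integration of gut/central amounts
    ke <- p$cl_s / 1000 / p$vd
    deriv <- function(t, y, parms)
      list(c(-p$ka * y[1], p$ka * y[1] - ke * y[2]))
    ev <- data.frame(var = "gut", time = dose_t,
                     value = p$s_fraction * doses, method = "add")
    tt <- sort(unique(c(times, dose_t)))
    sol <- deSolve::lsoda(c(gut = 0, central = 0), tt, deriv, NULL,
                          events = list(data = ev), rtol = 1e-11,
                          atol = 1e-11)
    ode_cp <- approx(sol[, "time"], sol[, "central"] / p$vd,
                     xout = times)$y
    expect_equal(closed, ode_cp, tolerance = 1e-6)
  }
})

test_that("steady-state average Cp equals dose rate over clearance", {
  p <- typical_params()
  reg <- daily_regimen(4.34, 70)
  tt <- seq(60 * 24, 61 * 24, by = 0.25)
  avg <- mean(cp_profile(reg, p, tt))
  expect_equal(avg, (0.5 * 4340 / 24) / 240, tolerance = 5e-3)
})

test_that("PK is linear: doubling all doses doubles Cp everywhere", {
  p <- typical_params()
  tt <- c(10, 50, 100, 300)
  expect_equal(cp_profile(daily_regimen(8, 15), p, tt),
               2 * cp_profile(daily_regimen(4, 15), p, tt),
               tolerance = 1e-12)
})

test_that("flip-flop degenerate case ka == ke uses the analytic limit", {
  p <- typical_params(vd = 1, ka = 0.005)  # cl/1000/vd == ka
  p$cl_s <- 5
  reg <- dose_regimen(0, 2)
  val <- cp_profile(reg, p, 10)
  expect_equal(val, 1 * 0.005 * 10 * exp(-0.005 * 10) / 1,
               tolerance = 1e-6)
})

test_that("NPT stays at baseline without drug and halves at Cp = IC50", {
  p <- typical_params()
  tt <- seq(0, 2000, by = 50)
  expect_equal(npt_profile(function(t) rep(0, length(t)), p, tt),
               rep(p$npt0, length(tt)), tolerance = 1e-10)
  # constant Cp at IC50: 50% synthesis inhibition, NPT -> NPT0/2
  half <- npt_profile(function(t) rep(p$ic50, length(t)), p, 5000)
  expect_equal(half, p$npt0 / 2, tolerance = 1e-4)
})

test_that("turnover integration is exact for constant inhibition", {
  # constant Cp makes the ODE linear with constant input: closed form
  p <- typical_params()
  cp0 <- 0.2
  inh <- 1 - cp0 / (p$ic50 + cp0)
  tt <- c(10, 51, 200, 700)
  closed <- p$npt0 * inh + (p$npt0 - p$npt0 * inh) * exp(-p$kout * tt)
  conv <- npt_profile(function(t) rep(cp0, length(t)), p, tt)
  expect_equal(conv, closed, tolerance = 1e-10)
  # turnover half-time ln2/kout governs the approach
  expect_equal(log(2) / p$kout, 51.0, tolerance = 1e-2)
  mid <- npt_profile(function(t) rep(cp0, length(t)), p, log(2) / p$kout)
  expect_equal((mid - p$npt0 * inh) / (p$npt0 - p$npt0 * inh), 0.5,
               tolerance = 1e-5)
})

test_that("grid integration agrees with the adaptive ODE solver", {
  p <- typical_params()
  reg <- daily_regimen(4, 40)
  cp_fn <- function(t) cp_profile(reg, p, t)
  tt <- c(96, 168, 336, 672, 950)
  ode <- npt_profile(cp_fn, p, tt, method = "ode", rtol = 1e-10,
                     atol = 1e-10)
  conv <- npt_profile(cp_fn, p, tt, grid_h = 0.5)
  expect_equal(conv, ode, tolerance = 2e-3)
  expect_error(npt_profile(function(t) rep(-1, length(t)), p, tt),
               "negative")
})

test_that("INR link reproduces bounds, worked value and monotonicity", {
  p <- typical_params()
  expect_equal(inr_from_npt(p$npt0, p), p$inr_base)
  expect_equal(inr_from_npt(0, p), p$inr_base + 5)
  # fractional inhibition 0.78 with lambda 3.48 and base 1.05
  expect_equal(inr_from_npt(118 * (1 - 0.78), p), 1.05 + 5 * 0.78^3.48,
               tolerance = 1e-9)
  expect_equal(1.05 + 5 * 0.78^3.48, 3.156, tolerance = 1e-3)
  npt_seq <- seq(0, p$npt0, length.out = 50)
  expect_true(all(diff(inr_from_npt(npt_seq, p)) <= 0))
  expect_warning(v <- inr_from_npt(p$npt0 * 1.05, p), "clamped")
  expect_equal(v, p$inr_base)
})

test_that("individual simulation composes the chain sensibly", {
  p <- typical_params()
  flat <- simulate_individual(p, dose_regimen(numeric(0), numeric(0)),
                              grid = seq(0, 100, by = 10))
  expect_true(all(flat$cp == 0))
  expect_true(all(flat$npt == p$npt0))
  expect_true(all(flat$inr == p$inr_base))
  # steady dosing: INR rises monotonically toward a plateau
  traj <- simulate_individual(p, daily_regimen(3, 28),
                              grid = seq(0, 27 * 24, by = 24))
  expect_true(all(diff(traj$inr) > -1e-6))
  expect_lt(max(traj$inr), p$inr_base + 5)
})
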