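# Shared fixtures: small cohorts and cached expensive fits.  Everything is
# generated in code at test time; the cache lives for one test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]]))
    .fixture_env[[name]] <- force(build)
  .fixture_env[[name]]
}

# small cohort for structural/fit plumbing tests
small_cohort <- function(n = 12, seed = 7, ...) {
  fixture(paste0("small", n, "_", seed), {
    simulate_cohort(cohort_spec(n_patients = n, missing_npt0 = 0),
                    seed = seed, ...)
  })
}

# fast single-start control for tests
ctrl1 <- function(...) default_fit_control(n_starts = 1, ...)

# a reference structural parameter set (typical Asian patient)
typical_params <- function(...) {
  structural_params(cl_s = 240, ic50 = 0.0725, kout = 0.0136, npt0 = 118,
                    lam = 3.48, inr_base = 1.05, ...)
}

# daily regimen helper
daily_regimen <- function(dose, days) {
  dose_regimen(seq(0, by = 24, length.out = days), rep(dose, days))
}
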