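#' Structural parameter set for one individual
#'
#' Bundles the parameters of the dose -> Cp(S) -> NPT -> INR model chain for
#' a single patient.  Fixed constants default to the values used throughout
#' the analysis: absorption rate constant `ka` = 2 /h, S-warfarin volume of
#' distribution `vd` = 13.8 L, bioavailability `f_bio` = 1, maximum
#' fractional inhibition of NPT synthesis `imax` = 1, and maximum INR rise
#' above baseline `inr_max` = 5.
#'
#' @param cl_s Oral clearance of S-warfarin (mL/h).
#' @param ic50 Cp(S) giving half-maximal inhibition of NPT synthesis (ug/mL).
#' @param kout First-order NPT degradation rate constant (1/h); the
#'   zero-order synthesis rate is `kout * npt0`.
#' @param npt0 Baseline normal prothrombin concentration (ug/mL).
#' @param lam Exponent linking fractional NPT inhibition to the INR rise.
#' @param inr_base Baseline INR.
#' @param vd,ka,f_bio,imax,inr_max Fixed structural constants (see above).
#' @param s_fraction Fraction of the racemic dose counted as S-warfarin
#'   (default 0.5; warfarin is dosed as the racemate).
#' @return An object of class `structural_params`.
#' @export
structural_params <- function(cl_s, ic50, kout, npt0, lam,
                              inr_base = 1.0, vd = 13.8, ka = 2.0,
                              f_bio = 1.0, imax = 1.0, inr_max = 5.0,
                              s_fraction = 0.5) {
  stopifnot(cl_s > 0, ic50 > 0, kout > 0, npt0 > 0, lam > 0,
            inr_base >= 0, vd > 0, ka > 0, f_bio > 0, imax == 1,
            s_fraction > 0, s_fraction <= 1)
  structure(list(cl_s = cl_s, ic50 = ic50, kout = kout, npt0 = npt0,
                 lam = lam, inr_base = inr_base, vd = vd, ka = ka,
                 f_bio = f_bio, imax = imax, inr_max = inr_max,
                 s_fraction = s_fraction),
            class = "structural_params")
}

#' Dosing regimen of timed racemic warfarin doses
#'
#' @param time Hours since the first dose; non-negative, strictly increasing.
#' @param dose_mg Racemic warfarin dose (mg) at each event; positive.
#' @return A `dose_regimen` data frame with columns `time` and `dose_mg`.
#' @export
dose_regimen <- function(time, dose_mg) {
  stopifnot(length(time) == length(dose_mg))
  if (length(time)) {
    stopifnot(all(time >= 0), all(diff(time) > 0), all(dose_mg > 0))
  }
  structure(data.frame(time = as.numeric(time), dose_mg = as.numeric(dose_mg)),
            class = c("dose_regimen", "data.frame"))
}

#' Covariate submodel for the oral clearance of S-warfarin
#'
#' `CL(S) = theta_cl * eff_cyp2c9^n3 * (bsa / center)^eff_bsa`, where `n3`
#' is the number of CYP2C9*3 alleles carried.  At the reference covariates
#' (no *3 allele, BSA at the centering value) the typical clearance is
#' `theta_cl` itself.
#'
#' @param theta_cl Population clearance at reference covariates (mL/h).
#' @param eff_cyp2c9 Multiplicative effect per CYP2C9*3 allele.
#' @param eff_bsa Allometric exponent on body surface area.
#' @param cyp2c9_star3 Number of *3 alleles (0, 1, 2).
#' @param bsa Body surface area (m^2).
#' @param center Centering BSA (m^2), default the cohort median 1.74.
#' @return Typical clearance (mL/h).
#' @export
cl_from_covariates <- function(theta_cl, eff_cyp2c9, eff_bsa,
                               cyp2c9_star3, bsa, center = 1.74) {
  if (any(theta_cl <= 0)) stop("theta_cl must be positive")
  if (any(bsa <= 0)) stop("bsa must be positive")
  stopifnot(all(cyp2c9_star3 %in% 0:2))
  theta_cl * eff_cyp2c9^cyp2c9_star3 * (bsa / center)^eff_bsa
}

#' Covariate submodel for the IC50 of NPT-synthesis inhibition
#'
#' `IC50 = theta_ic50 * eff_vkorc1^n1 * eff_cyp4f2^carrier`, where `n1`
#' counts VKORC1*1 (-1639G) alleles and `carrier` indicates carriage of at
#' least one CYP4F2*3 allele.  The reference individual is the VKORC1*2/*2
#' homozygote without CYP4F2*3.
#'
#' @param theta_ic50 Population IC50 at reference genotypes (ug/mL).
#' @param eff_vkorc1 Multiplicative effect per VKORC1*1 allele.
#' @param eff_cyp4f2 Multiplicative effect of CYP4F2*3 carriage.
#' @param vkorc1_star1 Number of *1 alleles (0, 1, 2).
#' @param cyp4f2_carrier 1 if at least one CYP4F2*3 allele, else 0.
#' @return Typical IC50 (ug/mL).
#' @export
ic50_from_covariates <- function(theta_ic50, eff_vkorc1, eff_cyp4f2,
                                 vkorc1_star1, cyp4f2_carrier) {
  if (any(theta_ic50 <= 0) || any(eff_vkorc1 <= 0) || any(eff_cyp4f2 <= 0))
    stop("IC50 submodel requires positive multipliers")
  stopifnot(all(vkorc1_star1 %in% 0:2), all(cyp4f2_carrier %in% 0:1))
  theta_ic50 * eff_vkorc1^vkorc1_star1 * eff_cyp4f2^cyp4f2_carrier
}

#' Covariate submodel for the NPT-to-INR exponent
#'
#' `lambda = theta_lam * exp(eff_npt0 * (npt0 - center))`; at the median
#' baseline NPT (center, default 119 ug/mL) the typical value is
#' `theta_lam`.
#'
#' @param theta_lam Population exponent at the centering NPT0.
#' @param eff_npt0 Slope of the exponential NPT0 effect (per ug/mL).
#' @param npt0 Baseline NPT concentration (ug/mL).
#' @param center Centering NPT0 (ug/mL), default 119.
#' @return Typical exponent (dimensionless).
#' @export
lambda_from_covariates <- function(theta_lam, eff_npt0, npt0, center = 119) {
  if (any(theta_lam <= 0)) stop("theta_lam must be positive")
  if (any(npt0 <= 0)) stop("npt0 must be positive")
  theta_lam * exp(eff_npt0 * (npt0 - center))
}

#' Plasma S-warfarin concentration profile
#'
#' Closed-form superposition of one-compartment profiles with first-order
#' absorption and elimination over the dose events of a regimen.  Each dose
#' contributes `F*D_S*Ka / (Vd*(Ka - ke)) * (exp(-ke*dt) - exp(-Ka*dt))`
#' for `dt >= 0`, with `ke = CL/Vd` and `D_S = s_fraction *` racemic dose.
#' The degenerate case `Ka == ke` uses the analytic limit
#' `D*Ka*dt*exp(-Ka*dt)/Vd`.
#'
#' @param regimen A [dose_regimen()].
#' @param p A [structural_params()].
#' @param times Evaluation times (h), non-negative.
#' @return Cp(S) in ug/mL at `times`.
#' @export
cp_profile <- function(regimen, p, times) {
  if (any(times < 0)) stop("times must be non-negative")
  amt <- p$f_bio * p$s_fraction * regimen$dose_mg
  cpp_cp_profile(as.numeric(times), as.numeric(regimen$time),
                 as.numeric(amt), p$cl_s, p$vd, p$ka)
}

#' Normal prothrombin (NPT) concentration profile
#'
#' Integrates the turnover model
#' `dNPT/dt = Kin * (1 - Imax*Cp/(IC50 + Cp)) - Kout * NPT` with
#' `Kin = Kout * NPT0` and `NPT(0) = NPT0`.  The default path uses the
#' exact integrating-factor solution of this linear ODE with the inhibition
#' input taken piecewise-linear on a uniform grid; `method = "ode"` runs
#' `deSolve::lsoda` on the same system and serves as an independent check.
#'
#' @param cp_fn Function of time (h) returning Cp(S) in ug/mL.
#' @param p A [structural_params()].
#' @param times Output times (h), non-negative, increasing.
#' @param method `"conv"` (integrating factor, default) or `"ode"`.
#' @param grid_h Grid step (h) for the default path.
#' @param rtol,atol Solver tolerances for the `"ode"` path.
#' @return NPT in ug/mL at `times`.
#' @export
npt_profile <- function(cp_fn, p, times, method = c("conv", "ode"),
                        grid_h = 0.5, rtol = 1e-8, atol = 1e-8) {
  method <- match.arg(method)
  if (any(times < 0)) stop("times must be non-negative")
  tmax <- max(times, 0)
  if (method == "conv") {
    grid <- seq(0, tmax + grid_h, by = grid_h)
    cp <- cp_fn(grid)
    if (any(cp < 0)) stop("negative Cp supplied to npt_profile")
    npt <- cpp_npt_grid(cp, grid_h, p$npt0, p$ic50, p$kout, p$imax)
    stats::approx(grid, npt, xout = times)$y
  } else {
    kin <- p$kout * p$npt0
    deriv <- function(t, y, parms) {
      cp <- cp_fn(t)
      if (any(cp < 0)) stop("negative Cp supplied to npt_profile")
      list(kin * (1 - p$imax * cp / (p$ic50 + cp)) - p$kout * y)
    }
    tt <- sort(unique(c(0, times)))
    sol <- deSolve::lsoda(c(npt = p$npt0), tt, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) stop("NPT ODE solver failed")
    stats::approx(sol[, "time"], sol[, "npt"], xout = times)$y
  }
}

#' INR from the NPT concentration
#'
#' `INR = INR_base + INR_max * ((NPT0 - NPT)/NPT0)^lambda`.  The inhibition
#' fraction is clamped to `[0, 1]`; observed NPT above baseline (possible
#' through assay noise) is treated as zero inhibition with a warning.
#'
#' @param npt NPT concentration(s), ug/mL.
#' @param p A [structural_params()].
#' @return INR value(s), bounded in `[inr_base, inr_base + inr_max]`.
#' @export
inr_from_npt <- function(npt, p) {
  frac <- (p$npt0 - npt) / p$npt0
  if (any(frac < 0)) {
    warning("NPT above baseline; inhibition clamped to 0")
    frac <- pmax(frac, 0)
  }
  frac <- pmin(frac, 1)
  p$inr_base + p$inr_max * frac^p$lam
}

#' Simulate one individual's Cp(S), NPT and INR trajectories
#'
#' Composes [cp_profile()], [npt_profile()] and [inr_from_npt()] on a time
#' grid (hourly by default).
#'
#' @param p A [structural_params()].
#' @param regimen A [dose_regimen()].
#' @param grid Output times (h); defaults to an hourly grid covering the
#'   regimen plus one week.
#' @param grid_h Integration step passed to [npt_profile()].
#' @return A data frame with columns `time`, `cp`, `npt`, `inr`.
#' @export
simulate_individual <- function(p, regimen, grid = NULL, grid_h = 0.5) {
  if (is.null(grid)) {
    tmax <- if (nrow(regimen)) max(regimen$time) + 168 else 168
    grid <- seq(0, tmax, by = 1)
  }
  cp <- cp_profile(regimen, p, grid)
  cp_fn <- function(t) cp_profile(regimen, p, t)
  npt <- npt_profile(cp_fn, p, grid, grid_h = grid_h)
  inr <- inr_from_npt(npt, p)
  data.frame(time = grid, cp = cp, npt = npt, inr = inr)
}
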