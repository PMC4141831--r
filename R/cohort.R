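#' Specification of a synthetic warfarin-initiation cohort
#'
#' Defaults reproduce the covariate distributions, genotype frequencies and
#' protocol mix of a 99-patient Chinese initiation cohort: age 64.5 +/- 15.2
#' yr, weight 68.4 +/- 12.4 kg, height 163.6 +/- 8.2 cm, baseline NPT
#' 118.2 +/- 22.1 ug/mL, baseline INR 1.05 +/- 0.10, AST 29.2 +/- 16.3 and
#' ALT 27.2 +/- 17.5 IU/L, CLcr 73.3 +/- 36.6 mL/min; minor-allele
#' frequencies 0.056 (CYP2C9*3), 0.096 (VKORC1*1, i.e. 0.904 for the -1639A
#' variant), 0.278 (CYP4F2*3); 77/99 genotype-guided dosing; 3/99 patients
#' with missing baseline NPT.  Age is negatively correlated with weight
#' (-0.358), body surface area (-0.397 in expectation) and CLcr (-0.568)
#' through a Gaussian copula.
#'
#' @param n_patients Cohort size.
#' @param maf Named minor-allele frequencies (`cyp2c9_star3`,
#'   `vkorc1_star1`, `cyp4f2_star3`).
#' @param continuous Named list of `c(mean, sd, lower, upper)` truncated
#'   normal marginals.
#' @param latent_cor Latent correlations: age with weight, height and
#'   CLcr, plus the weight-height correlation (`wt_ht`) that reproduces
#'   the reported BSA spread (1.74 +/- 0.18 m^2) and the age-BSA
#'   correlation of -0.397.
#' @param prevalence Named binary-covariate prevalences.
#' @param protocol_mix Fraction of patients dosed by genotype.
#' @param missing_npt0 Fraction of patients with missing baseline NPT.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 99,
                        maf = c(cyp2c9_star3 = 0.056,
                                vkorc1_star1 = 0.096,
                                cyp4f2_star3 = 0.278),
                        continuous = list(
                          age = c(64.5, 15.2, 20, 95),
                          weight = c(68.4, 12.4, 40, 120),
                          height = c(163.6, 8.2, 140, 190),
                          ast = c(29.2, 16.3, 8, 150),
                          alt = c(27.2, 17.5, 5, 150),
                          clcr = c(73.3, 36.6, 10, 220),
                          npt0 = c(118.2, 22.1, 60, 200),
                          inr_base = c(1.05, 0.10, 0.8, 1.4)),
                        latent_cor = c(weight = -0.358, height = -0.372,
                                       clcr = -0.568, wt_ht = 0.62),
                        prevalence = c(female = 39 / 99,
                                       diabetes = 19 / 99,
                                       hypertension = 66 / 99,
                                       hepatic_disease = 10 / 99,
                                       ckd = 16 / 99, chf = 0.08,
                                       alcohol = 28 / 99,
                                       smoking = 20 / 99,
                                       dvt = 25 / 99, af = 54 / 99),
                        protocol_mix = 77 / 99,
                        missing_npt0 = 3 / 99) {
  stopifnot(n_patients >= 1, all(maf >= 0), all(maf <= 1),
            all(prevalence >= 0), all(prevalence <= 1),
            protocol_mix >= 0, protocol_mix <= 1,
            missing_npt0 >= 0, missing_npt0 < 1)
  structure(list(n_patients = as.integer(n_patients), maf = maf,
                 continuous = continuous, latent_cor = latent_cor,
                 prevalence = prevalence, protocol_mix = protocol_mix,
                 missing_npt0 = missing_npt0),
            class = "cohort_spec")
}

#' Sparse sampling design of the initiation study
#'
#' Visit anchors at days 1-3 (drug sampling only), day 4 and weeks 1-12,
#' with per-type target counts: INR 8-13 points (mean 11.1, of which 5 are
#' pre-treatment), Cp(S) 1-12 points (mean 9.2), NPT 4-12 points (mean
#' 10.2); draw times get a +/- 6 h uniform jitter.
#'
#' @param anchors Candidate post-dose sampling times (h).
#' @param inr_pre_n Number of pre-treatment INR measurements (at t = 0).
#' @param inr_core First four anchors are always sampled for INR.
#' @param inr_extra_p Inclusion probability of each later INR anchor.
#' @param cp_mean,cp_sd,cp_range Count distribution for Cp samples.
#' @param npt_mean,npt_sd,npt_range Count distribution for NPT samples.
#' @param jitter_h Half-width of the uniform time jitter (h).
#' @param horizon_h Follow-up horizon (h), 3 months.
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(anchors = c(24, 48, 72, 96, 168, 336, 504, 672,
                                        1008, 1344, 1680, 2016),
                            inr_pre_n = 5,
                            inr_core = c(96, 168, 336, 672),
                            inr_extra_p = 0.525,
                            cp_mean = 9.2, cp_sd = 1.3, cp_range = c(5, 12),
                            npt_mean = 10.2, npt_sd = 1.3,
                            npt_range = c(4, 12),
                            jitter_h = 6, horizon_h = 2160) {
  structure(list(anchors = anchors, inr_pre_n = inr_pre_n,
                 inr_core = inr_core,
                 inr_extra = c(1008, 1344, 1680, 2016),
                 inr_extra_p = inr_extra_p,
                 cp_mean = cp_mean, cp_sd = cp_sd, cp_range = cp_range,
                 npt_mean = npt_mean, npt_sd = npt_sd,
                 npt_range = npt_range, jitter_h = jitter_h,
                 horizon_h = horizon_h),
            class = "sampling_design")
}

# truncated-normal quantile transform used by the Gaussian copula
qtnorm <- function(p, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + p * (pu - pl), mean, sd)
}

#' Body surface area by the Du Bois formula
#'
#' @param weight kg
#' @param height cm
#' @return BSA in m^2.
#' @export
bsa_dubois <- function(weight, height) {
  0.007184 * weight^0.425 * height^0.725
}

#' Draw patient covariates and genotypes
#'
#' Genotypes are drawn per locus under Hardy-Weinberg proportions at the
#' specified minor-allele frequencies; continuous covariates come from
#' truncated normals coupled through a Gaussian copula that reproduces the
#' reported negative correlations of age with weight, BSA and CLcr; BSA is
#' computed from height and weight by the Du Bois formula.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with one row per patient.
#' @export
sample_covariates <- function(spec) {
  n <- spec$n_patients
  # latent Gaussian: (age, weight, height, clcr), others independent
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- spec$latent_cor[["weight"]]
  R[1, 3] <- R[3, 1] <- spec$latent_cor[["height"]]
  R[1, 4] <- R[4, 1] <- spec$latent_cor[["clcr"]]
  R[2, 3] <- R[3, 2] <- spec$latent_cor[["wt_ht"]]
  ev <- eigen(R, symmetric = TRUE)
  if (any(ev$values <= 0)) stop("infeasible latent correlation matrix")
  L <- ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors)
  Z <- matrix(stats::rnorm(n * 4), n, 4) %*% L
  U <- stats::pnorm(Z)
  cc <- spec$continuous
  draw <- function(u, nm) qtnorm(u, cc[[nm]][1], cc[[nm]][2],
                                 cc[[nm]][3], cc[[nm]][4])
  age <- draw(U[, 1], "age")
  weight <- draw(U[, 2], "weight")
  height <- draw(U[, 3], "height")
  clcr <- draw(U[, 4], "clcr")
  ind <- function(nm) draw(stats::runif(n), nm)
  ast <- ind("ast"); alt <- ind("alt")
  npt0 <- ind("npt0"); inr_base <- ind("inr_base")
  geno <- function(maf) stats::rbinom(n, 2, maf)
  cyp2c9 <- geno(spec$maf[["cyp2c9_star3"]])
  vkorc1 <- geno(spec$maf[["vkorc1_star1"]])
  cyp4f2 <- geno(spec$maf[["cyp4f2_star3"]])
  bin <- function(nm) stats::rbinom(n, 1, spec$prevalence[[nm]])
  data.frame(
    patient_id = seq_len(n),
    age = age, sex = bin("female"), weight = weight, height = height,
    bsa = bsa_dubois(weight, height),
    bmi = weight / (height / 100)^2,
    ast = ast, alt = alt, clcr = clcr,
    npt0 = npt0, inr_base = inr_base,
    cyp2c9_star3 = cyp2c9, vkorc1_star1 = vkorc1,
    cyp4f2_star3 = cyp4f2, cyp4f2_carrier = as.integer(cyp4f2 > 0),
    diabetes = bin("diabetes"), hypertension = bin("hypertension"),
    hepatic_disease = bin("hepatic_disease"), ckd = bin("ckd"),
    chf = bin("chf"), alcohol = bin("alcohol"), smoking = bin("smoking"),
    dvt = bin("dvt"), af = bin("af"),
    protocol = ifelse(stats::runif(n) < spec$protocol_mix,
                      "genotype", "standard"))
}

#' Draw individual structural parameters from a population model set
#'
#' Individual parameter = covariate-model typical value x `exp(eta)` with
#' `eta ~ N(0, omega^2)` independently for CL(S), IC50, Kout and lambda.
#'
#' @param covdf Covariate data frame from [sample_covariates()].
#' @param pk,npt,inr [population_model()] objects for the three stages
#'   (defaults: [reference_popmodel()]).
#' @return Data frame of true individual parameters and their etas.
#' @export
sample_individual_params <- function(covdf,
                                     pk = reference_popmodel("pk"),
                                     npt = reference_popmodel("npt"),
                                     inr = reference_popmodel("inr")) {
  n <- nrow(covdf)
  tv_cl <- apply_covariate_model(pk, covdf)$cl
  tvn <- apply_covariate_model(npt, covdf)
  tv_lam <- apply_covariate_model(inr, covdf)$lam
  eta <- function(om) if (om > 0) stats::rnorm(n, 0, om) else numeric(n)
  e_cl <- eta(pk$omega[["cl"]])
  e_ic50 <- eta(npt$omega[["ic50"]])
  e_kout <- eta(npt$omega[["kout"]])
  e_lam <- eta(inr$omega[["lam"]])
  data.frame(patient_id = covdf$patient_id,
             cl = tv_cl * exp(e_cl),
             ic50 = tvn$ic50 * exp(e_ic50),
             kout = tvn$kout * exp(e_kout),
             lam = tv_lam * exp(e_lam),
             npt0 = covdf$npt0, inr_base = covdf$inr_base,
             eta_cl = e_cl, eta_ic50 = e_ic50, eta_kout = e_kout,
             eta_lam = e_lam)
}

# predicted maintenance dose (mg/day); the genotype-guided table is a
# calibrated stand-in targeting the reported group-mean starting doses
predicted_maintenance <- function(protocol, vkorc1_star1, cyp2c9_star3) {
  ifelse(protocol == "standard", 5.0,
         round((6.13 * 0.65^(2 - vkorc1_star1) * 0.6^cyp2c9_star3) / 0.25)
         * 0.25)
}

#' Assign a dosing regimen with loading doses and INR-driven titration
#'
#' Three loading days at 1.5x the predicted maintenance dose (genotype-
#' guided table or the 5 mg/day standard protocol), daily dosing
#' thereafter, and dose titration at the day-4 and week-1/2/4 visits
#' driven by the simulated INR: +0.5 mg/day below the 2-3 target range,
#' -0.5 mg/day above it, -1 mg/day at INR >= 4 (minimum 0.5 mg/day).
#'
#' @param params A [structural_params()] with the patient's true values
#'   (used to simulate the INR seen at titration visits).
#' @param protocol `"genotype"` or `"standard"`.
#' @param vkorc1_star1,cyp2c9_star3 Allele counts for the dose table.
#' @param days Treatment duration in days.
#' @param titration_times Visit times (h) at which the dose is adjusted.
#' @param step Titration step (mg/day).
#' @param grid_h Simulation grid step (h).
#' @return A [dose_regimen()] of daily doses.
#' @export
assign_regimen <- function(params, protocol = c("genotype", "standard"),
                           vkorc1_star1 = 0, cyp2c9_star3 = 0, days = 90,
                           titration_times = c(96, 168, 336, 672),
                           step = 0.5, grid_h = 1) {
  protocol <- match.arg(protocol)
  maint <- predicted_maintenance(protocol, vkorc1_star1, cyp2c9_star3)
  loading <- round((1.5 * maint) / 0.25) * 0.25
  dose <- c(rep(loading, 3), rep(maint, days - 3))
  dose_t <- (seq_len(days) - 1) * 24
  sim_inr_at <- function(tt) {
    grid <- seq(0, tt, by = grid_h)
    amt <- params$f_bio * params$s_fraction * dose
    cp <- cpp_cp_profile(grid, dose_t, amt, params$cl_s, params$vd,
                         params$ka)
    npt <- cpp_npt_grid(cp, grid_h, params$npt0, params$ic50, params$kout,
                        params$imax)
    frac <- min(max((params$npt0 - npt[length(npt)]) / params$npt0, 0), 1)
    params$inr_base + params$inr_max * frac^params$lam
  }
  for (tt in sort(titration_times)) {
    inr <- sim_inr_at(tt)
    later <- dose_t > tt
    if (inr >= 4) {
      dose[later] <- pmax(dose[later] - 2 * step, 0.5)
    } else if (inr > 3) {
      dose[later] <- pmax(dose[later] - step, 0.5)
    } else if (inr < 2) {
      dose[later] <- dose[later] + step
    }
  }
  dose_regimen(dose_t, dose)
}

# draw per-patient sampling times for one cohort
sample_design_times <- function(design, n) {
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  jit <- function(tt) clamp(tt + stats::runif(length(tt), -design$jitter_h,
                                              design$jitter_h),
                            1, design$horizon_h)
  lapply(seq_len(n), function(i) {
    n_cp <- clamp(round(stats::rnorm(1, design$cp_mean, design$cp_sd)),
                  design$cp_range[1], design$cp_range[2])
    n_npt <- clamp(round(stats::rnorm(1, design$npt_mean, design$npt_sd)),
                   design$npt_range[1], design$npt_range[2])
    cp_t <- jit(sort(sample(design$anchors, n_cp)))
    npt_t <- jit(sort(sample(design$anchors, n_npt)))
    inr_post <- design$inr_core
    extra <- design$inr_extra[stats::runif(length(design$inr_extra)) <
                                design$inr_extra_p]
    inr_t <- c(rep(0, design$inr_pre_n), jit(sort(c(inr_post, extra))))
    list(cp = cp_t, npt = npt_t, inr = inr_t)
  })
}

#' Add residual measurement error to noise-free observations
#'
#' Cp(S) and NPT get additive Gaussian noise (floored at zero); INR gets
#' relative (proportional) Gaussian noise.
#'
#' @param true_obs Data frame with columns `patient_id`, `time_h`,
#'   `obs_type` (`"CP"`, `"NPT"`, `"INR"`) and `truth`.
#' @param sigma_cp,sigma_npt Additive residual SDs (ug/mL).
#' @param sigma_inr Relative residual SD (fraction).
#' @return The input with a `value` column of noisy observations.
#' @export
generate_observations <- function(true_obs, sigma_cp = 0.0697,
                                  sigma_npt = 12.2, sigma_inr = 0.247) {
  stopifnot(all(true_obs$obs_type %in% c("CP", "NPT", "INR")))
  n <- nrow(true_obs)
  eps <- stats::rnorm(n)
  v <- true_obs$truth
  type <- true_obs$obs_type
  value <- ifelse(type == "CP", pmax(v + sigma_cp * eps, 0),
           ifelse(type == "NPT", pmax(v + sigma_npt * eps, 0),
                  v * (1 + sigma_inr * eps)))
  true_obs$value <- value
  true_obs
}

#' Simulate a complete synthetic warfarin-initiation cohort
#'
#' Draws covariates and genotypes, true individual PK-PD parameters,
#' protocol-specific dosing regimens with INR-driven titration, sparse
#' sampling times, and noisy observations, mirroring the design of the
#' 99-patient initiation study.  A fraction of patients (3/99 by default)
#' is emitted with missing baseline NPT to exercise the exclusion rules.
#'
#' @param spec A [cohort_spec()].
#' @param design A [sampling_design()].
#' @param seed Integer seed; all randomness flows from it.
#' @param pk,npt,inr Generating [population_model()]s.
#' @param grid_h Simulation grid step (h).
#' @return An object of class `warf_cohort`: a list with data frames
#'   `dosing`, `observations`, `covariates` and `truth`.
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            design = sampling_design(), seed = 1,
                            pk = reference_popmodel("pk"),
                            npt = reference_popmodel("npt"),
                            inr = reference_popmodel("inr"),
                            grid_h = 1) {
  set.seed(as.integer(seed))
  covdf <- sample_covariates(spec)
  truth <- sample_individual_params(covdf, pk, npt, inr)
  times <- sample_design_times(design, spec$n_patients)
  dosing <- vector("list", spec$n_patients)
  tobs <- vector("list", spec$n_patients)
  ge4 <- logical(spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    p <- structural_params(cl_s = truth$cl[i], ic50 = truth$ic50[i],
                           kout = truth$kout[i], npt0 = truth$npt0[i],
                           lam = truth$lam[i],
                           inr_base = truth$inr_base[i],
                           vd = pk$constants$vd, ka = pk$constants$ka,
                           f_bio = pk$constants$f_bio,
                           inr_max = inr$constants$inr_max,
                           s_fraction = pk$constants$s_fraction)
    reg <- assign_regimen(p, covdf$protocol[i],
                          vkorc1_star1 = covdf$vkorc1_star1[i],
                          cyp2c9_star3 = covdf$cyp2c9_star3[i],
                          days = ceiling(design$horizon_h / 24),
                          grid_h = grid_h)
    dosing[[i]] <- data.frame(patient_id = i, time_h = reg$time,
                              dose_mg = reg$dose_mg)
    grid <- seq(0, design$horizon_h, by = grid_h)
    amt <- p$f_bio * p$s_fraction * reg$dose_mg
    cp_g <- cpp_cp_profile(grid, reg$time, amt, p$cl_s, p$vd, p$ka)
    npt_g <- cpp_npt_grid(cp_g, grid_h, p$npt0, p$ic50, p$kout, p$imax)
    inr_g <- inr_from_npt(npt_g, p)
    ge4[i] <- any(inr_g >= 4)
    ti <- times[[i]]
    interp <- function(tt, yy) stats::approx(grid, yy, xout = tt)$y
    tobs[[i]] <- rbind(
      data.frame(patient_id = i, time_h = ti$cp, obs_type = "CP",
                 truth = cpp_cp_profile(ti$cp, reg$time, amt, p$cl_s,
                                        p$vd, p$ka)),
      data.frame(patient_id = i, time_h = ti$npt, obs_type = "NPT",
                 truth = interp(ti$npt, npt_g)),
      data.frame(patient_id = i, time_h = ti$inr, obs_type = "INR",
                 truth = ifelse(ti$inr <= 0, p$inr_base,
                                interp(pmax(ti$inr, 0), inr_g))))
  }
  obs <- generate_observations(do.call(rbind, tobs),
                               sigma_cp = pk$sigma, sigma_npt = npt$sigma,
                               sigma_inr = inr$sigma)
  truth$true_inr_ge4 <- ge4
  # measured baseline INR: mean of the pre-treatment draws
  pre <- obs[obs$obs_type == "INR" & obs$time_h <= 0, ]
  base_mean <- tapply(pre$value, pre$patient_id, mean)
  covdf$inr_base <- as.numeric(base_mean[as.character(covdf$patient_id)])
  n_miss <- round(spec$missing_npt0 * spec$n_patients)
  if (n_miss > 0) {
    miss <- sample(covdf$patient_id, n_miss)
    covdf$npt0[covdf$patient_id %in% miss] <- NA_real_
  }
  structure(list(dosing = do.call(rbind, dosing),
                 observations = obs[, c("patient_id", "time_h", "obs_type",
                                        "value")],
                 covariates = covdf, truth = truth, spec = spec,
                 design = design, seed = seed),
            class = "warf_cohort")
}

#' @export
print.warf_cohort <- function(x, ...) {
  nobs <- table(x$observations$obs_type)
  cat("Synthetic warfarin cohort:", nrow(x$covariates), "patients\n")
  cat("  observations:", paste(names(nobs), nobs, sep = " = ",
                               collapse = ", "), "\n")
  cat("  dose events:", nrow(x$dosing), "\n")
  cat("  missing baseline NPT:", sum(is.na(x$covariates$npt0)), "\n")
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Emits `dosing.csv`, `observations.csv`, `covariates.csv` and (when
#' present) `truth.csv` in comma-delimited UTF-8 with one header row.
#'
#' @param cohort A `warf_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$dosing, file.path(dir, "dosing.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$observations, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$truth))
    utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  invisible(dir)
}
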