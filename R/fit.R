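# Nonlinear mixed-effects estimation of the three sequential stages by
# per-subject Laplace approximation of the marginal likelihood (FOCE-type;
# with eta-variance interaction for the relative-error INR stage), quasi-
# Newton outer optimisation on log-transformed parameters, and empirical
# Bayes individual estimates.

#' Control settings for the stage fitters
#'
#' @param n_starts Number of multistart optimisations (deterministically
#'   jittered starting values guard against local minima).
#' @param jitter Log-scale shift applied to the extra starts.
#' @param grid_h Integration grid step (h) for the turnover model.
#' @param se Compute Hessian-based standard errors of the estimates.
#' @param iter_max Outer optimiser iteration cap.
#' @param rel_tol Outer optimiser relative convergence tolerance.
#' @return A list of control settings.
#' @export
default_fit_control <- function(n_starts = 3, jitter = 0.3, grid_h = 1,
                                se = FALSE, iter_max = 500,
                                rel_tol = 1e-9) {
  list(n_starts = n_starts, jitter = jitter, grid_h = grid_h, se = se,
       iter_max = iter_max, rel_tol = rel_tol)
}

# --- stage data assembly ----------------------------------------------------

flatten_by_patient <- function(df, ids, cols) {
  sp <- split(df[cols], factor(df$patient_id, levels = ids))
  ptr <- cumsum(c(0L, vapply(sp, nrow, integer(1))))
  list(data = do.call(rbind, sp), ptr = as.integer(ptr))
}

pk_stage_data <- function(cohort, s_fraction = 0.5, f_bio = 1) {
  obs <- cohort$observations
  cp <- obs[obs$obs_type == "CP", ]
  ids <- intersect(cohort$covariates$patient_id, unique(cp$patient_id))
  excluded <- setdiff(cohort$covariates$patient_id, ids)
  dose <- cohort$dosing[cohort$dosing$patient_id %in% ids, ]
  dose <- dose[order(dose$patient_id, dose$time_h), ]
  cp <- cp[cp$patient_id %in% ids, ]
  cp <- cp[order(match(cp$patient_id, ids), cp$time_h), ]
  fd <- flatten_by_patient(dose, ids, c("time_h", "dose_mg"))
  fo <- flatten_by_patient(cp, ids, c("time_h", "value"))
  covdf <- cohort$covariates[match(ids, cohort$covariates$patient_id), ]
  list(ids = ids, excluded = excluded, covdf = covdf,
       dose_t = fd$data$time_h,
       dose_amt = f_bio * s_fraction * fd$data$dose_mg, dptr = fd$ptr,
       obs_t = fo$data$time_h, obs_y = fo$data$value, optr = fo$ptr,
       obs_id = rep(ids, diff(fo$ptr)))
}

# per-patient Cp grids under individual clearances (cl named by patient id)
cp_grids <- function(cohort, ids, cl, horizon, grid_h, s_fraction = 0.5,
                     f_bio = 1, vd = 13.8, ka = 2) {
  grids <- lapply(seq_along(ids), function(k) {
    id <- ids[k]
    d <- cohort$dosing[cohort$dosing$patient_id == id, ]
    d <- d[order(d$time_h), ]
    grid <- seq(0, horizon[k], by = grid_h)
    cpp_cp_profile(grid, d$time_h, f_bio * s_fraction * d$dose_mg,
                   cl[[as.character(id)]], vd, ka)
  })
  ptr <- cumsum(c(0L, vapply(grids, length, integer(1))))
  list(cp = unlist(grids), gptr = as.integer(ptr))
}

npt_stage_data <- function(cohort, cl_ind, grid_h = 1, s_fraction = 0.5,
                           f_bio = 1, vd = 13.8, ka = 2) {
  obs <- cohort$observations
  np <- obs[obs$obs_type == "NPT", ]
  cov <- cohort$covariates
  ok_npt0 <- cov$patient_id[!is.na(cov$npt0)]
  ids <- intersect(ok_npt0, unique(np$patient_id))
  excluded <- setdiff(cov$patient_id, ids)
  np <- np[np$patient_id %in% ids, ]
  np <- np[order(match(np$patient_id, ids), np$time_h), ]
  fo <- flatten_by_patient(np, ids, c("time_h", "value"))
  no <- diff(fo$ptr)
  horizon <- vapply(split(fo$data$time_h, rep(seq_along(ids), no)), max,
                    numeric(1)) + grid_h
  g <- cp_grids(cohort, ids, cl_ind, horizon, grid_h, s_fraction, f_bio,
                vd, ka)
  # grid-cell index local to each patient's Cp grid (C++ indexes per patient)
  ng <- diff(g$gptr)
  idx <- pmin(floor(fo$data$time_h / grid_h), rep(ng, no) - 2)
  frac <- fo$data$time_h / grid_h - idx
  covdf <- cov[match(ids, cov$patient_id), ]
  list(ids = ids, excluded = excluded, covdf = covdf,
       cp = g$cp, gptr = g$gptr, grid_h = grid_h,
       obs_idx = as.integer(idx),
       obs_frac = frac, obs_y = fo$data$value, optr = fo$ptr,
       obs_t = fo$data$time_h, obs_id = rep(ids, no),
       npt0 = covdf$npt0)
}

inr_stage_data <- function(cohort, ind_params, grid_h = 1,
                           s_fraction = 0.5, f_bio = 1, vd = 13.8,
                           ka = 2, imax = 1) {
  obs <- cohort$observations
  inr <- obs[obs$obs_type == "INR" & obs$time_h > 0, ]
  pre <- obs[obs$obs_type == "INR" & obs$time_h <= 0, ]
  cov <- cohort$covariates
  ok_npt0 <- cov$patient_id[!is.na(cov$npt0)]
  ids <- intersect(ok_npt0, unique(inr$patient_id))
  ids <- intersect(ids, ind_params$patient_id)
  excluded <- setdiff(cov$patient_id, ids)
  inr <- inr[inr$patient_id %in% ids, ]
  inr <- inr[order(match(inr$patient_id, ids), inr$time_h), ]
  fo <- flatten_by_patient(inr, ids, c("time_h", "value"))
  no <- diff(fo$ptr)
  covdf <- cov[match(ids, cov$patient_id), ]
  # baseline INR: mean of pre-treatment measurements, falling back on the
  # covariate value when none were taken
  base <- vapply(ids, function(id) {
    v <- pre$value[pre$patient_id == id]
    if (length(v)) mean(v) else covdf$inr_base[match(id, covdf$patient_id)]
  }, numeric(1))
  # individual NPT predictions at the INR observation times
  horizon <- vapply(split(fo$data$time_h, rep(seq_along(ids), no)), max,
                    numeric(1)) + grid_h
  ip <- ind_params[match(ids, ind_params$patient_id), ]
  cl <- stats::setNames(ip$cl, ip$patient_id)
  g <- cp_grids(cohort, ids, cl, horizon, grid_h, s_fraction, f_bio, vd,
                ka)
  npt_pred <- numeric(length(fo$data$time_h))
  for (k in seq_along(ids)) {
    cpg <- g$cp[(g$gptr[k] + 1):g$gptr[k + 1]]
    ng <- cpp_npt_grid(cpg, grid_h, covdf$npt0[k], ip$ic50[k], ip$kout[k],
                       imax)
    tt <- fo$data$time_h[(fo$ptr[k] + 1):fo$ptr[k + 1]]
    grid <- seq(0, by = grid_h, length.out = length(cpg))
    npt_pred[(fo$ptr[k] + 1):fo$ptr[k + 1]] <-
      stats::approx(grid, ng, xout = tt)$y
  }
  list(ids = ids, excluded = excluded, covdf = covdf,
       npt_pred = npt_pred, obs_y = fo$data$value, optr = fo$ptr,
       obs_t = fo$data$time_h, obs_id = rep(ids, no),
       npt0 = covdf$npt0, inr_base = base)
}

# --- objective factories ----------------------------------------------------

make_objective <- function(stage, sd, model, control) {
  n <- length(sd$ids)
  env <- new.env(parent = emptyenv())
  env$eta <- if (stage == "npt") matrix(0, n, 2) else rep(0, n)
  cst <- model$constants
  obj <- function(par, want_pred = FALSE) {
    m <- unpack_model(par, model)
    tv <- apply_covariate_model(m, sd$covdf)
    res <- switch(stage,
      pk = cpp_pk_laplace(sd$dose_t, sd$dose_amt, sd$dptr, sd$obs_t,
                          sd$obs_y, sd$optr, tv$cl, cst$vd, cst$ka,
                          m$omega[["cl"]], m$sigma, env$eta, want_pred),
      npt = cpp_npt_laplace(sd$cp, sd$gptr, sd$grid_h, sd$obs_idx,
                            sd$obs_frac, sd$obs_y, sd$optr, sd$npt0,
                            tv$ic50, tv$kout, cst$imax,
                            m$omega[["ic50"]], m$omega[["kout"]],
                            m$sigma, env$eta, want_pred),
      inr = cpp_inr_laplace(sd$npt_pred, sd$obs_y, sd$optr, sd$npt0,
                            sd$inr_base, tv$lam, cst$inr_max,
                            m$omega[["lam"]], m$sigma, env$eta,
                            want_pred))
    env$eta <- res$eta
    if (want_pred) res else res$ofv
  }
  list(obj = obj, env = env)
}

# --- generic stage fitter ---------------------------------------------------

fit_stage_impl <- function(stage, cohort, model, sd, control) {
  fac <- make_objective(stage, sd, model, control)
  start0 <- pack_model(model)
  shifts <- c(0, control$jitter, -control$jitter)[seq_len(control$n_starts)]
  best <- NULL
  convs <- list()
  for (s in shifts) {
    fac$env$eta[] <- 0
    st <- start0 + s
    ans <- tryCatch(
      stats::nlminb(st, fac$obj,
                    control = list(iter.max = control$iter_max,
                                   eval.max = 4 * control$iter_max,
                                   rel.tol = control$rel_tol %||% 1e-9)),
      error = function(e) NULL)
    if (is.null(ans) || !is.finite(ans$objective)) next
    convs[[length(convs) + 1]] <- ans$convergence
    if (is.null(best) || ans$objective < best$objective) best <- ans
  }
  if (is.null(best))
    stop("stage '", stage, "' fit failed to produce a finite objective")
  # final pass at the optimum for EBEs and predictions
  fac$env$eta[] <- 0
  final <- fac$obj(best$par, want_pred = TRUE)
  fitted_model <- unpack_model(best$par, model)
  tv <- apply_covariate_model(fitted_model, sd$covdf)
  eta <- final$eta
  ind <- switch(stage,
    pk = data.frame(patient_id = sd$ids, cl_typ = tv$cl,
                    eta_cl = as.numeric(eta),
                    cl = tv$cl * exp(as.numeric(eta))),
    npt = data.frame(patient_id = sd$ids, ic50_typ = tv$ic50,
                     kout_typ = tv$kout, eta_ic50 = eta[, 1],
                     eta_kout = eta[, 2],
                     ic50 = tv$ic50 * exp(eta[, 1]),
                     kout = tv$kout * exp(eta[, 2])),
    inr = data.frame(patient_id = sd$ids, lam_typ = tv$lam,
                     eta_lam = as.numeric(eta),
                     lam = tv$lam * exp(as.numeric(eta))))
  # expected SD of (obs - population prediction): residual error plus the
  # FO-linearised inter-individual contribution grad * omega
  res_var <- if (fitted_model$error == "additive") fitted_model$sigma^2
             else (fitted_model$sigma * final$pred_pop)^2
  iiv_var <- 0
  g <- final$pred_grad
  if (stage == "pk") {
    iiv_var <- (g * fitted_model$omega[["cl"]])^2
  } else if (stage == "npt") {
    iiv_var <- (g[, 1] * fitted_model$omega[["ic50"]])^2 +
      (g[, 2] * fitted_model$omega[["kout"]])^2
  } else {
    iiv_var <- (g * fitted_model$omega[["lam"]])^2
  }
  pred <- data.frame(patient_id = sd$obs_id, time_h = sd$obs_t,
                     obs = sd$obs_y, pred_pop = final$pred_pop,
                     pred_ind = final$pred_ind,
                     wres = (sd$obs_y - final$pred_pop) /
                       sqrt(res_var + iiv_var))
  se <- NULL
  if (isTRUE(control$se)) {
    # -2LL Hessian: vcov is 2 * H^-1; delta method back to natural scale
    # for log-parameterised entries (theta, omega, sigma, cat multipliers)
    H <- tryCatch(stats::optimHess(best$par, fac$obj), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H / 2), error = function(e) NULL)
    if (!is.null(V)) {
      se_t <- sqrt(pmax(diag(V), 0))
      logged <- rep(TRUE, length(start0))
      is_beta <- grepl("^beta\\.", names(start0))
      if (any(is_beta)) {
        forms <- vapply(fitted_model$covariates, function(tm) tm$form,
                        character(1))
        logged[is_beta] <- forms == "cat"
      }
      se <- ifelse(logged, se_t * exp(best$par), se_t)
      names(se) <- names(start0)
    }
  }
  structure(list(stage = stage, model = fitted_model, ofv = best$objective,
                 theta = fitted_model$theta,
                 covariates = fitted_model$covariates,
                 omega = fitted_model$omega, sigma = fitted_model$sigma,
                 ind_params = ind, pred = pred, se = se,
                 excluded = sd$excluded, ids = sd$ids,
                 n_patients = length(sd$ids), n_obs = length(sd$obs_y),
                 convergence = best$convergence, message = best$message,
                 par = best$par, control = control),
            class = "popfit")
}

#' Fit the stage-1 population PK model (dose to Cp(S))
#'
#' One-compartment model with first-order absorption and elimination,
#' log-normal inter-individual variability on CL(S), additive residual
#' error; approximate marginal likelihood by per-subject Laplace
#' expansion about the conditional mode, maximised by quasi-Newton with
#' log-transformed parameters and multistart.
#'
#' @param cohort A `warf_cohort` (or any list with `dosing`,
#'   `observations`, `covariates` data frames).
#' @param model A [population_model()] for the `"pk"` stage; its values
#'   serve as starting estimates.
#' @param control See `default_fit_control()`: number of starts, start
#'   jitter, grid step, whether to compute Hessian-based SEs.
#' @return An object of class `popfit`.
#' @export
fit_stage_pk <- function(cohort, model = reference_popmodel("pk"),
                         control = default_fit_control()) {
  stopifnot(model$stage == "pk")
  sd <- pk_stage_data(cohort, model$constants$s_fraction,
                      model$constants$f_bio)
  if (!length(sd$ids)) stop("no Cp(S) observations in the dataset")
  fit_stage_impl("pk", cohort, model, sd, control)
}

#' Individual parameters for every patient in a cohort
#'
#' Combines a fit's empirical Bayes estimates with the fitted covariate
#' model: patients in the fit keep their EBE; patients outside it (for
#' example, excluded for missing data) get the typical value (eta = 0).
#'
#' @param fit A `popfit`.
#' @param cohort The cohort the fit came from.
#' @return Data frame of individual parameter values per patient.
#' @export
individual_parameters <- function(fit, cohort) {
  cov <- cohort$covariates
  ok <- !is.na(cov$npt0)
  covq <- cov
  covq$npt0[!ok] <- stats::median(cov$npt0, na.rm = TRUE)  # placeholder only
  tv <- apply_covariate_model(fit$model, covq)
  out <- data.frame(patient_id = cov$patient_id)
  for (pn in names(tv)) out[[pn]] <- tv[[pn]]
  ix <- match(out$patient_id, fit$ind_params$patient_id)
  for (pn in names(tv)) {
    ind <- fit$ind_params[[pn]]
    hit <- !is.na(ix)
    out[[pn]][hit] <- ind[ix[hit]]
  }
  out
}

#' Fit the stage-2 indirect-response model (Cp(S) to NPT)
#'
#' Turnover model with synthesis inhibited by an Emax term in Cp(S),
#' log-normal variability on IC50 and Kout, additive residual error.
#' Individual Cp(S) prediction functions come from the stage-1 fit
#' (empirical Bayes clearances); patients with missing baseline NPT are
#' excluded.
#'
#' @param cohort A `warf_cohort`.
#' @param pk_fit The stage-1 `popfit`, or a data frame with columns
#'   `patient_id` and `cl` giving individual clearances directly.
#' @param model A [population_model()] for the `"npt"` stage.
#' @param control See [fit_stage_pk()].
#' @return An object of class `popfit`.
#' @export
fit_stage_npt <- function(cohort, pk_fit,
                          model = reference_popmodel("npt"),
                          control = default_fit_control()) {
  stopifnot(model$stage == "npt")
  ip <- if (inherits(pk_fit, "popfit"))
    individual_parameters(pk_fit, cohort) else pk_fit
  cl <- stats::setNames(ip$cl, ip$patient_id)
  sd <- npt_stage_data(cohort, cl, control$grid_h,
                       model$constants$s_fraction, model$constants$f_bio,
                       model$constants$vd, model$constants$ka)
  if (!length(sd$ids)) stop("no NPT observations available after exclusions")
  fit <- fit_stage_impl("npt", cohort, model, sd, control)
  fit$ind_params$cl <- cl[as.character(fit$ind_params$patient_id)]
  fit
}

#' Fit the stage-3 nonlinear NPT-to-INR model
#'
#' `INR = INR_base + INR_max * ((NPT0 - NPT)/NPT0)^lambda` with log-normal
#' variability on lambda and relative residual error (Laplace with the
#' error-variance interaction term).  Individual NPT predictions come from
#' the stage-2 fit; the baseline INR of each patient is the mean of the
#' pre-treatment INR measurements.
#'
#' @param cohort A `warf_cohort`.
#' @param npt_fit The stage-2 `popfit`, or a data frame with columns
#'   `patient_id`, `cl`, `ic50`, `kout`.
#' @param model A [population_model()] for the `"inr"` stage.
#' @param control See [fit_stage_pk()].
#' @return An object of class `popfit`.
#' @export
fit_stage_inr <- function(cohort, npt_fit,
                          model = reference_popmodel("inr"),
                          control = default_fit_control()) {
  stopifnot(model$stage == "inr")
  ip <- if (inherits(npt_fit, "popfit")) {
    d <- individual_parameters(npt_fit, cohort)
    cl <- npt_fit$ind_params$cl[match(d$patient_id,
                                      npt_fit$ind_params$patient_id)]
    d$cl <- cl
    d[!is.na(d$cl), c("patient_id", "cl", "ic50", "kout")]
  } else npt_fit
  sd <- inr_stage_data(cohort, ip, control$grid_h,
                       model$constants$s_fraction, model$constants$f_bio,
                       model$constants$vd, model$constants$ka,
                       model$constants$imax)
  if (!length(sd$ids)) stop("no INR observations available after exclusions")
  fit_stage_impl("inr", cohort, model, sd, control)
}

#' Fit one sequential stage by name
#'
#' Thin dispatcher over [fit_stage_pk()], [fit_stage_npt()] and
#' [fit_stage_inr()]; `upstream` is ignored for the PK stage.
#'
#' @param stage `"pk"`, `"npt"` or `"inr"`.
#' @param cohort A `warf_cohort`.
#' @param model A [population_model()] for that stage.
#' @param upstream The upstream `popfit` (or individual-parameter data
#'   frame) required by the NPT and INR stages.
#' @param control See [fit_stage_pk()].
#' @return A `popfit`.
#' @export
fit_stage <- function(stage, cohort, model, upstream = NULL,
                      control = default_fit_control()) {
  switch(stage,
         pk = fit_stage_pk(cohort, model, control),
         npt = fit_stage_npt(cohort, upstream, model, control),
         inr = fit_stage_inr(cohort, upstream, model, control),
         stop("unknown stage '", stage, "'"))
}

#' @export
print.popfit <- function(x, ...) {
  cat("Population ", toupper(x$stage), " fit: ", x$n_patients,
      " patients, ", x$n_obs, " observations\n", sep = "")
  cat("  OFV:", format(x$ofv, digits = 8), "\n")
  cat("  theta:", paste(names(x$theta), signif(x$theta, 4), sep = " = ",
                        collapse = ", "), "\n")
  for (tm in x$covariates)
    cat("  ", tm$param, " ~ ", tm$name, " (", tm$form, "): ",
        signif(tm$value, 4), "\n", sep = "")
  cat("  omega (%):", paste(names(x$omega), signif(100 * x$omega, 3),
                            sep = " = ", collapse = ", "), "\n")
  cat("  sigma:", signif(x$sigma, 4),
      if (x$model$error == "relative") "(relative)" else "(additive)", "\n")
  if (length(x$excluded))
    cat("  excluded patients:", length(x$excluded), "\n")
  invisible(x)
}

#' Objective function value of a fit
#'
#' The Laplace approximation to -2 log marginal likelihood at the optimum
#' (all 2*pi constants included); only differences between nested models
#' on the same data are interpretable.
#'
#' @param fit A `popfit`.
#' @return Scalar OFV.
#' @export
ofv <- function(fit) {
  stopifnot(inherits(fit, "popfit"))
  fit$ofv
}

#' Empirical Bayes estimates of a fit
#'
#' @param fit A `popfit`.
#' @return Data frame of per-patient etas and individual parameters.
#' @export
ebe <- function(fit) {
  stopifnot(inherits(fit, "popfit"))
  fit$ind_params
}

#' Population-weighted residuals of a fit
#'
#' `(observation - population prediction) / expected SD` under the fitted
#' residual-error model; approximately zero-mean with unit SD when the
#' model is well specified.
#'
#' @param fit A `popfit`.
#' @return Data frame with `patient_id`, `time_h`, `obs`, `pred_pop`,
#'   `pred_ind` and `wres`.
#' @export
weighted_residuals <- function(fit) {
  stopifnot(inherits(fit, "popfit"))
  fit$pred
}
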