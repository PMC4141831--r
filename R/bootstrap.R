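# Non-parametric bootstrap of population parameters and goodness-of-fit
# diagnostics (observed vs predicted tables, visual predictive check).

resample_cohort <- function(cohort, draw) {
  new_ids <- seq_along(draw)
  pick <- function(df) {
    out <- do.call(rbind, lapply(seq_along(draw), function(k) {
      rows <- df[df$patient_id == draw[k], ]
      rows$patient_id <- new_ids[k]
      rows
    }))
    rownames(out) <- NULL
    out
  }
  structure(list(dosing = pick(cohort$dosing),
                 observations = pick(cohort$observations),
                 covariates = pick(cohort$covariates),
                 truth = if (!is.null(cohort$truth)) pick(cohort$truth),
                 spec = cohort$spec, design = cohort$design),
            class = "warf_cohort")
}

boot_param_vector <- function(fit) {
  th <- stats::setNames(as.numeric(fit$theta),
                        paste0("theta.", names(fit$theta)))
  cf <- vapply(fit$covariates, function(tm) tm$value, numeric(1))
  if (length(cf))
    names(cf) <- paste0("beta.", vapply(fit$covariates, function(tm)
      paste0(tm$param, ".", tm$name), character(1)))
  om <- stats::setNames(as.numeric(fit$omega),
                        paste0("omega.", names(fit$omega)))
  c(th, cf, om, sigma = fit$sigma)
}

#' Non-parametric bootstrap of one fitted stage
#'
#' Resamples patients with replacement (cohort size preserved), refits
#' the final model of the stage on each resampled dataset starting from
#' the original point estimates, and reports the bootstrap mean and the
#' 2.5th/97.5th values of the ranked estimates for every parameter.  For
#' the NPT and INR stages, the individual upstream predictions (empirical
#' Bayes clearances, and IC50/Kout) are carried over from the original
#' sequential fit of each resampled patient; the covariate model structure
#' is held fixed.  Failed refits are excluded and reported; more than
#' `max_fail` of them aborts the run.
#'
#' @param cohort The original `warf_cohort`.
#' @param fit The fitted `popfit` whose model is bootstrapped.
#' @param upstream For `"npt"`/`"inr"` stages: the upstream `popfit` or
#'   individual-parameter data frame used in the original fit.
#' @param n_resamples Number of bootstrap datasets (the reference analysis
#'   used 1,000 for Cp(S) and INR and 100 for NPT).
#' @param seed Integer seed for the resampling draws.
#' @param control Fit control; refits use one start at the point estimates.
#' @param max_fail Maximum tolerated refit failure fraction.
#' @return An object of class `warf_bootstrap` with elements `summary`
#'   (parameter, point, mean, lower, upper), `draws`, `n_ok`, `n_fail`.
#' @export
bootstrap_fit <- function(cohort, fit, upstream = NULL, n_resamples = 200,
                          seed = 1, control = default_fit_control(),
                          max_fail = 0.2) {
  stopifnot(n_resamples >= 2)
  set.seed(as.integer(seed))
  ids <- cohort$covariates$patient_id
  stage <- fit$stage
  control <- search_control(control)
  up_ip <- NULL
  if (stage != "pk") {
    stopifnot(!is.null(upstream))
    up_ip <- if (inherits(upstream, "popfit")) {
      d <- individual_parameters(upstream, cohort)
      if (stage == "inr") {
        d$cl <- upstream$ind_params$cl[match(d$patient_id,
                                             upstream$ind_params$patient_id)]
        d <- d[!is.na(d$cl), ]
      }
      d
    } else upstream
  }
  draws <- vector("list", n_resamples)
  n_fail <- 0
  for (b in seq_len(n_resamples)) {
    draw <- sample(ids, length(ids), replace = TRUE)
    bco <- resample_cohort(cohort, draw)
    bup <- NULL
    if (!is.null(up_ip)) {
      bup <- up_ip[match(draw, up_ip$patient_id), ]
      bup$patient_id <- seq_along(draw)
      bup <- bup[!is.na(bup[[2]]), ]
    }
    bf <- tryCatch(fit_stage(stage, bco, fit$model, bup, control),
                   error = function(e) NULL)
    if (is.null(bf) || !is.finite(bf$ofv)) {
      n_fail <- n_fail + 1
      next
    }
    draws[[b]] <- boot_param_vector(bf)
  }
  draws <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  if (n_fail > max_fail * n_resamples)
    stop("bootstrap aborted: ", n_fail, "/", n_resamples, " refits failed")
  point <- boot_param_vector(fit)
  # footnote-style rank percentiles: the 2.5th and 97.5th ranked values
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), type = 1,
              names = FALSE)
  summary <- data.frame(parameter = colnames(draws),
                        point = as.numeric(point[colnames(draws)]),
                        mean = colMeans(draws),
                        lower = qs[1, ], upper = qs[2, ],
                        row.names = NULL)
  structure(list(summary = summary, draws = draws,
                 n_ok = nrow(draws), n_fail = n_fail, stage = stage),
            class = "warf_bootstrap")
}

#' @export
print.warf_bootstrap <- function(x, ...) {
  cat("Bootstrap of", toupper(x$stage), "stage:", x$n_ok,
      "successful refits", paste0("(", x$n_fail, " failed)"), "\n")
  print(transform(x$summary,
                  point = signif(point, 4), mean = signif(mean, 4),
                  lower = signif(lower, 4), upper = signif(upper, 4)))
  invisible(x)
}

#' Goodness-of-fit tables for a fitted stage
#'
#' Pairs every observation with its population and individual predictions
#' and weighted residual, and reports the identity-line regression slopes
#' (observed on predicted) plus the trend slope of weighted residuals on
#' population predictions.
#'
#' @param fit A `popfit`.
#' @return List with `table` (per-observation data frame) and `slopes`
#'   (`obs_vs_pred_pop`, `obs_vs_pred_ind`, `wres_trend`).
#' @export
gof_tables <- function(fit) {
  stopifnot(inherits(fit, "popfit"))
  tab <- fit$pred
  slopes <- c(
    obs_vs_pred_pop = unname(stats::coef(stats::lm(obs ~ pred_pop,
                                                   data = tab))[2]),
    obs_vs_pred_ind = unname(stats::coef(stats::lm(obs ~ pred_ind,
                                                   data = tab))[2]),
    wres_trend = unname(stats::coef(stats::lm(wres ~ pred_pop,
                                              data = tab))[2]))
  list(table = tab, slopes = slopes)
}

#' Visual predictive check of a fitted stage
#'
#' Simulates `n_sim` replicate datasets from the fitted model at the
#' observed design (same patients, doses and sampling times; new
#' inter-individual and residual draws), pools them per time bin, and
#' returns the simulated 5th/50th/95th percentile bands next to the
#' observed percentiles.
#'
#' @param cohort The `warf_cohort` the fit came from.
#' @param fit A `popfit`.
#' @param upstream Upstream fit or frame (NPT/INR stages), as used in the
#'   original fit.
#' @param n_sim Number of simulation replicates.
#' @param seed Integer seed.
#' @param n_bins Number of time bins (quantile-spaced).
#' @return Data frame with one row per bin: `t_mid`, `n_obs`, observed and
#'   simulated 5/50/95th percentiles.
#' @export
vpc <- function(cohort, fit, upstream = NULL, n_sim = 100, seed = 1,
                n_bins = 8) {
  stopifnot(inherits(fit, "popfit"), n_sim >= 1)
  set.seed(as.integer(seed))
  stage <- fit$stage
  control <- fit$control
  sdd <- rebuild_stage_data(cohort, fit, upstream)
  n <- length(sdd$ids)
  tv <- apply_covariate_model(fit$model, sdd$covdf)
  sims <- matrix(NA_real_, length(sdd$obs_y), n_sim)
  for (s in seq_len(n_sim)) {
    if (stage == "pk") {
      eta <- stats::rnorm(n, 0, fit$omega[["cl"]])
      cl <- tv$cl * exp(eta)
      f <- numeric(length(sdd$obs_y))
      for (k in seq_len(n)) {
        jj <- (sdd$optr[k] + 1):sdd$optr[k + 1]
        dj <- (sdd$dptr[k] + 1):sdd$dptr[k + 1]
        f[jj] <- cpp_cp_profile(sdd$obs_t[jj], sdd$dose_t[dj],
                                sdd$dose_amt[dj], cl[k],
                                fit$model$constants$vd,
                                fit$model$constants$ka)
      }
      sims[, s] <- pmax(f + stats::rnorm(length(f), 0, fit$sigma), 0)
    } else if (stage == "npt") {
      e1 <- stats::rnorm(n, 0, fit$omega[["ic50"]])
      e2 <- stats::rnorm(n, 0, fit$omega[["kout"]])
      f <- numeric(length(sdd$obs_y))
      for (k in seq_len(n)) {
        jj <- (sdd$optr[k] + 1):sdd$optr[k + 1]
        cpg <- sdd$cp[(sdd$gptr[k] + 1):sdd$gptr[k + 1]]
        ng <- cpp_npt_grid(cpg, sdd$grid_h, sdd$npt0[k],
                           tv$ic50[k] * exp(e1[k]), tv$kout[k] * exp(e2[k]),
                           fit$model$constants$imax)
        f[jj] <- ng[sdd$obs_idx[jj] + 1] + sdd$obs_frac[jj] *
          (ng[sdd$obs_idx[jj] + 2] - ng[sdd$obs_idx[jj] + 1])
      }
      sims[, s] <- pmax(f + stats::rnorm(length(f), 0, fit$sigma), 0)
    } else {
      eta <- stats::rnorm(n, 0, fit$omega[["lam"]])
      f <- numeric(length(sdd$obs_y))
      for (k in seq_len(n)) {
        jj <- (sdd$optr[k] + 1):sdd$optr[k + 1]
        frac <- pmin(pmax((sdd$npt0[k] - sdd$npt_pred[jj]) / sdd$npt0[k],
                          0), 1)
        f[jj] <- sdd$inr_base[k] +
          fit$model$constants$inr_max * frac^(tv$lam[k] * exp(eta[k]))
      }
      sims[, s] <- f * (1 + stats::rnorm(length(f), 0, fit$sigma))
    }
  }
  tt <- sdd$obs_t
  edges <- unique(stats::quantile(tt, probs = seq(0, 1, length.out =
                                                    n_bins + 1)))
  bin <- cut(tt, edges, include.lowest = TRUE)
  pr <- c(0.05, 0.5, 0.95)
  out <- lapply(levels(bin), function(bl) {
    sel <- bin == bl
    ob <- stats::quantile(sdd$obs_y[sel], pr, names = FALSE)
    sm <- stats::quantile(as.numeric(sims[sel, , drop = FALSE]), pr,
                          names = FALSE)
    data.frame(bin = bl, t_mid = stats::median(tt[sel]), n_obs = sum(sel),
               obs_p5 = ob[1], obs_p50 = ob[2], obs_p95 = ob[3],
               sim_p5 = sm[1], sim_p50 = sm[2], sim_p95 = sm[3])
  })
  do.call(rbind, out)
}

# Rebuild the flattened stage data used by a fit (for vpc and friends).
rebuild_stage_data <- function(cohort, fit, upstream = NULL) {
  cst <- fit$model$constants
  switch(fit$stage,
    pk = pk_stage_data(cohort, cst$s_fraction, cst$f_bio),
    npt = {
      stopifnot(!is.null(upstream))
      ip <- if (inherits(upstream, "popfit"))
        individual_parameters(upstream, cohort) else upstream
      cl <- stats::setNames(ip$cl, ip$patient_id)
      npt_stage_data(cohort, cl, fit$control$grid_h, cst$s_fraction,
                     cst$f_bio, cst$vd, cst$ka)
    },
    inr = {
      stopifnot(!is.null(upstream))
      ip <- if (inherits(upstream, "popfit")) {
        d <- individual_parameters(upstream, cohort)
        d$cl <- upstream$ind_params$cl[match(d$patient_id,
                                             upstream$ind_params$patient_id)]
        d[!is.na(d$cl), c("patient_id", "cl", "ic50", "kout")]
      } else upstream
      inr_stage_data(cohort, ip, fit$control$grid_h, cst$s_fraction,
                     cst$f_bio, cst$vd, cst$ka, cst$imax)
    })
}
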