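# End-to-end orchestration: dataset reading with validation, run
# configuration, and the reproducible simulate -> fit -> covariate search
# -> bootstrap -> cohort statistics pipeline.

#' Read and validate a three-table cohort dataset
#'
#' Reads `dosing.csv`, `observations.csv`, `covariates.csv` (and
#' `truth.csv` when present) from a directory, validates the schemas, and
#' cross-references patient ids: every dose and observation must belong
#' to a patient in the covariate table.  Exclusion counts (missing
#' baseline NPT) are reported as messages.
#'
#' @param dir Directory holding the CSV files.
#' @return A `warf_cohort`.
#' @export
read_dataset <- function(dir) {
  need <- c("dosing.csv", "observations.csv", "covariates.csv")
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing))
    stop("missing dataset file(s): ", paste(missing, collapse = ", "))
  dosing <- utils::read.csv(paths[1])
  observations <- utils::read.csv(paths[2])
  covariates <- utils::read.csv(paths[3])
  check_cols <- function(df, cols, file) {
    absent <- setdiff(cols, names(df))
    if (length(absent))
      stop(file, " lacks column(s): ", paste(absent, collapse = ", "))
  }
  check_cols(dosing, c("patient_id", "time_h", "dose_mg"), "dosing.csv")
  check_cols(observations, c("patient_id", "time_h", "obs_type", "value"),
             "observations.csv")
  check_cols(covariates, c("patient_id", "npt0", "inr_base", "bsa",
                           "cyp2c9_star3", "vkorc1_star1",
                           "cyp4f2_carrier"), "covariates.csv")
  if (anyDuplicated(covariates$patient_id))
    stop("covariates.csv: duplicated patient_id")
  bad <- setdiff(unique(observations$patient_id), covariates$patient_id)
  if (length(bad))
    stop("observations.csv refers to unknown patient id(s): ",
         paste(bad, collapse = ", "))
  bad <- setdiff(unique(dosing$patient_id), covariates$patient_id)
  if (length(bad))
    stop("dosing.csv refers to unknown patient id(s): ",
         paste(bad, collapse = ", "))
  if (!all(observations$obs_type %in% c("CP", "NPT", "INR")))
    stop("observations.csv: obs_type must be CP, NPT or INR")
  if (any(dosing$dose_mg <= 0)) stop("dosing.csv: non-positive dose")
  if (any(dosing$time_h < 0) || any(observations$time_h < 0))
    stop("negative times in dataset")
  n_miss <- sum(is.na(covariates$npt0))
  if (n_miss)
    message(n_miss, " patient(s) with missing baseline NPT will be ",
            "excluded from the NPT and INR stages")
  truth <- NULL
  tp <- file.path(dir, "truth.csv")
  if (file.exists(tp)) truth <- utils::read.csv(tp)
  structure(list(dosing = dosing, observations = observations,
                 covariates = covariates, truth = truth),
            class = "warf_cohort")
}

#' Configuration of a full pipeline run
#'
#' Bundles every tunable of the simulate/fit/search/bootstrap/statistics
#' chain; the defaults are the settings of the reference analysis
#' (99 patients, entry dOFV 3.84, removal dOFV 6.63, bootstrap 1,000 /
#' 100 / 1,000 resamples for the PK / NPT / INR stages).
#'
#' @param n_patients Cohort size.
#' @param seed Master seed: every random draw of the run flows from it.
#' @param spec,design Cohort and sampling-design specifications.
#' @param dofv_in,dofv_out Covariate search thresholds.
#' @param n_boot Named resample counts per stage.
#' @param do_covsearch,do_bootstrap Toggle the expensive stages.
#' @param control Fit control (see [fit_stage_pk()]).
#' @param outdir Optional directory for CSV artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_patients = 99, seed = 1, spec = NULL,
                       design = sampling_design(), dofv_in = 3.84,
                       dofv_out = 6.63,
                       n_boot = c(pk = 1000, npt = 100, inr = 1000),
                       do_covsearch = TRUE, do_bootstrap = TRUE,
                       control = default_fit_control(), outdir = NULL) {
  if (n_patients < 1) stop("n_patients must be at least 1")
  if (is.null(spec)) spec <- cohort_spec(n_patients = n_patients)
  stopifnot(all(c("pk", "npt", "inr") %in% names(n_boot)),
            all(n_boot >= 2))
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed), spec = spec, design = design,
                 dofv_in = dofv_in, dofv_out = dofv_out, n_boot = n_boot,
                 do_covsearch = do_covsearch, do_bootstrap = do_bootstrap,
                 control = control, outdir = outdir),
            class = "run_config")
}

#' Save / load a run configuration
#'
#' Plain-text round trip of a [run_config()] via deparsed R source.
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `load_config` returns the restored `run_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  dput(unclass(config), file = path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  structure(dget(path), class = "run_config")
}

#' Observed over-anticoagulation flag per patient
#'
#' TRUE when any post-baseline INR observation reaches 4.
#'
#' @param cohort A `warf_cohort`.
#' @return Named logical vector over patients.
#' @export
observed_inr_ge4 <- function(cohort) {
  obs <- cohort$observations
  inr <- obs[obs$obs_type == "INR" & obs$time_h > 0, ]
  flag <- tapply(inr$value >= 4, inr$patient_id, any)
  out <- stats::setNames(rep(FALSE, nrow(cohort$covariates)),
                         cohort$covariates$patient_id)
  out[names(flag)] <- as.logical(flag)
  out
}

#' Run the full sequential analysis pipeline
#'
#' Simulates a cohort (unless one is supplied), runs the three sequential
#' fits, optionally the stepwise covariate search per stage and the
#' per-stage bootstrap, and computes the cohort statistics: genotype
#' frequencies, 2x2 odds ratios and group comparisons against the
#' observed INR >= 4 outcome, plus the stepwise logistic regression on
#' the empirical Bayes parameters.  Fully reproducible given the seed.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-built `warf_cohort` (skips simulation).
#' @return A list of class `warf_run` with elements `cohort`, `fits`,
#'   `covsearch`, `bootstrap`, `stats` and `reference` (the generating /
#'   reference parameter values next to the recovered estimates).
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort))
    cohort <- simulate_cohort(config$spec, config$design,
                              seed = config$seed)
  ctrl <- config$control
  fits <- list()
  fits$pk <- fit_stage_pk(cohort, control = ctrl)
  fits$npt <- fit_stage_npt(cohort, fits$pk, control = ctrl)
  fits$inr <- fit_stage_inr(cohort, fits$npt, control = ctrl)
  covsearch <- NULL
  if (isTRUE(config$do_covsearch)) {
    covsearch <- list(
      pk = covariate_search(cohort, "pk", dofv_in = config$dofv_in,
                            dofv_out = config$dofv_out, control = ctrl),
      npt = covariate_search(cohort, "npt", upstream = fits$pk,
                             dofv_in = config$dofv_in,
                             dofv_out = config$dofv_out, control = ctrl),
      inr = covariate_search(cohort, "inr", upstream = fits$npt,
                             dofv_in = config$dofv_in,
                             dofv_out = config$dofv_out, control = ctrl))
  }
  boots <- NULL
  if (isTRUE(config$do_bootstrap)) {
    boots <- list(
      pk = bootstrap_fit(cohort, fits$pk,
                         n_resamples = config$n_boot[["pk"]],
                         seed = config$seed + 1, control = ctrl),
      npt = bootstrap_fit(cohort, fits$npt, upstream = fits$pk,
                          n_resamples = config$n_boot[["npt"]],
                          seed = config$seed + 2, control = ctrl),
      inr = bootstrap_fit(cohort, fits$inr, upstream = fits$npt,
                          n_resamples = config$n_boot[["inr"]],
                          seed = config$seed + 3, control = ctrl))
  }
  stats_out <- cohort_statistics(cohort, fits)
  reference <- data.frame(
    parameter = c("theta.cl", "beta.cl.bsa", "beta.cl.cyp2c9_star3",
                  "omega.cl", "sigma.cp", "theta.ic50", "theta.kout",
                  "beta.ic50.vkorc1_star1", "beta.ic50.cyp4f2_carrier",
                  "omega.ic50", "omega.kout", "sigma.npt", "theta.lam",
                  "beta.lam.npt0", "omega.lam", "sigma.inr"),
    reference = c(240, 2.14, 0.543, 0.399, 0.0697, 0.0725, 0.0136,
                  2.07, 1.30, 0.385, 0.456, 12.2, 3.48, 0.00588, 0.241,
                  0.247),
    estimate = c(fits$pk$theta[["cl"]],
                 cov_value(fits$pk, "bsa"),
                 cov_value(fits$pk, "cyp2c9_star3"),
                 fits$pk$omega[["cl"]], fits$pk$sigma,
                 fits$npt$theta[["ic50"]], fits$npt$theta[["kout"]],
                 cov_value(fits$npt, "vkorc1_star1"),
                 cov_value(fits$npt, "cyp4f2_carrier"),
                 fits$npt$omega[["ic50"]], fits$npt$omega[["kout"]],
                 fits$npt$sigma, fits$inr$theta[["lam"]],
                 cov_value(fits$inr, "npt0"), fits$inr$omega[["lam"]],
                 fits$inr$sigma))
  out <- structure(list(cohort = cohort, fits = fits,
                        covsearch = covsearch, bootstrap = boots,
                        stats = stats_out, reference = reference,
                        config = config),
                   class = "warf_run")
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(config$outdir, "cohort"))
    utils::write.csv(reference,
                     file.path(config$outdir, "estimates.csv"),
                     row.names = FALSE)
    for (st in names(fits))
      utils::write.csv(fits[[st]]$pred,
                       file.path(config$outdir,
                                 paste0("pred_", st, ".csv")),
                       row.names = FALSE)
  }
  out
}

cov_value <- function(fit, name) {
  for (tm in fit$covariates) if (tm$name == name) return(tm$value)
  NA_real_
}

#' Cohort statistics against the observed INR >= 4 outcome
#'
#' Minor-allele frequencies, comorbidity odds ratios, Mann-Whitney group
#' comparisons of the empirical Bayes CL(S), IC50 and lambda, and the
#' stepwise logistic regression with c-statistic.
#'
#' @param cohort A `warf_cohort`.
#' @param fits List with `pk`, `npt`, `inr` fits.
#' @return List with `maf`, `odds_ratios`, `groups`, `logistic`.
#' @export
cohort_statistics <- function(cohort, fits) {
  cov <- cohort$covariates
  flag <- observed_inr_ge4(cohort)
  flag <- flag[as.character(cov$patient_id)]
  maf <- vapply(c("cyp2c9_star3", "vkorc1_star1", "cyp4f2_star3"),
                function(g) mean(cov[[g]]) / 2, numeric(1))
  or_of <- function(x) {
    a <- sum(x == 1 & flag); b <- sum(x == 1 & !flag)
    cc <- sum(x == 0 & flag); d <- sum(x == 0 & !flag)
    tryCatch(odds_ratio_2x2(a, b, cc, d), error = function(e) NULL)
  }
  ors <- list(hypertension = or_of(cov$hypertension),
              ckd = or_of(cov$ckd), af = or_of(cov$af),
              standard_protocol = or_of(as.integer(cov$protocol ==
                                                     "standard")))
  ebes <- merge(merge(fits$pk$ind_params[, c("patient_id", "cl")],
                      fits$npt$ind_params[, c("patient_id", "ic50")],
                      by = "patient_id"),
                fits$inr$ind_params[, c("patient_id", "lam")],
                by = "patient_id")
  eflag <- flag[as.character(ebes$patient_id)]
  groups <- group_compare(ebes, eflag, params = c("cl", "ic50", "lam"))
  ldf <- merge(cov, ebes, by = "patient_id")
  ldf$log_alt <- log(ldf$alt)
  lflag <- flag[as.character(ldf$patient_id)]
  logistic <- stepwise_logistic(
    ldf, lflag,
    candidates = c("cl", "lam", "log_alt", "age", "sex", "weight", "bsa",
                   "clcr", "hepatic_disease", "ckd", "chf", "hypertension",
                   "alcohol", "smoking", "dvt"),
    screen_vars = c("cl", "lam"))
  list(maf = maf, odds_ratios = ors, groups = groups, logistic = logistic,
       outcome_rate = mean(flag))
}

#' @export
print.warf_run <- function(x, ...) {
  cat("Sequential population PK-PD run (seed ", x$config$seed, ")\n",
      sep = "")
  print(x$cohort)
  cat("\nRecovered vs reference parameters:\n")
  print(transform(x$reference, reference = signif(reference, 4),
                  estimate = signif(estimate, 4)))
  cat("\nObserved INR>=4 rate:", signif(x$stats$outcome_rate, 3), "\n")
  invisible(x)
}
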