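# Stepwise covariate model building on the objective function value:
# forward inclusion at dOFV > 3.84 (chi-squared 1 df, P < 0.05) and backward
# deletion at dOFV < 6.63 (chi-squared 1 df, P < 0.01).

#' Candidate covariates for stepwise selection on one stage
#'
#' The roster holds age, body weight, BSA, BMI, AST, ALT and CLcr as
#' continuous candidates (power and exponential forms both tried), sex and
#' the comorbidity/history flags as categorical candidates, plus the
#' stage-specific terms: CYP2C9*3 for CL(S), VKORC1*1 and CYP4F2*3
#' carriage for IC50, baseline NPT for lambda.
#'
#' @param stage `"pk"`, `"npt"` or `"inr"`.
#' @return List of candidate descriptors (`param`, `name`, `kind`).
#' @export
covariate_candidates <- function(stage = c("pk", "npt", "inr")) {
  stage <- match.arg(stage)
  param <- switch(stage, pk = "cl", npt = "ic50", inr = "lam")
  cont <- c("age", "weight", "bsa", "bmi", "ast", "alt", "clcr")
  cat <- c("sex", "hepatic_disease", "ckd", "chf", "hypertension",
           "alcohol", "smoking")
  extra <- switch(stage,
                  pk = list(list(param = param, name = "cyp2c9_star3",
                                 kind = "categorical")),
                  npt = list(list(param = param, name = "vkorc1_star1",
                                  kind = "categorical"),
                             list(param = param, name = "cyp4f2_carrier",
                                  kind = "categorical")),
                  inr = list(list(param = param, name = "npt0",
                                  kind = "continuous")))
  c(lapply(cont, function(nm) list(param = param, name = nm,
                                   kind = "continuous")),
    lapply(cat, function(nm) list(param = param, name = nm,
                                  kind = "categorical")),
    extra)
}

add_term <- function(model, param, name, form, center = NULL, value = NULL) {
  if (is.null(value)) value <- if (form == "cat") 1 else 0
  tm <- list(param = param, name = name, form = form, value = value)
  if (form != "cat") tm$center <- center
  model$covariates <- c(model$covariates, list(tm))
  model
}

drop_term <- function(model, k) {
  model$covariates <- model$covariates[-k]
  model
}

search_control <- function(control) {
  control$n_starts <- 1
  control$se <- FALSE
  # dOFV decisions at thresholds ~4-7 need far less objective precision
  # than final estimates; a looser outer tolerance halves search cost
  control$rel_tol <- max(control$rel_tol %||% 1e-9, 1e-6)
  control
}

fit_candidate <- function(stage, cohort, model, upstream, control) {
  tryCatch(fit_stage(stage, cohort, model, upstream,
                     search_control(control)),
           error = function(e) NULL)
}

candidate_forms <- function(cand, covdf) {
  x <- covdf[[cand$name]]
  if (is.null(x) || anyNA(x) || stats::var(x) == 0) return(NULL)
  if (cand$kind == "categorical") {
    list(list(form = "cat", center = NULL))
  } else {
    list(list(form = "power", center = stats::median(x)),
         list(form = "exp", center = stats::median(x)))
  }
}

#' Forward covariate inclusion by objective-function drop
#'
#' Iteratively adds the candidate whose inclusion lowers the OFV the most,
#' as long as the drop exceeds `dofv_in` (default 3.84, chi-squared with
#' 1 df at P < 0.05).  Both the power and exponential forms of each
#' continuous candidate are fitted and the better one competes.  Fit
#' failures on a candidate are skipped and logged.
#'
#' @param cohort A `warf_cohort`.
#' @param base_fit A fitted `popfit` to start from.
#' @param candidates From [covariate_candidates()].
#' @param upstream Upstream fit or individual-parameter frame (NPT/INR
#'   stages).
#' @param dofv_in Inclusion threshold on the OFV drop.
#' @param control Fit control; searches always use one warm start.
#' @return List with the expanded `fit` and an `audit` data frame
#'   (step, candidate, form, delta_ofv, decision).
#' @export
forward_include <- function(cohort, base_fit, candidates,
                            upstream = NULL, dofv_in = 3.84,
                            control = default_fit_control()) {
  stage <- base_fit$stage
  audit <- list()
  pool <- candidates
  step <- 0
  repeat {
    step <- step + 1
    best <- NULL
    rows <- list()
    for (cand in pool) {
      in_model <- vapply(base_fit$model$covariates, function(tm)
        tm$param == cand$param && tm$name == cand$name, logical(1))
      if (any(in_model)) next
      covdf <- cohort$covariates[cohort$covariates$patient_id %in%
                                   base_fit$ids, ]
      forms <- candidate_forms(cand, covdf)
      if (is.null(forms)) {
        rows[[length(rows) + 1]] <-
          data.frame(step = step, candidate = cand$name, form = NA,
                     delta_ofv = NA, decision = "skipped (degenerate)")
        next
      }
      cbest <- NULL
      for (fm in forms) {
        m <- add_term(base_fit$model, cand$param, cand$name, fm$form,
                      fm$center)
        ft <- fit_candidate(stage, cohort, m, upstream, control)
        if (is.null(ft)) next
        if (is.null(cbest) || ft$ofv < cbest$fit$ofv)
          cbest <- list(fit = ft, form = fm$form)
      }
      if (is.null(cbest)) {
        rows[[length(rows) + 1]] <-
          data.frame(step = step, candidate = cand$name, form = NA,
                     delta_ofv = NA, decision = "skipped (fit failure)")
        next
      }
      dofv <- base_fit$ofv - cbest$fit$ofv
      rows[[length(rows) + 1]] <-
        data.frame(step = step, candidate = cand$name, form = cbest$form,
                   delta_ofv = dofv, decision = "tested")
      if (dofv > dofv_in && (is.null(best) || dofv > best$dofv))
        best <- list(fit = cbest$fit, cand = cand, form = cbest$form,
                     dofv = dofv)
    }
    audit <- c(audit, rows)
    if (is.null(best)) break
    audit[[length(audit) + 1]] <-
      data.frame(step = step, candidate = best$cand$name, form = best$form,
                 delta_ofv = best$dofv, decision = "included")
    base_fit <- best$fit
  }
  list(fit = base_fit, audit = do.call(rbind, audit))
}

#' Backward covariate deletion by objective-function rise
#'
#' Iteratively removes the covariate whose deletion raises the OFV the
#' least, as long as that rise stays below `dofv_out` (default 6.63,
#' chi-squared with 1 df at P < 0.01).
#'
#' @inheritParams forward_include
#' @param full_fit The fitted full model from the forward step.
#' @param dofv_out Retention threshold on the OFV rise.
#' @return List with the pruned `fit` and an `audit` data frame.
#' @export
backward_delete <- function(cohort, full_fit, upstream = NULL,
                            dofv_out = 6.63,
                            control = default_fit_control()) {
  stage <- full_fit$stage
  audit <- list()
  step <- 0
  repeat {
    step <- step + 1
    terms <- full_fit$model$covariates
    if (!length(terms)) break
    worst <- NULL
    for (k in seq_along(terms)) {
      m <- drop_term(full_fit$model, k)
      ft <- fit_candidate(stage, cohort, m, upstream, control)
      if (is.null(ft)) next
      rise <- ft$ofv - full_fit$ofv
      audit[[length(audit) + 1]] <-
        data.frame(step = step, candidate = terms[[k]]$name,
                   form = terms[[k]]$form, delta_ofv = rise,
                   decision = "tested")
      if (is.null(worst) || rise < worst$rise)
        worst <- list(fit = ft, k = k, rise = rise,
                      name = terms[[k]]$name, form = terms[[k]]$form)
    }
    if (is.null(worst) || worst$rise >= dofv_out) break
    audit[[length(audit) + 1]] <-
      data.frame(step = step, candidate = worst$name, form = worst$form,
                 delta_ofv = worst$rise, decision = "deleted")
    full_fit <- worst$fit
  }
  list(fit = full_fit, audit = do.call(rbind, audit))
}

#' Full stepwise covariate search on one stage
#'
#' Starts from the covariate-free base model, runs forward inclusion
#' (P < 0.05 on the OFV drop) followed by backward deletion (P < 0.01 on
#' the OFV rise) and returns the final fit with the full audit trail.
#' The procedure is deterministic given the data and candidate order;
#' ties break in favour of the earlier candidate.
#'
#' @param cohort A `warf_cohort`.
#' @param stage `"pk"`, `"npt"` or `"inr"`.
#' @param upstream Upstream fit or individual-parameter frame.
#' @param candidates Candidate roster; default [covariate_candidates()].
#' @param base_model Covariate-free starting [population_model()];
#'   defaults to the reference model stripped of its covariate terms.
#' @param dofv_in,dofv_out Inclusion/retention thresholds.
#' @param control Fit control.
#' @return List with `fit`, `audit`, and `selected` (character vector of
#'   retained covariate names).
#' @export
covariate_search <- function(cohort, stage, upstream = NULL,
                             candidates = covariate_candidates(stage),
                             base_model = NULL, dofv_in = 3.84,
                             dofv_out = 6.63,
                             control = default_fit_control()) {
  if (is.null(base_model)) {
    base_model <- reference_popmodel(stage)
    base_model$covariates <- list()
  }
  base_fit <- fit_stage(stage, cohort, base_model, upstream,
                        search_control(control))
  fw <- forward_include(cohort, base_fit, candidates, upstream, dofv_in,
                        control)
  bw <- backward_delete(cohort, fw$fit, upstream, dofv_out, control)
  audit <- rbind(cbind(phase = "forward", fw$audit),
                 if (!is.null(bw$audit)) cbind(phase = "backward", bw$audit))
  selected <- vapply(bw$fit$model$covariates, function(tm) tm$name,
                     character(1))
  list(fit = bw$fit, audit = audit, selected = selected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
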