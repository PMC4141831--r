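#' Population model specification for one sequential stage
#'
#' Describes the fixed effects, covariate submodels, inter-individual
#' variability and residual-error model of one of the three sequential
#' stages: `"pk"` (dose -> Cp(S)), `"npt"` (Cp(S) -> NPT) and `"inr"`
#' (NPT -> INR).
#'
#' Covariate terms multiply the typical value of their target parameter:
#' * `form = "power"`: `(x / center)^value` (continuous),
#' * `form = "exp"`: `exp(value * (x - center))` (continuous),
#' * `form = "cat"`: `value^x` for an indicator or allele count `x`.
#'
#' @param stage One of `"pk"`, `"npt"`, `"inr"`.
#' @param theta Named vector of fixed effects (`cl`; `ic50`, `kout`; `lam`).
#' @param covariates List of terms, each a list with elements `param`
#'   (target parameter name), `name` (covariate column), `form`, `value`
#'   (effect size / initial estimate) and, for continuous forms, `center`.
#' @param omega Named vector of inter-individual standard deviations on the
#'   log scale (an entry of 0 fixes that random effect to zero).
#' @param sigma Residual error: SD in observation units for the additive
#'   model, fractional SD for the relative model.
#' @param error `"additive"` or `"relative"`.
#' @param constants Fixed structural constants.
#' @return An object of class `population_model`.
#' @export
population_model <- function(stage = c("pk", "npt", "inr"), theta,
                             covariates = list(), omega, sigma,
                             error = c("additive", "relative"),
                             constants = list(vd = 13.8, ka = 2,
                                              f_bio = 1, imax = 1,
                                              inr_max = 5, s_fraction = 0.5)) {
  stage <- match.arg(stage)
  error <- match.arg(error)
  stopifnot(is.numeric(theta), !is.null(names(theta)), all(theta > 0),
            is.numeric(omega), all(omega >= 0), length(sigma) == 1,
            sigma > 0)
  need <- switch(stage, pk = "cl", npt = c("ic50", "kout"), inr = "lam")
  if (!setequal(names(theta), need))
    stop("stage '", stage, "' needs theta entries: ",
         paste(need, collapse = ", "))
  if (!all(names(omega) %in% names(theta)))
    stop("omega names must match theta names")
  for (tm in covariates) {
    stopifnot(tm$param %in% names(theta),
              tm$form %in% c("power", "exp", "cat"))
    if (tm$form != "cat" && is.null(tm$center))
      stop("continuous covariate term '", tm$name, "' needs a center")
    if (tm$form == "cat" && tm$value <= 0)
      stop("categorical effect must be a positive multiplier")
  }
  structure(list(stage = stage, theta = theta, covariates = covariates,
                 omega = omega, sigma = sigma, error = error,
                 constants = constants),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population model, stage '", x$stage, "'\n", sep = "")
  cat("  theta:", paste(names(x$theta), signif(x$theta, 4),
                        sep = " = ", collapse = ", "), "\n")
  for (tm in x$covariates)
    cat("  covariate on ", tm$param, ": ", tm$name, " (", tm$form,
        ") = ", signif(tm$value, 4), "\n", sep = "")
  cat("  omega (SD):", paste(names(x$omega), signif(x$omega, 4),
                             sep = " = ", collapse = ", "), "\n")
  cat("  sigma:", signif(x$sigma, 4), paste0("(", x$error, ")"), "\n")
  invisible(x)
}

#' Reference population PK-PD model of warfarin initiation
#'
#' Returns the final-model parameter set estimated in a 99-patient Asian
#' warfarin-initiation cohort: CL(S) 240 mL/h with a 0.543 multiplier per
#' CYP2C9*3 allele and a BSA power exponent 2.14 (centered at 1.74 m^2);
#' IC50 0.0725 ug/mL with multipliers 2.07 per VKORC1*1 allele and 1.30
#' for CYP4F2*3 carriage; Kout 0.0136 /h; lambda 3.48 with an exponential
#' baseline-NPT effect 0.00588 (centered at 119 ug/mL).  Inter-individual
#' SDs: 0.399 (CL), 0.385 (IC50), 0.456 (Kout), 0.241 (lambda).  Residual
#' errors: additive 0.0697 ug/mL (Cp), additive 12.2 ug/mL (NPT),
#' relative 24.7% (INR).
#'
#' @param stage One of `"pk"`, `"npt"`, `"inr"`.
#' @return A [population_model()].
#' @export
reference_popmodel <- function(stage = c("pk", "npt", "inr")) {
  stage <- match.arg(stage)
  switch(stage,
    pk = population_model(
      "pk", theta = c(cl = 240),
      covariates = list(
        list(param = "cl", name = "cyp2c9_star3", form = "cat",
             value = 0.543),
        list(param = "cl", name = "bsa", form = "power", center = 1.74,
             value = 2.14)),
      omega = c(cl = 0.399), sigma = 0.0697, error = "additive"),
    npt = population_model(
      "npt", theta = c(ic50 = 0.0725, kout = 0.0136),
      covariates = list(
        list(param = "ic50", name = "vkorc1_star1", form = "cat",
             value = 2.07),
        list(param = "ic50", name = "cyp4f2_carrier", form = "cat",
             value = 1.30)),
      omega = c(ic50 = 0.385, kout = 0.456), sigma = 12.2,
      error = "additive"),
    inr = population_model(
      "inr", theta = c(lam = 3.48),
      covariates = list(
        list(param = "lam", name = "npt0", form = "exp", center = 119,
             value = 0.00588)),
      omega = c(lam = 0.241), sigma = 0.247, error = "relative"))
}

# Per-patient typical values of every theta parameter under the covariate
# submodels; covdf must hold one row per patient.
apply_covariate_model <- function(model, covdf) {
  out <- lapply(names(model$theta), function(pn) {
    tv <- rep(model$theta[[pn]], nrow(covdf))
    for (tm in model$covariates) {
      if (tm$param != pn) next
      x <- covdf[[tm$name]]
      if (is.null(x)) stop("covariate column '", tm$name, "' not found")
      if (anyNA(x)) stop("covariate '", tm$name, "' has missing values")
      tv <- tv * switch(tm$form,
                        power = (x / tm$center)^tm$value,
                        exp = exp(tm$value * (x - tm$center)),
                        cat = tm$value^x)
    }
    tv
  })
  names(out) <- names(model$theta)
  out
}

# --- parameter packing for estimation --------------------------------------
# Layout: log(theta) | covariate coefs (cat on log scale, power/exp raw) |
# log(omega > 0) | log(sigma)

pack_model <- function(model) {
  th <- log(model$theta)
  names(th) <- paste0("theta.", names(model$theta))
  cf <- vapply(model$covariates, function(tm)
    if (tm$form == "cat") log(tm$value) else tm$value, numeric(1))
  if (length(cf))
    names(cf) <- paste0("beta.", vapply(model$covariates, function(tm)
      paste0(tm$param, ".", tm$name), character(1)))
  est_om <- model$omega[model$omega > 0]
  om <- if (length(est_om)) stats::setNames(log(est_om),
                                            paste0("omega.", names(est_om)))
        else numeric(0)
  sg <- c(sigma = log(model$sigma))
  c(th, cf, om, sg)
}

unpack_model <- function(par, model) {
  i <- 0
  for (pn in names(model$theta)) {
    i <- i + 1
    model$theta[[pn]] <- exp(par[[i]])
  }
  if (length(model$covariates)) {
    for (k in seq_along(model$covariates)) {
      i <- i + 1
      model$covariates[[k]]$value <-
        if (model$covariates[[k]]$form == "cat") exp(par[[i]]) else par[[i]]
    }
  }
  for (on in names(model$omega)) {
    if (model$omega[[on]] > 0) {
      i <- i + 1
      model$omega[[on]] <- exp(par[[i]])
    }
  }
  i <- i + 1
  model$sigma <- exp(par[[i]])
  model
}
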