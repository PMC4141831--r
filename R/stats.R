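# Cohort-level statistics: allele frequencies, 2x2 odds ratios, rank and
# contingency tests, correlations, stepwise logistic regression for the
# over-anticoagulation outcome (INR >= 4), and group comparisons of
# empirical Bayes parameter estimates.

#' Minor allele frequency from genotype counts
#'
#' `(hetero + 2 * homo) / (2 * n)` where `homo` counts homozygotes for the
#' counted allele.  Note the orientation follows the reporting convention
#' of the locus: for VKORC1 the -1639A variant is the *major* allele in
#' Asian cohorts, so the printed frequency (e.g. 0.904) counts A.
#'
#' @param wild,hetero,homo Genotype counts.
#' @return Allele frequency of the counted allele, in `[0, 1]`.
#' @export
minor_allele_freq <- function(wild, hetero, homo) {
  n <- wild + hetero + homo
  if (n <= 0) stop("no genotyped patients")
  stopifnot(wild >= 0, hetero >= 0, homo >= 0)
  (hetero + 2 * homo) / (2 * n)
}

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' `OR = a*d / (b*c)` with the exposed-case/exposed-noncase/unexposed-case/
#' unexposed-noncase layout; 95% CI `exp(log OR +/- 1.96 * sqrt(1/a + 1/b
#' + 1/c + 1/d))`.  A zero cell triggers the Haldane-Anscombe 0.5
#' correction on all cells (reported in the result).
#'
#' @param a Exposed cases.
#' @param b Exposed non-cases.
#' @param c Unexposed cases.
#' @param d Unexposed non-cases.
#' @param conf Confidence level.
#' @return List with `or`, `lower`, `upper`, `corrected`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d, conf = 0.95) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  if (sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0 ||
      sum(cells[c(1, 2)]) == 0 || sum(cells[c(3, 4)]) == 0)
    stop("a margin of the 2x2 table is zero")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- cells[1] * cells[4] / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = or, lower = exp(log(or) - z * se),
       upper = exp(log(or) + z * se), corrected = corrected)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples: exact permutation enumeration when
#' both groups have at most `exact_max` observations (ties handled by
#' mid-ranks), otherwise the tie-corrected normal approximation without
#' continuity correction.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest per-group size for the exact branch.
#' @return List with `U` (for the first sample), `p` (two-sided) and
#'   `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    Us <- apply(idx, 2, function(ii) sum(r[ii])) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(r)
    v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(v)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal"
  }
  list(U = U, p = min(p, 1), method = method)
}

#' Chi-squared or Fisher's exact test of a 2x2 table
#'
#' Pearson chi-squared without continuity correction; switches to
#' Fisher's exact test when any expected cell count falls below 5.
#'
#' @inheritParams odds_ratio_2x2
#' @return List with `p` and `method`.
#' @export
chi2_or_fisher <- function(a, b, c, d) {
  m <- matrix(c(a, c, b, d), 2, 2)
  stopifnot(all(m >= 0))
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    list(p = stats::fisher.test(m)$p.value, method = "fisher")
  } else {
    list(p = suppressWarnings(
      stats::chisq.test(m, correct = FALSE)$p.value), method = "chisq")
  }
}

#' Pearson correlation with t-distribution p-value
#'
#' @param x,y Numeric vectors (n >= 3, non-degenerate).
#' @return List with `r` and `p`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a correlation input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Concordance (c-) statistic
#'
#' Probability that a randomly chosen case scores higher than a randomly
#' chosen non-case, computed from mid-ranks (ties count 1/2); equals the
#' area under the ROC curve.
#'
#' @param score Numeric risk scores.
#' @param outcome Binary outcome (1 = case).
#' @return The c-statistic.
#' @export
c_statistic <- function(score, outcome) {
  outcome <- as.integer(outcome)
  stopifnot(all(outcome %in% 0:1))
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome groups must be non-empty")
  r <- rank(score)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

lr_p <- function(fit_small, fit_big) {
  stats::pchisq(fit_small$deviance - fit_big$deviance,
                df = fit_small$df.residual - fit_big$df.residual,
                lower.tail = FALSE)
}

#' Stepwise logistic regression for a binary outcome
#'
#' Forward entry by likelihood-ratio test (`entry_p`, default 0.05)
#' followed by backward removal (`removal_p`, default 0.10, the common
#' stepwise default).  Before the search, continuous candidates that
#' correlate too strongly (|r| > `screen_r`) with any of the named
#' `screen_vars` are dropped, mirroring the internal-correlation screen
#' applied before modelling over-anticoagulation risk.  Complete
#' separation is detected and flagged.
#'
#' @param data Data frame of candidate predictors (and screen variables).
#' @param outcome Binary outcome vector (1 = event).
#' @param candidates Character vector of candidate column names.
#' @param entry_p,removal_p Entry and removal P-value thresholds.
#' @param screen_vars Columns against which the correlation screen runs
#'   (set `NULL` to skip).
#' @param screen_r Absolute correlation threshold of the screen.
#' @return List of class `stepwise_logistic`: `coefficients` data frame
#'   (term, beta, or, lower, upper, p), `included`, `screened_out`,
#'   `c_statistic`, `sensitivity`, `specificity`, `separation`, `fit`.
#' @export
stepwise_logistic <- function(data, outcome, candidates,
                              entry_p = 0.05, removal_p = 0.10,
                              screen_vars = intersect(c("cl", "lam"),
                                                      names(data)),
                              screen_r = 0.7) {
  outcome <- as.integer(outcome)
  stopifnot(all(outcome %in% 0:1), nrow(data) == length(outcome))
  screened_out <- character(0)
  if (length(screen_vars)) {
    for (cand in setdiff(candidates, screen_vars)) {
      x <- data[[cand]]
      if (!is.numeric(x) || length(unique(x)) <= 2) next
      rmax <- max(vapply(screen_vars, function(sv)
        abs(stats::cor(x, data[[sv]], use = "complete.obs")), numeric(1)))
      if (rmax > screen_r) screened_out <- c(screened_out, cand)
    }
    candidates <- setdiff(candidates, screened_out)
  }
  df <- data.frame(.y = outcome, data)
  # separation and non-convergence in small candidate fits are detected
  # explicitly below; glm's own warnings would only repeat that
  glm_quiet <- function(expr) suppressWarnings(expr)
  current <- glm_quiet(stats::glm(.y ~ 1, family = stats::binomial(),
                                  data = df))
  included <- character(0)
  # forward entry
  repeat {
    pool <- setdiff(candidates, included)
    if (!length(pool)) break
    ps <- vapply(pool, function(cand) {
      big <- tryCatch(glm_quiet(stats::update(current, stats::as.formula(
        paste(". ~ . +", cand)))), error = function(e) NULL)
      if (is.null(big)) return(NA_real_)
      lr_p(current, big)
    }, numeric(1))
    if (all(is.na(ps)) || min(ps, na.rm = TRUE) >= entry_p) break
    take <- pool[which.min(ps)]
    included <- c(included, take)
    current <- glm_quiet(stats::update(current, stats::as.formula(
      paste(". ~ . +", take))))
  }
  # backward removal
  repeat {
    if (!length(included)) break
    ps <- vapply(included, function(cand) {
      small <- glm_quiet(stats::update(current, stats::as.formula(
        paste(". ~ . -", cand))))
      lr_p(small, current)
    }, numeric(1))
    if (max(ps) < removal_p) break
    dropv <- included[which.max(ps)]
    included <- setdiff(included, dropv)
    current <- glm_quiet(stats::update(current, stats::as.formula(
      paste(". ~ . -", dropv))))
  }
  w <- stats::coef(summary(current))
  z <- stats::qnorm(0.975)
  coefs <- data.frame(term = rownames(w), beta = w[, 1],
                      or = exp(w[, 1]),
                      lower = exp(w[, 1] - z * w[, 2]),
                      upper = exp(w[, 1] + z * w[, 2]),
                      p = w[, 4], row.names = NULL)
  prob <- stats::fitted(current)
  separation <- any(prob > 1 - 1e-8) || any(prob < 1e-8)
  pred_case <- prob >= 0.5
  sens <- if (sum(outcome == 1)) mean(pred_case[outcome == 1]) else NA
  spec <- if (sum(outcome == 0)) mean(!pred_case[outcome == 0]) else NA
  cs <- if (length(unique(outcome)) == 2) c_statistic(prob, outcome) else NA
  structure(list(coefficients = coefs, included = included,
                 screened_out = screened_out, c_statistic = cs,
                 sensitivity = sens, specificity = spec,
                 separation = separation, fit = current),
            class = "stepwise_logistic")
}

#' @export
print.stepwise_logistic <- function(x, ...) {
  cat("Stepwise logistic regression:",
      if (length(x$included)) paste(x$included, collapse = ", ")
      else "(intercept only)", "\n")
  print(transform(x$coefficients, beta = signif(beta, 3),
                  or = signif(or, 3), lower = signif(lower, 3),
                  upper = signif(upper, 3), p = signif(p, 3)))
  cat(sprintf("c = %.3f, sensitivity %.1f%%, specificity %.1f%%\n",
              x$c_statistic, 100 * x$sensitivity, 100 * x$specificity))
  if (x$separation) cat("WARNING: complete separation detected\n")
  invisible(x)
}

#' Compare individual parameter estimates between outcome groups
#'
#' Medians with quartiles per group and a Mann-Whitney p-value for every
#' parameter column, as used to contrast patients with and without an
#' INR >= 4 episode.
#'
#' @param values Data frame of per-patient parameter values.
#' @param flag Logical/binary group indicator aligned with `values` rows.
#' @param params Columns to compare (default: all numeric except ids).
#' @return Data frame with group medians, quartiles and p-values.
#' @export
group_compare <- function(values, flag,
                          params = setdiff(names(values)[vapply(
                            values, is.numeric, logical(1))],
                            "patient_id")) {
  flag <- as.logical(flag)
  stopifnot(length(flag) == nrow(values))
  if (!any(flag) || all(flag)) stop("both groups must be non-empty")
  out <- lapply(params, function(pn) {
    x1 <- values[[pn]][flag]; x0 <- values[[pn]][!flag]
    q1 <- stats::quantile(x1, c(0.25, 0.5, 0.75), names = FALSE)
    q0 <- stats::quantile(x0, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(parameter = pn,
               median_flag = q1[2], q25_flag = q1[1], q75_flag = q1[3],
               median_ref = q0[2], q25_ref = q0[1], q75_ref = q0[3],
               p = mann_whitney(x1, x0)$p)
  })
  do.call(rbind, out)
}
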