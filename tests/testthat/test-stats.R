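# Cohort-level statistics: allele frequencies, odds ratios, rank and
# contingency tests, concordance, stepwise logistic regression.

test_that("minor allele frequency matches the published genotype counts", {
  expect_equal(round(minor_allele_freq(88, 11, 0), 3), 0.056)
  expect_equal(round(minor_allele_freq(1, 17, 81), 3), 0.904)
  expect_equal(round(minor_allele_freq(50, 43, 6), 3), 0.278)
  expect_equal(minor_allele_freq(30, 0, 0), 0)
  expect_error(minor_allele_freq(0, 0, 0), "no genotyped")
})

test_that("MAF is a frequency and complements orient correctly", {
  set.seed(1)
  for (i in 1:20) {
    g <- rmultinom(1, 50, runif(3))[, 1]
    f <- minor_allele_freq(g[1], g[2], g[3])
    expect_gte(f, 0); expect_lte(f, 1)
    expect_equal(minor_allele_freq(g[3], g[2], g[1]), 1 - f)
  }
})

test_that("odds ratios reproduce the published 2x2 results", {
  # hypertension vs over-anticoagulation: cases 30/5, non-cases 36/28
  ht <- odds_ratio_2x2(30, 36, 5, 28)
  expect_equal(round(ht$or, 1), 4.7)
  expect_equal(round(ht$lower, 1), 1.6)
  expect_equal(round(ht$upper, 1), 13.6)
  ckd <- odds_ratio_2x2(11, 5, 24, 59)
  expect_equal(round(ckd$or, 1), 5.4)
  expect_equal(round(ckd$lower, 1), 1.7)
  expect_equal(round(ckd$upper, 1), 17.2)
  af <- odds_ratio_2x2(27, 27, 8, 37)
  expect_equal(round(af$or, 1), 4.6)
  expect_equal(round(af$lower, 1), 1.8)
  expect_equal(round(af$upper, 1), 11.7)
  std <- odds_ratio_2x2(13, 9, 22, 55)
  expect_equal(round(std$or, 1), 3.6)
  expect_equal(round(std$lower, 1), 1.4)
  expect_equal(round(std$upper, 1), 9.7)
})

test_that("odds ratio symmetry, reciprocity and zero-cell handling", {
  expect_equal(odds_ratio_2x2(1, 1, 1, 1)$or, 1)
  set.seed(2)
  for (i in 1:10) {
    t4 <- rpois(4, 12) + 1
    o1 <- odds_ratio_2x2(t4[1], t4[2], t4[3], t4[4])$or
    o2 <- odds_ratio_2x2(t4[3], t4[4], t4[1], t4[2])$or
    expect_equal(o1 * o2, 1, tolerance = 1e-12)
  }
  zc <- odds_ratio_2x2(5, 0, 3, 7)
  expect_true(zc$corrected)
  expect_error(odds_ratio_2x2(0, 5, 0, 7), "margin")
})

test_that("Mann-Whitney exact branch matches enumeration", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  expect_equal(mann_whitney(x, y)$U, length(x) * length(y) / 2)
  # tie-free cases agree with the exact Wilcoxon distribution
  set.seed(3)
  for (i in 1:10) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(100, n1 + n2)
    ours <- mann_whitney(v[1:n1], v[-(1:n1)])
    ref <- suppressWarnings(wilcox.test(v[1:n1], v[-(1:n1)],
                                        exact = TRUE))
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney normal branch is tie-corrected and sane", {
  set.seed(4)
  x <- round(rnorm(30, 0, 2)); y <- round(rnorm(25, 1, 2))
  ours <- mann_whitney(x, y)
  expect_equal(ours$method, "normal")
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                      correct = FALSE))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
})

test_that("chi-squared / Fisher switch follows the expected-count rule", {
  expect_equal(chi2_or_fisher(10, 10, 10, 10)$p, 1, tolerance = 1e-12)
  f <- chi2_or_fisher(5, 0, 0, 5)
  expect_equal(f$method, "fisher")
  expect_equal(f$p, 2 / choose(10, 5), tolerance = 1e-12)
  # all expected counts exactly 5: chi-squared branch
  expect_equal(chi2_or_fisher(5, 5, 5, 5)$method, "chisq")
  # shrink one margin below the threshold: Fisher branch
  expect_equal(chi2_or_fisher(4, 5, 5, 5)$method, "fisher")
})

test_that("Pearson correlation behaves at the extremes", {
  expect_equal(pearson_corr(1:10, 2 * (1:10) + 3)$r, 1, tolerance = 1e-12)
  set.seed(5)
  r <- pearson_corr(rnorm(4000), rnorm(4000))
  expect_lt(abs(r$r), 0.05)
  expect_error(pearson_corr(rep(1, 5), rnorm(5)), "variance")
})

test_that("c-statistic equals the concordant-pair fraction", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  brute <- function(s, y) {
    cases <- s[y == 1]; ctrl <- s[y == 0]
    tot <- 0
    for (a in cases) for (b in ctrl)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(cases) * length(ctrl))
  }
  set.seed(6)
  for (i in 1:15) {
    n <- sample(6:30, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), 1)
    expect_equal(c_statistic(s, y), brute(s, y), tolerance = 1e-12)
  }
})

test_that("stepwise logistic finds structure and respects the null", {
  set.seed(7)
  n <- 150
  # outcome driven negatively by cl, positively by hypertension
  cl <- rnorm(n, 240, 80)
  ht <- rbinom(n, 1, 0.5)
  noise1 <- rnorm(n); noise2 <- rbinom(n, 1, 0.3)
  lp <- 2 - 0.012 * cl + 1.4 * ht
  y <- rbinom(n, 1, plogis(lp))
  d <- data.frame(cl = cl, hypertension = ht, noise1 = noise1,
                  noise2 = noise2)
  m <- stepwise_logistic(d, y, c("cl", "hypertension", "noise1", "noise2"),
                         screen_vars = NULL)
  expect_true(all(c("cl", "hypertension") %in% m$included))
  b_cl <- m$coefficients$beta[m$coefficients$term == "cl"]
  expect_lt(b_cl, 0)
  expect_gt(m$c_statistic, 0.6)
  # null outcome: intercept-only in most replicates
  picks <- vapply(1:25, function(i) {
    y0 <- rbinom(n, 1, 0.35)
    length(stepwise_logistic(d, y0, c("cl", "noise1", "noise2"),
                             screen_vars = NULL)$included)
  }, numeric(1))
  expect_gte(mean(picks == 0), 0.6)
})

test_that("correlation screen drops proxies of the screen variables", {
  set.seed(8)
  n <- 120
  cl <- rnorm(n, 240, 60)
  proxy <- cl + rnorm(n, 0, 10)       # |r| with cl ~ 0.99
  other <- rnorm(n)
  y <- rbinom(n, 1, plogis(1 - 0.01 * cl))
  d <- data.frame(cl = cl, lam = rnorm(n, 3.5, 0.5), proxy = proxy,
                  other = other)
  m <- stepwise_logistic(d, y, c("proxy", "other"), screen_vars = c("cl",
                                                                    "lam"))
  expect_true("proxy" %in% m$screened_out)
})

test_that("group comparison reports medians, quartiles and p-values", {
  v <- data.frame(cl = c(1, 2, 3, 4, 5, 101, 102, 103, 104, 105))
  fl <- rep(c(FALSE, TRUE), each = 5)
  g <- group_compare(v, fl, params = "cl")
  expect_equal(g$median_flag, 103)
  expect_equal(g$q25_flag, 102)
  expect_equal(g$q75_flag, 104)
  expect_equal(g$median_ref, 3)
  expect_lt(g$p, 0.05)
  same <- group_compare(data.frame(x = rep(1:6, 2)),
                        rep(c(TRUE, FALSE), each = 6), params = "x")
  expect_equal(same$median_flag, same$median_ref)
  expect_equal(same$p, 1, tolerance = 1e-9)
  expect_error(group_compare(v, rep(TRUE, 10)), "non-empty")
})
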