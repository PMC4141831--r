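# Independent oracles used across test files.

# Adaptive Gauss-Hermite quadrature of a 1-D marginal -2 log-likelihood.
# q(eta) must be -2 log{p(y|eta) p(eta)}; nodes are centered at the mode
# and scaled by the local curvature.
agq_ofv <- function(q, lower = -3, upper = 3, n_nodes = 40) {
  opt <- stats::optimize(q, c(lower, upper), tol = 1e-12)
  h <- 1e-4
  H <- (q(opt$minimum + h) - 2 * opt$objective + q(opt$minimum - h)) / h^2
  s <- 1 / sqrt(0.5 * H)
  gh <- pracma::gaussHermite(n_nodes)
  x <- opt$minimum + sqrt(2) * s * gh$x
  lj <- vapply(x, function(e) -0.5 * q(e), numeric(1))
  m <- max(lj + gh$x^2)
  -2 * (log(sum(gh$w * exp(lj + gh$x^2 - m))) + m + log(sqrt(2) * s))
}

# Laplace approximation computed independently in R (same definition the
# package implements, via generic optimize + finite differences).
r_laplace_ofv <- function(q, lower = -3, upper = 3) {
  opt <- stats::optimize(q, c(lower, upper), tol = 1e-12)
  h <- 1e-5
  H <- (q(opt$minimum + h) - 2 * opt$objective + q(opt$minimum - h)) / h^2
  opt$objective - log(2 * pi) + log(0.5 * H)
}

# One-patient PK toy: repeated daily dosing, sparse sampling, additive
# error, log-normal clearance.  Returns data plus the conditional -2LL.
pk_toy <- function(seed, omega, sigma, n_obs = 9) {
  set.seed(seed)
  dose_t <- seq(0, 24 * 14, by = 24)
  dose_amt <- rep(2.5, length(dose_t))
  obs_t <- sort(runif(n_obs, 4, 300))
  cl_i <- 240 * exp(rnorm(1, 0, omega))
  y <- warfpkpd:::cpp_cp_profile(obs_t, dose_t, dose_amt, cl_i, 13.8, 2) +
    rnorm(n_obs, 0, sigma)
  q <- function(eta) {
    f <- warfpkpd:::cpp_cp_profile(obs_t, dose_t, dose_amt,
                                   240 * exp(eta), 13.8, 2)
    sum(log(2 * pi * sigma^2) + (y - f)^2 / sigma^2) +
      log(2 * pi * omega^2) + eta^2 / omega^2
  }
  ofv <- warfpkpd:::cpp_pk_laplace(dose_t, dose_amt,
                                   c(0L, length(dose_t)), obs_t, y,
                                   c(0L, as.integer(n_obs)), 240, 13.8, 2,
                                   omega, sigma, 0, FALSE)$ofv
  list(q = q, ofv = ofv)
}

# One-patient INR toy with the relative (interaction) error model.
inr_toy <- function(seed, omega, sigma, n_obs = 8) {
  set.seed(seed)
  npt <- runif(n_obs, 20, 110)
  npt0 <- 118; base <- 1.05; lam_t <- 3.48
  frac <- pmin(pmax((npt0 - npt) / npt0, 0), 1)
  lam_i <- lam_t * exp(rnorm(1, 0, omega))
  y <- (base + 5 * frac^lam_i) * (1 + rnorm(n_obs, 0, sigma))
  q <- function(eta) {
    f <- base + 5 * frac^(lam_t * exp(eta))
    v <- sigma^2 * f^2
    sum(log(2 * pi * v) + (y - f)^2 / v) +
      log(2 * pi * omega^2) + eta^2 / omega^2
  }
  ofv <- warfpkpd:::cpp_inr_laplace(npt, y, c(0L, as.integer(n_obs)),
                                    npt0, base, lam_t, 5, omega, sigma,
                                    0, FALSE)$ofv
  list(q = q, ofv = ofv)
}

# noise-free-ish degenerate cohort: omega = 0 everywhere, tiny sigma
degenerate_models <- function(sg = c(cp = 1e-4, npt = 0.02, inr = 1e-4)) {
  pk <- reference_popmodel("pk"); pk$omega[] <- 0; pk$sigma <- sg[["cp"]]
  npt <- reference_popmodel("npt"); npt$omega[] <- 0
  npt$sigma <- sg[["npt"]]
  inr <- reference_popmodel("inr"); inr$omega[] <- 0
  inr$sigma <- sg[["inr"]]
  list(pk = pk, npt = npt, inr = inr)
}
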