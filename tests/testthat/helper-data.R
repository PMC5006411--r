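# Shared fixtures and independent oracles, built in code.

table1_counts <- function() beitler_landis()
table1_data <- function() beitler_landis(expand = TRUE)

# Clustered dataset with a baseline covariate, a pure function of the seed;
# frozen reference values for it were computed with an independent GEE
# implementation.
cov_fixture <- function() {
  sp <- scenario_spec("identity", n_per_center = 20L, pi_c = 0.25,
                      true_rd = 0.10, icc = 0.05,
                      covariate_effect = "fifty_percent")
  simulate_trial(sp, seed = 4242)
}

# Finite-difference oracle for the delta-method SE of the average RD:
# recomputes the standardized RD from scratch (no package gradient code) and
# differentiates it numerically at the fitted coefficients.
fd_delta_se <- function(fit, h = 1e-6) {
  linkinv <- stats::make.link(fit$link)$linkinv
  z <- if (fit$covariate) fit$data$covariate else rep(0, nrow(fit$data))
  g <- function(theta) {
    gam <- if (length(theta) > 2) theta[3] else 0
    mean(linkinv(theta[1] + theta[2] + gam * z) - linkinv(theta[1] + gam * z))
  }
  th <- unname(fit$coefficients)
  grad <- vapply(seq_along(th), function(k) {
    e <- replace(numeric(length(th)), k, h)
    (g(th + e) - g(th - e)) / (2 * h)
  }, numeric(1))
  sqrt(drop(grad %*% fit$robust_cov %*% grad))
}

# One-way ANOVA (moment) estimator of the intraclass correlation of the
# outcomes, independent of the GEE machinery.
anova_icc <- function(data) {
  y <- data$outcome
  cl <- data$center
  nj <- tabulate(cl)
  J <- length(nj)
  n <- length(y)
  ybar_j <- tapply(y, cl, mean)
  ssb <- sum(nj * (ybar_j - mean(y))^2)
  ssw <- sum((y - ybar_j[cl])^2)
  msb <- ssb / (J - 1)
  msw <- ssw / (n - J)
  n0 <- (n - sum(nj^2) / n) / (J - 1)
  (msb - msw) / (msb + (n0 - 1) * msw)
}

all_gee_methods <- function() setdiff(rd_methods(), "unadjusted")
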