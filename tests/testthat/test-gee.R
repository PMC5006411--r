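# Frozen reference values computed with an independent exchangeable-GEE
# implementation (statsmodels 0.14, Exchangeable covariance) on the exact
# same data: coefficients, robust SEs and moment estimate of rho.
t1_oracle <- list(
  "binomial-identity" = list(coef = c(0.294410, 0.126248),
                             se = c(0.097700, 0.050762), rho = 0.216891),
  "poisson-identity"  = list(coef = c(0.295695, 0.125057),
                             se = c(0.097566, 0.049992), rho = 0.217511),
  "normal-identity"   = list(coef = c(0.293256, 0.127327),
                             se = c(0.097837, 0.051589), rho = 0.215609),
  "binomial-log"      = list(coef = c(-1.222782, 0.356846),
                             se = c(0.331851, 0.171836), rho = 0.216891),
  "poisson-log"       = list(coef = c(-1.218427, 0.352714),
                             se = c(0.329955, 0.167374), rho = 0.217511),
  "binomial-logit"    = list(coef = c(-0.874061, 0.553987),
                             se = c(0.470317, 0.232974), rho = 0.216891))

cov_oracle <- list(
  "binomial-identity" = list(coef = c(0.268472, 0.044271, 0.121224),
                             se = c(0.023126, 0.047928, 0.051392),
                             rho = 0.004871),
  "poisson-identity"  = list(coef = c(0.264594, 0.050727, 0.124874),
                             se = c(0.023776, 0.049409, 0.052099),
                             rho = 0.002201),
  "normal-identity"   = list(coef = c(0.272403, 0.038477, 0.119351),
                             se = c(0.022729, 0.046897, 0.051080),
                             rho = 0.007171),
  "binomial-log"      = list(coef = c(-1.279571, 0.095315, 0.336668),
                             se = c(0.077384, 0.137859, 0.128177),
                             rho = 0.005201),
  "poisson-log"       = list(coef = c(-1.293256, 0.117676, 0.342837),
                             se = c(0.079101, 0.141718, 0.128415),
                             rho = 0.002848),
  "binomial-logit"    = list(coef = c(-0.977923, 0.177321, 0.528232),
                             se = c(0.111557, 0.213997, 0.212641),
                             rho = 0.005037))

fit_by_label <- function(data, label, covariate = FALSE, ...) {
  fl <- strsplit(label, "-", fixed = TRUE)[[1]]
  fit_gee(data, fl[1], fl[2], covariate = covariate, ...)
}

test_that("all six models match an independent GEE implementation", {
  td <- table1_data()
  for (m in names(t1_oracle)) {
    fit <- fit_by_label(td, m)
    expect_true(fit$converged, info = m)
    expect_equal(unname(coef(fit)), t1_oracle[[m]]$coef, tolerance = 1e-4,
                 info = m)
    expect_equal(unname(sqrt(diag(vcov(fit)))), t1_oracle[[m]]$se,
                 tolerance = 1e-4, info = m)
    expect_lt(abs(fit$icc - t1_oracle[[m]]$rho), 2e-5, label = paste(m, "rho"))
    expect_equal(fit$robust_cov, t(fit$robust_cov))
  }
})

test_that("covariate-adjusted models match the independent implementation", {
  td <- cov_fixture()
  for (m in names(cov_oracle)) {
    fit <- fit_by_label(td, m, covariate = TRUE)
    expect_true(fit$converged, info = m)
    expect_equal(unname(coef(fit)), cov_oracle[[m]]$coef, tolerance = 1e-4,
                 info = m)
    expect_equal(unname(sqrt(diag(vcov(fit)))), cov_oracle[[m]]$se,
                 tolerance = 1e-4, info = m)
    expect_lt(abs(fit$icc - cov_oracle[[m]]$rho), 2e-5, label = paste(m, "rho"))
    expect_equal(fit$p, 2L)
  }
})

test_that("forcing independence recovers GLM / least-squares exactly", {
  td <- table1_data()
  ctrl <- gee_control(fix_rho = 0)

  f_logit <- fit_gee(td, "binomial", "logit", control = ctrl)
  g <- stats::glm(outcome ~ treatment, data = td, family = stats::binomial())
  expect_equal(unname(coef(f_logit)), unname(coef(g)), tolerance = 1e-7)

  f_norm <- fit_gee(td, "normal", "identity", control = ctrl)
  ls <- stats::lm(outcome ~ treatment, data = td)
  expect_equal(unname(coef(f_norm)), unname(coef(ls)), tolerance = 1e-10)
})

test_that("independence sandwich equals the cluster-robust covariance oracle", {
  td <- table1_data()
  f <- fit_gee(td, "binomial", "logit", control = gee_control(fix_rho = 0))
  g <- stats::glm(outcome ~ treatment, data = td, family = stats::binomial())
  v_or <- sandwich::vcovCL(g, cluster = td$center, type = "HC0",
                           cadjust = FALSE)
  expect_equal(unname(vcov(f)), unname(v_or), tolerance = 1e-8)
})

test_that("fits are invariant to center relabeling and record permutation", {
  td <- table1_data()
  ref <- fit_gee(td, "binomial", "identity")
  set.seed(31)
  perm <- sample(nrow(td))
  alt <- trial_data(paste0("z", rev(LETTERS)[as.integer(td$center)])[perm],
                    td$treatment[perm], td$outcome[perm])
  fit <- fit_gee(alt, "binomial", "identity")
  expect_equal(coef(fit), coef(ref), tolerance = 1e-10)
  expect_equal(unname(vcov(fit)), unname(vcov(ref)), tolerance = 1e-10)
  expect_equal(fit$icc, ref$icc, tolerance = 1e-10)
})

test_that("no between-center variation yields a near-zero ICC estimate", {
  sp <- scenario_spec("identity", pi_c = 0.25, true_rd = 0.10, icc = 0,
                      n_per_center = 100L)
  td <- simulate_trial(sp, seed = 77)
  fit <- fit_gee(td, "binomial", "identity")
  expect_lt(abs(fit$icc), 0.05)
})

test_that("GEE rho estimate recovers the generating ICC on average", {
  sp <- scenario_spec("identity", pi_c = 0.50, true_rd = 0.05, icc = 0.10,
                      n_per_center = 100L)
  rhos <- vapply(1:60, function(r) {
    td <- simulate_trial(sp, seed = derive_seed(5, 1, r))
    fit_gee(td, "binomial", "identity")$icc
  }, numeric(1))
  mcse <- stats::sd(rhos) / sqrt(length(rhos))
  expect_lt(abs(mean(rhos) - 0.10), max(3 * mcse, 0.01))
})

test_that("boundary-seeking log-binomial fits report non-convergence, not errors", {
  # treated arm all events: the unconstrained log-binomial optimum lies at a
  # fitted probability of 1
  td <- trial_data(center = rep(1:4, each = 10),
                   treatment = rep(rep(c(1, 0), each = 5), 4),
                   outcome = rep(c(rep(1, 5), rep(c(0, 1), length.out = 5)), 4))
  fit <- fit_gee(td, "binomial", "log")
  expect_s3_class(fit, "gee_fit")
  expect_false(fit$converged)
  expect_true(all(is.na(coef(fit))))
  expect_error(estimate_rd(fit), "converge")
  expect_error(predict_prob(fit, 1), "converged")
})

test_that("fitted probabilities come back on the response scale", {
  td <- table1_data()
  f_id <- fit_gee(td, "binomial", "identity")
  expect_equal(predict_prob(f_id, 1),
               unname(sum(coef(f_id))), tolerance = 1e-10)
  expect_equal(predict_prob(f_id, 0), unname(coef(f_id)[1]), tolerance = 1e-10)

  f_log <- fit_gee(td, "poisson", "log")
  expect_equal(predict_prob(f_log, 0), unname(exp(coef(f_log)[1])),
               tolerance = 1e-10)

  null_logit <- f_id
  null_logit$link <- "logit"
  null_logit$coefficients[] <- 0
  expect_equal(predict_prob(null_logit, 0), 0.5)
  expect_equal(predict_prob(null_logit, 1), 0.5)
})

test_that("structural misuse raises errors rather than silent fits", {
  td <- table1_data()
  expect_error(fit_gee(td, "normal", "log"), "unsupported")
  expect_error(fit_gee(td, "poisson", "logit"), "unsupported")
  expect_error(fit_gee(td, "binomial", "identity", covariate = TRUE),
               "covariate")
  single <- trial_data(center = 1:6, treatment = rep(c(0, 1), 3),
                       outcome = rep(c(0, 1), 3))
  expect_error(fit_gee(single, "binomial", "identity"), "pairs")
})
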