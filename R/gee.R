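#' Fitting control for GEE estimation
#'
#' @param max_iter iteration cap for the Fisher-scoring loop.
#' @param tol convergence tolerance: largest absolute coefficient change
#'   between successive iterations.
#' @param fix_rho if non-`NULL`, the working correlation is held at this
#'   value instead of being estimated (the value 0 gives the independence
#'   working model, used for cross-checks against ordinary GLM fits); the
#'   moment estimate is still reported.
#' @param max_halving maximum number of step-halvings used to keep fitted
#'   means inside the family's admissible range (not applied to the
#'   log-binomial model, see [fit_gee()]).
#' @return A list of class `gee_control`.
#' @export
gee_control <- function(max_iter = 100L, tol = 1e-6, fix_rho = NULL,
                        max_halving = 20L) {
  stopifnot(max_iter >= 1L, tol > 0, max_halving >= 0L)
  if (!is.null(fix_rho)) stopifnot(fix_rho > -1, fix_rho < 1)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 fix_rho = fix_rho, max_halving = as.integer(max_halving)),
            class = "gee_control")
}

family_variance <- function(family) {
  switch(family,
         binomial = function(mu) mu * (1 - mu),
         poisson  = function(mu) mu,
         normal   = function(mu) rep.int(1, length(mu)))
}

family_admissible <- function(family) {
  switch(family,
         binomial = function(mu) all(mu > 0 & mu < 1),
         poisson  = function(mu) all(mu > 0),
         normal   = function(mu) TRUE)
}

#' Fit a marginal model for clustered binary outcomes by GEE
#'
#' Solves the generalized estimating equations for a population-averaged mean
#' model `g(pi_ij) = alpha + beta * treatment (+ gamma * covariate)` under an
#' exchangeable working correlation (any two subjects in the same center
#' share correlation rho), by Fisher scoring with moment updates of the scale
#' and correlation parameters.  The coefficient covariance is the robust
#' (sandwich) estimator, consistent under misspecification of both the
#' working correlation and the outcome distribution — which is what licenses
#' the Poisson and normal families for Bernoulli outcomes.
#'
#' Six family/link combinations are supported for risk-difference work:
#' binomial, Poisson or normal family with identity link (the treatment
#' coefficient is the risk difference directly), binomial or Poisson family
#' with log link, and binomial with logit link (converted to the
#' risk-difference scale by [average_rd()]).
#'
#' Numerical failure is part of the object's contract, not an exception: if
#' the iteration does not meet `tol` within `max_iter`, produces non-finite
#' estimates, or visits fitted means outside the family's admissible range
#' that step-halving cannot repair, the fit is returned with
#' `converged = FALSE` so simulation code can count it.  For the log-binomial
#' model any iterate with a fitted mean at or above 1 is counted as
#' non-convergence outright (no step-halving rescue) — this model's fragility
#' near the probability boundary is a known property being measured, not a
#' defect to paper over.
#'
#' @param data a [trial_data] object.
#' @param family `"binomial"`, `"poisson"` or `"normal"`.
#' @param link `"identity"`, `"log"` or `"logit"` (logit only with binomial).
#' @param covariate include the baseline covariate in the mean model
#'   (requires a covariate column).
#' @param control a [gee_control()] list.
#' @return An object of class `gee_fit`: `coefficients` (named vector),
#'   `robust_cov` (sandwich covariance), `icc` (moment estimate of the
#'   exchangeable correlation), `scale` (Pearson dispersion), `converged`,
#'   `n_iter`, `n_clusters`, `p` (number of non-intercept regressors),
#'   `family`, `link`, `covariate`, and `data` (the fitted dataset).
#' @examples
#' td <- beitler_landis(expand = TRUE)
#' fit <- fit_gee(td, "binomial", "identity")
#' coef(fit)[["treatment"]]  # risk difference
#' fit$icc
#' @export
fit_gee <- function(data, family = c("binomial", "poisson", "normal"),
                    link = c("identity", "log", "logit"),
                    covariate = FALSE, control = gee_control()) {
  stopifnot(inherits(data, "trial_data"), inherits(control, "gee_control"))
  family <- match.arg(family)
  link <- match.arg(link)
  ok <- (link == "identity") ||
    (link == "log" && family %in% c("binomial", "poisson")) ||
    (link == "logit" && family == "binomial")
  if (!ok) stop("unsupported family/link combination: ", family, "/", link,
                call. = FALSE)
  if (covariate && is.null(data$covariate))
    stop("covariate = TRUE but the data has no covariate column", call. = FALSE)

  y <- data$outcome
  X <- if (covariate)
    cbind("(Intercept)" = 1, treatment = data$treatment,
          covariate = data$covariate)
  else cbind("(Intercept)" = 1, treatment = data$treatment)
  cl <- as.integer(data$center)
  nj <- tabulate(cl)
  pairs_tot <- sum(nj * (nj - 1) / 2)
  if (pairs_tot - ncol(X) <= 0)
    stop("too few within-center pairs to estimate the exchangeable ",
         "correlation", call. = FALSE)
  if (length(unique(data$treatment)) < 2L)
    stop("treatment indicator is constant; both arms required", call. = FALSE)

  strict <- (family == "binomial" && link == "log")
  eng <- gee_engine(y, X, cl, nj, family, link, control, strict)

  structure(c(eng, list(family = family, link = link, covariate = covariate,
                        n_clusters = length(nj), p = ncol(X) - 1L,
                        data = data)),
            class = "gee_fit")
}

# Independence-GLM starting values; NULL when the GLM errors, does not
# converge, or lands on an inadmissible boundary.
init_coefficients <- function(y, X, family, link) {
  fam <- switch(family,
                binomial = stats::binomial(link),
                poisson  = stats::poisson(link),
                normal   = stats::gaussian(link))
  g <- tryCatch(suppressWarnings(stats::glm.fit(X, y, family = fam)),
                error = function(e) NULL)
  if (is.null(g) || !g$converged || !all(is.finite(g$coefficients)))
    return(NULL)
  if (!family_admissible(family)(g$fitted.values)) return(NULL)
  g$coefficients
}

# Fisher-scoring GEE core.  Exploits the closed-form inverse of the
# compound-symmetry correlation matrix, R^{-1} = a I + b 11', so all
# cluster-wise sums reduce to rowsum() calls and no per-cluster loop or
# matrix inversion is needed.  The scale parameter cancels from both the
# scoring update and the sandwich, so it enters only the rho estimate.
gee_engine <- function(y, X, cl, nj, family, link, control, strict) {
  lk <- stats::make.link(link)
  vfun <- family_variance(family)
  admissible <- family_admissible(family)
  N <- length(y); q <- ncol(X)
  pairs_tot <- sum(nj * (nj - 1) / 2)
  rho_lo <- -1 / (max(nj) - 1) + 1e-4

  fail <- function(it) {
    cf <- rep(NA_real_, q); names(cf) <- colnames(X)
    list(coefficients = cf,
         robust_cov = matrix(NA_real_, q, q, dimnames = list(colnames(X), colnames(X))),
         icc = NA_real_, scale = NA_real_, converged = FALSE, n_iter = it)
  }

  # Initial coefficients from the independence GLM, the convention of
  # estimating-equation software.  Its unguarded IRLS is the first place the
  # log-binomial model hits the probability boundary; that counts as the
  # model failing to run.  For the other models a failed initializer falls
  # back to moment starting values built from the clamped arm rates, since
  # step-halving protects their iterations.
  beta <- init_coefficients(y, X, family, link)
  init_ok <- !is.null(beta) && all(is.finite(beta)) &&
    admissible(lk$linkinv(drop(X %*% beta)))
  if (!init_ok) {
    if (strict) return(fail(0L))
    x <- X[, 2L]
    clamp <- function(p) min(max(p, 1e-3), 1 - 1e-3)
    beta <- numeric(q)
    p0 <- clamp(mean(y[x == 0])); p1 <- clamp(mean(y[x == 1]))
    beta[1L] <- lk$linkfun(p0)
    beta[2L] <- lk$linkfun(p1) - lk$linkfun(p0)
  }
  eta <- drop(X %*% beta)
  mu <- lk$linkinv(eta)
  if (!admissible(mu)) return(fail(0L))

  est_rho <- function(e, phi) {
    t_j <- rowsum(e, cl)[, 1L]
    s_j <- rowsum(e * e, cl)[, 1L]
    r <- sum((t_j^2 - s_j) / 2) / phi / (pairs_tot - q)
    min(max(r, rho_lo), 0.999)
  }

  converged <- FALSE
  it <- 0L
  res <- tryCatch({
    repeat {
      it <- it + 1L
      v <- vfun(mu)
      e <- (y - mu) / sqrt(v)
      phi <- sum(e * e) / (N - q)
      rho <- if (is.null(control$fix_rho)) est_rho(e, phi) else control$fix_rho
      a <- 1 / (1 - rho)
      b_j <- -rho / ((1 - rho) * (1 + (nj - 1) * rho))
      U <- X * (lk$mu.eta(eta) / sqrt(v))
      S <- rowsum(U, cl)
      t_j <- rowsum(e, cl)[, 1L]
      B <- a * crossprod(U) + crossprod(S, S * b_j)
      score <- a * crossprod(U, e) + crossprod(S, b_j * t_j)
      delta <- drop(solve(B, score))
      step <- 1
      ok <- FALSE
      for (h in 0:control$max_halving) {
        cand <- beta + step * delta
        mu_c <- lk$linkinv(drop(X %*% cand))
        if (admissible(mu_c) && all(is.finite(mu_c))) { ok <- TRUE; break }
        if (strict) break
        step <- step / 2
      }
      if (!ok) break
      beta <- cand
      eta <- drop(X %*% beta)
      mu <- mu_c
      if (max(abs(step * delta)) < control$tol) { converged <- TRUE; break }
      if (it >= control$max_iter) break
    }
    if (!converged) return(fail(it))
    # final correlation, scale and sandwich at the solution
    v <- vfun(mu)
    e <- (y - mu) / sqrt(v)
    phi <- sum(e * e) / (N - q)
    icc <- est_rho(e, phi)
    rho <- if (is.null(control$fix_rho)) icc else control$fix_rho
    a <- 1 / (1 - rho)
    b_j <- -rho / ((1 - rho) * (1 + (nj - 1) * rho))
    U <- X * (lk$mu.eta(eta) / sqrt(v))
    S <- rowsum(U, cl)
    t_j <- rowsum(e, cl)[, 1L]
    B <- a * crossprod(U) + crossprod(S, S * b_j)
    G <- a * rowsum(U * e, cl) + S * (b_j * t_j)
    Binv <- solve(B)
    V <- Binv %*% crossprod(G) %*% Binv
    V <- (V + t(V)) / 2
    if (!all(is.finite(beta)) || !all(is.finite(V))) return(fail(it))
    names(beta) <- colnames(X)
    dimnames(V) <- list(colnames(X), colnames(X))
    list(coefficients = beta, robust_cov = V, icc = icc, scale = phi,
         converged = TRUE, n_iter = it)
  }, error = function(err) fail(it))
  res
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$robust_cov

#' @export
print.gee_fit <- function(x, ...) {
  cat("GEE fit (", x$family, " family, ", x$link,
      " link, exchangeable correlation)\n", sep = "")
  if (!x$converged) {
    cat("  DID NOT CONVERGE after", x$n_iter, "iterations\n")
    return(invisible(x))
  }
  print(round(x$coefficients, 5))
  cat(sprintf("  robust SEs: %s\n",
              paste(signif(sqrt(diag(x$robust_cov)), 4), collapse = ", ")))
  cat(sprintf("  ICC (rho) = %.4f   scale = %.4f   clusters = %d   iterations = %d\n",
              x$icc, x$scale, x$n_clusters, x$n_iter))
  invisible(x)
}

#' Fitted outcome probability under a counterfactual treatment assignment
#'
#' Evaluates the fitted mean model `g^{-1}(alpha + beta * treatment + gamma *
#' covariate)` on the probability scale.  For identity and log links the
#' value can fall outside `[0, 1]` — a documented drawback of those links —
#' and is returned as-is.
#'
#' @param fit a converged [fit_gee()] object.
#' @param treatment 0/1 (vectorized).
#' @param covariate 0/1 (vectorized), required iff the fit includes the
#'   covariate.
#' @return Numeric vector of fitted probabilities.
#' @export
predict_prob <- function(fit, treatment, covariate = NULL) {
  stopifnot(inherits(fit, "gee_fit"))
  if (!fit$converged)
    stop("cannot predict from a non-converged fit", call. = FALSE)
  if (fit$covariate && is.null(covariate))
    stop("this fit includes a covariate; supply its value", call. = FALSE)
  if (!all(treatment %in% c(0, 1))) stop("treatment must be 0/1", call. = FALSE)
  b <- fit$coefficients
  eta <- b[1L] + b[2L] * treatment
  if (fit$covariate) {
    if (!all(covariate %in% c(0, 1))) stop("covariate must be 0/1", call. = FALSE)
    eta <- eta + b[3L] * covariate
  }
  unname(stats::make.link(fit$link)$linkinv(eta))
}
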