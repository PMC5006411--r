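#' Small-sample correction of a cluster-robust standard error
#'
#' With few clusters the sandwich variance is biased downward.  The
#' degrees-of-freedom factor `J / (J - p - 1)` — `J` clusters, `p`
#' non-intercept regressors — is applied to the robust *variance*, i.e. the
#' standard error is multiplied by `sqrt(J / (J - p - 1))`.  This is the
#' standard DF-correction convention and is the reading under which published
#' corrected SEs and Wald intervals for the 8-center worked example
#' reconstruct exactly (the raw sandwich SE there is 0.051; times
#' `sqrt(8/6)` it gives the reported 0.059).
#'
#' @param se_raw uncorrected robust standard error(s).
#' @param J number of clusters (centers).
#' @param p number of regressors excluding the intercept.
#' @return Corrected standard error(s).
#' @examples
#' apply_small_sample_correction(0.0508, J = 8, p = 1)
#' @export
apply_small_sample_correction <- function(se_raw, J, p) {
  se_raw * sqrt(small_sample_factor(J, p))
}

#' @rdname apply_small_sample_correction
#' @export
small_sample_factor <- function(J, p) {
  if (J <= p + 1)
    stop("small-sample factor J/(J-p-1) undefined for J = ", J, ", p = ", p,
         call. = FALSE)
  J / (J - p - 1)
}

rd_estimate <- function(rd, se_raw, J, p, method, n_used, icc = NA_real_,
                        correct = TRUE) {
  se_corrected <- if (correct) apply_small_sample_correction(se_raw, J, p)
                  else se_raw
  if (method != "unadjusted" && abs(rd) > 1)
    warning("risk-difference estimate outside [-1, 1] (fitted probabilities ",
            "escape the unit interval under this link)", call. = FALSE)
  structure(list(rd = rd, se_raw = se_raw, se_corrected = se_corrected,
                 ci_low = rd - 1.96 * se_corrected,
                 ci_high = rd + 1.96 * se_corrected,
                 method = method, n_used = n_used, icc = icc),
            class = "rd_estimate")
}

#' @export
print.rd_estimate <- function(x, ...) {
  cat(sprintf("%s: RD = %.3f  SE = %.3f  95%% CI (%.3f, %.3f)\n",
              x$method, x$rd, x$se_corrected, x$ci_low, x$ci_high))
  invisible(x)
}

method_label <- function(fit) paste(fit$family, fit$link, sep = "-")

#' Risk difference from an identity-link GEE fit
#'
#' Under the identity link the treatment coefficient *is* the risk
#' difference, and its robust SE (small-sample corrected) gives the Wald
#' interval directly.
#'
#' @param fit a converged identity-link [fit_gee()] object.
#' @return An `rd_estimate`: `rd`, `se_raw`, `se_corrected`
#'   (`= se_raw * sqrt(J/(J-p-1))`), 95% Wald `ci_low`/`ci_high`, `method`,
#'   `n_used`, `icc`.
#' @examples
#' rd_from_identity(fit_gee(beitler_landis(expand = TRUE), "binomial", "identity"))
#' @export
rd_from_identity <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  if (fit$link != "identity")
    stop("rd_from_identity() requires an identity-link fit; use average_rd() ",
         "for log/logit links", call. = FALSE)
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  rd_estimate(rd = unname(fit$coefficients["treatment"]),
              se_raw = sqrt(fit$robust_cov["treatment", "treatment"]),
              J = fit$n_clusters, p = fit$p,
              method = method_label(fit), n_used = nrow(fit$data),
              icc = fit$icc)
}

#' Marginally standardized (average) risk difference
#'
#' For log- and logit-link models the treatment coefficient lives on the
#' relative-risk or odds-ratio scale.  The average risk difference
#' standardizes it to the probability scale over the analysis sample: each
#' subject's outcome probability is predicted twice — treatment set to 1 and
#' to 0, keeping the subject's own covariate value — and the differences are
#' averaged over all n subjects:
#' `RD = (1/n) * sum(pi_ij(1) - pi_ij(0))`.
#' The standard error comes from the delta method ([delta_se_average_rd()]),
#' then receives the small-sample correction.
#'
#' @param fit a converged log- or logit-link [fit_gee()] object.
#' @return An `rd_estimate` (see [rd_from_identity()]).
#' @examples
#' average_rd(fit_gee(beitler_landis(expand = TRUE), "binomial", "logit"))
#' @export
average_rd <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  if (!fit$link %in% c("log", "logit"))
    stop("average_rd() requires a log or logit link; identity-link fits ",
         "report the RD as the treatment coefficient (rd_from_identity)",
         call. = FALSE)
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  z <- if (fit$covariate) fit$data$covariate else rep(0L, nrow(fit$data))
  pi1 <- predict_prob(fit, 1, if (fit$covariate) z)
  pi0 <- predict_prob(fit, 0, if (fit$covariate) z)
  rd_estimate(rd = mean(pi1 - pi0),
              se_raw = delta_se_average_rd(fit),
              J = fit$n_clusters, p = fit$p,
              method = method_label(fit), n_used = nrow(fit$data),
              icc = fit$icc)
}

#' Delta-method standard error of the average risk difference
#'
#' First-order propagation of the robust coefficient covariance into the
#' averaged risk difference `g(theta) = mean(pi_ij(1) - pi_ij(0))`:
#' `SE = sqrt(grad' V grad)` with the gradient averaged over subjects.  Per
#' subject, writing `v_t = pi_t (1 - pi_t)`:
#' \describe{
#'   \item{log link}{`d/dalpha = pi1 - pi0`, `d/dbeta = pi1`,
#'     `d/dgamma = z (pi1 - pi0)`}
#'   \item{logit link}{`d/dalpha = v1 - v0`, `d/dbeta = v1`,
#'     `d/dgamma = z (v1 - v0)`}
#' }
#'
#' @param fit a converged log- or logit-link [fit_gee()] object.
#' @return The uncorrected delta-method standard error (a scalar).
#' @export
delta_se_average_rd <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  if (!fit$link %in% c("log", "logit"))
    stop("delta-method SE applies to log/logit links only", call. = FALSE)
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  z <- if (fit$covariate) fit$data$covariate else rep(0L, nrow(fit$data))
  pi1 <- predict_prob(fit, 1, if (fit$covariate) z)
  pi0 <- predict_prob(fit, 0, if (fit$covariate) z)
  if (fit$link == "log") {
    d_alpha <- pi1 - pi0
    d_beta <- pi1
  } else {
    v1 <- pi1 * (1 - pi1); v0 <- pi0 * (1 - pi0)
    d_alpha <- v1 - v0
    d_beta <- v1
  }
  grad <- c(mean(d_alpha), mean(d_beta))
  if (fit$covariate) grad <- c(grad, mean(z * d_alpha))
  var_rd <- drop(grad %*% fit$robust_cov %*% grad)
  if (var_rd < 0)
    stop("robust covariance produced a negative delta-method variance",
         call. = FALSE)
  sqrt(var_rd)
}

#' Risk difference from a fitted model, dispatching on link
#'
#' @param fit a converged [fit_gee()] object.
#' @return An `rd_estimate` via [rd_from_identity()] or [average_rd()].
#' @export
estimate_rd <- function(fit) {
  if (fit$link == "identity") rd_from_identity(fit) else average_rd(fit)
}

#' Unadjusted risk difference from the pooled 2x2 table
#'
#' The comparator analysis: pool all centers, ignore the covariate, and
#' compare raw proportions.  `RD = e1/n1 - e0/n0` with the Wald standard
#' error `sqrt(p1(1-p1)/n1 + p0(1-p0)/n0)` and `RD +/- 1.96 SE` interval.
#' No cluster adjustment and no small-sample correction apply
#' (`se_corrected == se_raw`).
#'
#' @param x a [trial_data] object, or the number of active-arm subjects `n1`.
#' @param e1,n0,e0 active-arm events, control-arm subjects and events, when
#'   `x` is given as a count.
#' @return An `rd_estimate` with `method = "unadjusted"`.
#' @examples
#' unadjusted_rd(beitler_landis(expand = TRUE))
#' unadjusted_rd(130, 55, 143, 47)
#' @export
unadjusted_rd <- function(x, e1 = NULL, n0 = NULL, e0 = NULL) {
  if (inherits(x, "trial_data")) {
    s <- summarize_2x2(x)
    n1 <- s[["n1"]]; e1 <- s[["e1"]]; n0 <- s[["n0"]]; e0 <- s[["e0"]]
  } else {
    n1 <- x
    stopifnot(is.numeric(n1), !is.null(e1), !is.null(n0), !is.null(e0))
  }
  if (n1 <= 0 || n0 <= 0)
    stop("both arms must be non-empty (n1 = ", n1, ", n0 = ", n0, ")",
         call. = FALSE)
  if (e1 < 0 || e0 < 0 || e1 > n1 || e0 > n0)
    stop("events must satisfy 0 <= e <= n in each arm", call. = FALSE)
  p1 <- e1 / n1; p0 <- e0 / n0
  se <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  if (se == 0)
    warning("degenerate Wald SE of 0 (boundary proportions in both arms)",
            call. = FALSE)
  rd_estimate(rd = p1 - p0, se_raw = se, J = NA, p = NA,
              method = "unadjusted", n_used = n1 + n0, correct = FALSE)
}

#' All methods of the package
#' @export
rd_methods <- function() c("binomial-identity", "poisson-identity",
                           "normal-identity", "binomial-log", "poisson-log",
                           "binomial-logit", "unadjusted")

fit_method <- function(data, method, covariate, control) {
  if (method == "unadjusted") return(unadjusted_rd(data))
  fl <- strsplit(method, "-", fixed = TRUE)[[1L]]
  fit <- fit_gee(data, family = fl[1L], link = fl[2L],
                 covariate = covariate, control = control)
  if (!fit$converged) return(structure(list(method = method, converged = FALSE),
                                       class = "rd_nonconverged"))
  estimate_rd(fit)
}

#' Risk-difference estimates from every method, side by side
#'
#' Fits each requested method to the same data and lays the results out one
#' row per method: point estimate, corrected SE, 95% Wald interval and the
#' estimated intracenter correlation (blank for the unadjusted method).
#' A GEE method that fails to converge yields an `NA` row rather than an
#' error.
#'
#' @param data a [trial_data] object.
#' @param methods subset of [rd_methods()].
#' @param covariate adjust the GEE models for the baseline covariate.
#' @param control a [gee_control()].
#' @return Data frame with columns
#'   `method, rd, se, ci_low, ci_high, icc, converged`.
#' @examples
#' rd_table(beitler_landis(expand = TRUE))
#' @export
rd_table <- function(data, methods = rd_methods(), covariate = FALSE,
                     control = gee_control()) {
  bad <- setdiff(methods, rd_methods())
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  rows <- lapply(methods, function(m) {
    est <- fit_method(data, m, covariate, control)
    if (inherits(est, "rd_nonconverged"))
      data.frame(method = m, rd = NA_real_, se = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, icc = NA_real_, converged = FALSE)
    else
      data.frame(method = m, rd = est$rd, se = est$se_corrected,
                 ci_low = est$ci_low, ci_high = est$ci_high,
                 icc = est$icc, converged = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
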