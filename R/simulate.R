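#' Define one clustered-trial simulation scenario
#'
#' A scenario fixes the true data-generating model for a multicenter trial
#' with a binary outcome: the true response function (additive risk, i.e.
#' identity link, or multiplicative risk, i.e. log link), the number of
#' centers and subjects per center, the control-arm outcome rate, the true
#' risk difference, the intracenter correlation rho, and whether a binary
#' baseline covariate (prevalence 0.3) raises risk by 50 percent.
#'
#' The defaults mirror a small-number-of-centers perinatal-trial setting:
#' 18 centers with treatment allocated by permuted blocks of four within
#' center, covariate prevalence 0.3, and between-center heterogeneity induced
#' by a normal random center effect whose variance is derived from rho (see
#' [derive_params()]).
#'
#' @param true_link `"identity"` or `"log"`.
#' @param n_centers number of centers J.
#' @param n_per_center subjects per center (scalar, or vector of length
#'   `n_centers`).
#' @param pi_c control-arm outcome rate, in (0, 1).
#' @param true_rd true risk difference, `pi(1) - pi(0)`.
#' @param icc intracenter correlation rho, in `[0, 1)`.
#' @param covariate_effect `"none"` or `"fifty_percent"` (a 50% risk
#'   increase: `gamma = 0.5 * pi_c` on the additive scale, `log(1.5)` on the
#'   multiplicative scale).
#' @return A list of class `scenario_spec`.
#' @examples
#' sp <- scenario_spec("identity", pi_c = 0.25, true_rd = 0.10, icc = 0.05)
#' derive_params(sp)
#' @export
scenario_spec <- function(true_link = c("identity", "log"), n_centers = 18L,
                          n_per_center = 10L, pi_c = 0.25, true_rd = 0.10,
                          icc = 0.05,
                          covariate_effect = c("none", "fifty_percent")) {
  true_link <- match.arg(true_link)
  covariate_effect <- match.arg(covariate_effect)
  if (!(pi_c > 0 && pi_c < 1)) stop("pi_c must be in (0, 1)", call. = FALSE)
  if (icc < 0 || icc >= 1) stop("icc must be in [0, 1)", call. = FALSE)
  if (n_centers < 2L) stop("at least 2 centers required", call. = FALSE)
  if (length(n_per_center) == 1L)
    n_per_center <- rep(as.integer(n_per_center), n_centers)
  if (length(n_per_center) != n_centers || any(n_per_center < 2L))
    stop("n_per_center must be a scalar or length-n_centers vector, all >= 2",
         call. = FALSE)
  sp <- structure(list(true_link = true_link, n_centers = as.integer(n_centers),
                       n_per_center = n_per_center, pi_c = pi_c,
                       true_rd = true_rd, icc = icc,
                       covariate_effect = covariate_effect),
                  class = "scenario_spec")
  derive_params(sp)  # validates admissibility at construction
  sp
}

#' Derive generating parameters from a scenario
#'
#' Converts the scenario's marginal quantities into link-scale coefficients
#' and the center-effect variance:
#' \describe{
#'   \item{identity link}{`alpha = pi_c`, `beta = true_rd`, `gamma = 0` or
#'     `0.5 * pi_c`; mean outcome rate `pi_bar = alpha + 0.5 beta +
#'     0.3 gamma` (half the subjects treated, covariate prevalence 0.3);
#'     center variance `sigma2 = rho * pi_bar * (1 - pi_bar)`.}
#'   \item{log link}{`alpha = log(pi_c)`, `gamma = 0` or `log(1.5)`;
#'     `beta = log(1 + RD / exp(alpha + 0.3 gamma))`, chosen so the marginal
#'     risk difference at covariate prevalence 0.3 equals `true_rd`;
#'     `pi_bar = exp(alpha + 0.5 beta + 0.3 gamma)`; `sigma2 = rho *
#'     (1 - pi_bar) / pi_bar` (delta-method transfer of the correlation to
#'     the log scale).}
#' }
#'
#' Construction fails when the cell with the highest risk (treated, covariate
#' present) already exceeds probability 1 at zero center effect, since no
#' rejection sampling could repair that.
#'
#' @param spec a [scenario_spec()].
#' @return List with `alpha`, `beta`, `gamma`, `pi_bar`, `sigma2`.
#' @export
derive_params <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_cov <- spec$covariate_effect == "fifty_percent"
  if (spec$true_link == "identity") {
    alpha <- spec$pi_c
    beta <- spec$true_rd
    gamma <- if (with_cov) 0.5 * spec$pi_c else 0
    pi_bar <- alpha + 0.5 * beta + 0.3 * gamma
    sigma2 <- spec$icc * pi_bar * (1 - pi_bar)
    top <- alpha + beta + gamma
  } else {
    alpha <- log(spec$pi_c)
    gamma <- if (with_cov) log(1.5) else 0
    beta <- log(1 + spec$true_rd / exp(alpha + 0.3 * gamma))
    pi_bar <- exp(alpha + 0.5 * beta + 0.3 * gamma)
    sigma2 <- spec$icc * (1 - pi_bar) / pi_bar
    top <- exp(alpha + beta + gamma)
  }
  if (with_cov && spec$true_link == "identity" &&
      1.5 * alpha + beta > 1)
    stop("inadmissible identity-link scenario: alpha*1.5 + beta = ",
         signif(1.5 * alpha + beta, 3), " > 1 in the treated, covariate-",
         "positive cell", call. = FALSE)
  if (top >= 1)
    stop("inadmissible scenario: outcome probability ", signif(top, 3),
         " >= 1 in the treated", if (with_cov) ", covariate-positive",
         " cell at zero center effect", call. = FALSE)
  if (pi_bar <= 0 || pi_bar >= 1)
    stop("average outcome probability outside (0, 1)", call. = FALSE)
  list(alpha = alpha, beta = beta, gamma = gamma, pi_bar = pi_bar,
       sigma2 = sigma2)
}

#' Stratified permuted-block treatment allocation
#'
#' Allocates treatment within one center using permuted blocks of size four
#' with two treated per block.  A trailing incomplete block of size r gets
#' `floor(r/2)` or `ceiling(r/2)` treated subjects, the extra one assigned by
#' a fair coin, so per-center arm sizes never differ by more than 1.
#' Consumes the current RNG state.
#'
#' @param n_j center size (>= 2).
#' @return Integer 0/1 vector of length `n_j`.
#' @export
block_randomize <- function(n_j) {
  if (n_j < 2L) stop("center size must be at least 2", call. = FALSE)
  n_full <- n_j %/% 4L
  r <- n_j %% 4L
  x <- unlist(lapply(seq_len(n_full), function(b) sample(c(1L, 1L, 0L, 0L))),
              use.names = FALSE)
  if (r > 0L) {
    k <- r %/% 2L + (r %% 2L == 1L && stats::runif(1) < 0.5)
    x <- c(x, sample(rep(c(1L, 0L), c(k, r - k))))
  }
  x
}

#' Simulate one clustered binary trial
#'
#' Generates a trial dataset from the scenario's true model.  Per center j:
#' treatment by [block_randomize()]; a Bernoulli(0.3) covariate per subject
#' (when the scenario has one); a random center effect `nu_j ~ N(0, sigma2)`;
#' subject probabilities `pi_ij = alpha + beta x + gamma z + nu_j` (identity)
#' or `exp(alpha + beta x + gamma z + nu_j)` (log).  If any subject's
#' probability falls outside (0, 1), a fresh `nu_j` is drawn for that center
#' — keeping the allocation and covariates fixed — until all probabilities
#' are strictly interior.  Outcomes are then Bernoulli(`pi_ij`).
#'
#' The rejection step truncates the normal center-effect distribution, which
#' slightly shrinks the realized between-center variance when `sigma2` is
#' large; this is a property of the design being studied, left as-is.
#'
#' @param spec a [scenario_spec()].
#' @param seed optional integer seed set before generation, making the
#'   dataset a pure function of `(spec, seed)`.
#' @param max_redraw cap on center-effect redraws per center.
#' @return A [trial_data] object; the true subject probabilities are attached
#'   as `attr(, "pi")` and the generating parameters as `attr(, "params")`.
#' @examples
#' td <- simulate_trial(scenario_spec("identity"), seed = 1)
#' td
#' @export
simulate_trial <- function(spec, seed = NULL, max_redraw = 10000L) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  par <- derive_params(spec)
  sd_nu <- sqrt(par$sigma2)
  with_cov <- spec$covariate_effect == "fifty_percent"
  J <- spec$n_centers
  linkinv <- if (spec$true_link == "identity") identity else exp
  center <- rep(seq_len(J), spec$n_per_center)
  x <- unlist(lapply(spec$n_per_center, block_randomize), use.names = FALSE)
  z <- if (with_cov) stats::rbinom(length(x), 1L, 0.3) else NULL
  eta_fix <- par$alpha + par$beta * x +
    (if (with_cov) par$gamma * z else 0)
  pi <- numeric(length(x))
  for (j in seq_len(J)) {
    idx <- which(center == j)
    for (draw in seq_len(max_redraw)) {
      nu <- stats::rnorm(1L, 0, sd_nu)
      pij <- linkinv(eta_fix[idx] + nu)
      if (all(pij > 0 & pij < 1)) break
      if (draw == max_redraw)
        stop("no admissible center effect found for center ", j,
             " after ", max_redraw, " redraws (", spec$true_link,
             " link, pi_c = ", spec$pi_c, ", rd = ", spec$true_rd,
             ", icc = ", spec$icc, ")", call. = FALSE)
    }
    pi[idx] <- pij
  }
  y <- stats::rbinom(length(pi), 1L, pi)
  out <- trial_data(center, x, y, covariate = z)
  attr(out, "pi") <- pi
  attr(out, "params") <- par
  out
}
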