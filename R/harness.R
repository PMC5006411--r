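#' Derive a replicate seed from the master seed
#'
#' Deterministic mixing of (master seed, scenario index, replicate index)
#' into a 31-bit seed, so every replicate of every scenario is independently
#' reproducible and results do not depend on execution order or worker count.
#'
#' @param master master seed (integer).
#' @param scenario scenario index (integer >= 1).
#' @param replicate replicate index (integer >= 1).
#' @return An integer seed in `[1, 2^31 - 20]`.
#' @export
derive_seed <- function(master, scenario, replicate) {
  m <- 2147483629
  s <- (as.double(master) %% m) * 48271 + as.double(scenario) * 1299709 +
    as.double(replicate) * 7919
  as.integer(s %% m) + 1L
}

#' Analyze one simulated replicate with several methods
#'
#' Applies each requested method to one dataset.  GEE non-convergence is
#' recorded, never raised, so the harness can tally convergence rates; the
#' closed-form unadjusted method always converges.
#'
#' @param data a [trial_data] object.
#' @param true_rd the scenario's true risk difference, used for the
#'   covered-flag.
#' @param methods subset of [rd_methods()].
#' @param covariate adjust GEE models for the covariate.
#' @param control a [gee_control()].
#' @return Data frame, one row per method: `method, converged, rd, se,
#'   ci_low, ci_high, covered` (closed-interval inclusion of `true_rd`).
#' @export
run_replicate <- function(data, true_rd, methods = rd_methods(),
                          covariate = !is.null(data$covariate),
                          control = gee_control()) {
  rows <- lapply(methods, function(m) {
    est <- tryCatch(fit_method(data, m, covariate, control),
                    error = function(e) structure(list(method = m),
                                                  class = "rd_nonconverged"))
    if (inherits(est, "rd_nonconverged"))
      data.frame(method = m, converged = FALSE, rd = NA_real_, se = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, covered = NA)
    else
      data.frame(method = m, converged = TRUE, rd = est$rd,
                 se = est$se_corrected, ci_low = est$ci_low,
                 ci_high = est$ci_high,
                 covered = est$ci_low <= true_rd & true_rd <= est$ci_high)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run one simulation scenario
#'
#' Generates `n_reps` independently seeded datasets from the scenario,
#' analyzes each with every method, and aggregates the three performance
#' measures: convergence rate, bias (mean of estimate minus truth) and 95% CI
#' coverage.  Bias and coverage are computed over the replicates for which
#' that specific method converged.
#'
#' @param spec a [scenario_spec()].
#' @param n_reps number of replicate datasets.
#' @param methods subset of [rd_methods()].
#' @param seed master seed (replicate seeds come from [derive_seed()]).
#' @param scenario_id index of this scenario within a grid (enters the seed
#'   derivation).
#' @param control a [gee_control()].
#' @return Data frame of class `scenario_result`, one row per method:
#'   `method, convergence_rate, bias, coverage, mcse_bias, n_converged,
#'   n_reps`, with the spec attached as `attr(, "spec")`.
#' @examples
#' run_scenario(scenario_spec("identity"), n_reps = 20, seed = 1)
#' @export
run_scenario <- function(spec, n_reps, methods = rd_methods(), seed = 1L,
                         scenario_id = 1L, control = gee_control()) {
  stopifnot(inherits(spec, "scenario_spec"), n_reps >= 1L)
  covariate <- spec$covariate_effect != "none"
  per_rep <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    td <- simulate_trial(spec, seed = derive_seed(seed, scenario_id, r))
    per_rep[[r]] <- run_replicate(td, spec$true_rd, methods,
                                  covariate = covariate, control = control)
  }
  all <- do.call(rbind, per_rep)
  rows <- lapply(methods, function(m) {
    sub <- all[all$method == m, ]
    conv <- sub$converged
    est <- sub$rd[conv]
    cov <- sub$covered[conv]
    data.frame(method = m,
               convergence_rate = mean(conv),
               bias = if (length(est)) mean(est - spec$true_rd) else NA_real_,
               coverage = if (length(cov)) mean(cov) else NA_real_,
               mcse_bias = if (length(est) > 1)
                 stats::sd(est) / sqrt(length(est)) else NA_real_,
               n_converged = sum(conv), n_reps = n_reps)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  class(out) <- c("scenario_result", "data.frame")
  out
}

#' Build the factorial grid of simulation scenarios
#'
#' Cartesian product of the factor levels; the defaults give the full
#' 432-scenario design (2 links x 4 risk differences x 3 control rates x
#' 3 ICCs x 3 center sizes x 2 covariate settings) with 18 centers.
#'
#' @param true_link,true_rd,pi_c,icc,n_per_center,covariate_effect factor
#'   levels; each must be non-empty.
#' @param n_centers number of centers (held fixed across the grid).
#' @return Data frame with one row per scenario and a `scenario_id` column.
#' @examples
#' nrow(factorial_grid())  # 432
#' @export
factorial_grid <- function(true_link = c("identity", "log"),
                           true_rd = c(0, 0.05, 0.10, 0.15),
                           pi_c = c(0.10, 0.25, 0.50),
                           icc = c(0.01, 0.05, 0.10),
                           n_per_center = c(10L, 50L, 100L),
                           covariate_effect = c("none", "fifty_percent"),
                           n_centers = 18L) {
  args <- list(true_link = true_link, true_rd = true_rd, pi_c = pi_c,
               icc = icc, n_per_center = n_per_center,
               covariate_effect = covariate_effect)
  for (nm in names(args))
    if (length(args[[nm]]) == 0L)
      stop("empty factor level list: ", nm, call. = FALSE)
  g <- expand.grid(args, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g$n_centers <- as.integer(n_centers)
  g$scenario_id <- seq_len(nrow(g))
  g
}

#' Run a grid of scenarios
#'
#' Applies [run_scenario()] to every row of a [factorial_grid()], collecting
#' results in one long data frame keyed by the scenario factors.  A scenario
#' whose generator is infeasible (inadmissible parameters) is reported with
#' an `error` column set, without aborting the rest of the grid.
#'
#' @param grid a [factorial_grid()] data frame.
#' @param n_reps replicates per scenario.
#' @param methods subset of [rd_methods()].
#' @param seed master seed.
#' @param control a [gee_control()].
#' @param progress print a line per scenario.
#' @return Long data frame: grid factors + per-method performance columns.
#' @export
run_grid <- function(grid, n_reps, methods = rd_methods(), seed = 1L,
                     control = gee_control(), progress = FALSE) {
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gi <- grid[i, ]
    res <- tryCatch({
      sp <- scenario_spec(gi$true_link, n_centers = gi$n_centers,
                          n_per_center = gi$n_per_center, pi_c = gi$pi_c,
                          true_rd = gi$true_rd, icc = gi$icc,
                          covariate_effect = gi$covariate_effect)
      run_scenario(sp, n_reps, methods, seed = seed,
                   scenario_id = gi$scenario_id, control = control)
    }, error = function(e)
      data.frame(method = methods, convergence_rate = NA_real_,
                 bias = NA_real_, coverage = NA_real_, mcse_bias = NA_real_,
                 n_converged = NA_integer_, n_reps = n_reps,
                 error = conditionMessage(e)))
    if (is.null(res$error)) res$error <- NA_character_
    key <- gi[rep(1L, nrow(res)),
              c("scenario_id", "true_link", "true_rd", "pi_c", "icc",
                "n_per_center", "covariate_effect")]
    out[[i]] <- cbind(key, res)
    if (progress)
      message(sprintf("scenario %d/%d done", i, nrow(grid)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reshape grid results to one row per metric
#'
#' @param results output of [run_grid()] (or a single [run_scenario()] result
#'   bound to its factors).
#' @return Long data frame with columns `...factors..., method, metric,
#'   value, n_converged, n_reps`; metrics are `convergence_rate`, `bias`,
#'   `coverage`.
#' @export
summarize_results <- function(results) {
  stopifnot(nrow(results) >= 1L)
  keys <- intersect(c("scenario_id", "true_link", "true_rd", "pi_c", "icc",
                      "n_per_center", "covariate_effect", "method",
                      "n_converged", "n_reps"), names(results))
  long <- lapply(c("convergence_rate", "bias", "coverage"), function(m) {
    cbind(results[keys], metric = m, value = results[[m]])
  })
  out <- do.call(rbind, long)
  ord <- c(setdiff(keys, c("n_converged", "n_reps")), "metric", "value",
           "n_converged", "n_reps")
  out <- out[c(ord)]
  rownames(out) <- NULL
  out
}

#' Faceted performance plot
#'
#' Plots one performance metric against center size, one line per method,
#' faceted by control rate and ICC.  Requires ggplot2.
#'
#' @param results output of [run_grid()].
#' @param metric `"coverage"`, `"bias"` or `"convergence_rate"`.
#' @return A ggplot object.
#' @export
plot_performance <- function(results, metric = c("coverage", "bias",
                                                 "convergence_rate")) {
  metric <- match.arg(metric)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_performance() requires the ggplot2 package", call. = FALSE)
  df <- results[!is.na(results[[metric]]), ]
  df$metric_value <- df[[metric]]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(n_per_center),
                                        y = metric_value,
                                        colour = method,
                                        group = interaction(method, true_rd))) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_grid(pi_c ~ icc, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "subjects per center", y = metric)
  if (metric == "coverage")
    p <- p + ggplot2::geom_hline(yintercept = 0.95, linetype = 2)
  if (metric == "bias")
    p <- p + ggplot2::geom_hline(yintercept = 0, linetype = 2)
  p
}
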