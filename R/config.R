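#' Read a simulation scenario from YAML
#'
#' The file's keys mirror the [scenario_spec()] arguments (`true_link`,
#' `n_centers`, `n_per_center`, `pi_c`, `true_rd`, `icc`,
#' `covariate_effect`); absent keys fall back to the defaults.
#'
#' @param path YAML file.
#' @return A [scenario_spec()].
#' @export
read_scenario_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("true_link", "n_centers", "n_per_center", "pi_c", "true_rd",
             "icc", "covariate_effect")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown scenario field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  do.call(scenario_spec, cfg)
}

#' Read factorial-grid factor levels from YAML
#'
#' Keys mirror the [factorial_grid()] arguments; each value is a list of
#' levels.  Absent keys fall back to the full default design.
#'
#' @param path YAML file.
#' @return A [factorial_grid()] data frame.
#' @export
read_grid_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("true_link", "true_rd", "pi_c", "icc", "n_per_center",
             "covariate_effect", "n_centers")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown grid field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(cfg$icc) && any(unlist(cfg$icc) < 0 | unlist(cfg$icc) >= 1))
    stop("invalid icc level(s): ", paste(cfg$icc, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$pi_c) && any(unlist(cfg$pi_c) <= 0 | unlist(cfg$pi_c) >= 1))
    stop("invalid pi_c level(s): ", paste(cfg$pi_c, collapse = ", "),
         call. = FALSE)
  do.call(factorial_grid, lapply(cfg, unlist))
}
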