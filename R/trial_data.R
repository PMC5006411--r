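#' Construct a clustered binary trial dataset
#'
#' A `trial_data` object holds one record per subject of a two-arm trial run
#' across several centers: the center the subject was enrolled at, a binary
#' treatment indicator, an optional binary baseline covariate, and the binary
#' outcome.  All estimation functions in the package operate on this class.
#'
#' Center labels are opaque: they are stored as a factor in first-appearance
#' order and every estimator is invariant to relabeling (the exchangeable
#' working correlation does not distinguish centers by name).  Missing values
#' are rejected rather than imputed.
#'
#' @param center vector of center identifiers (at least 2 distinct values).
#' @param treatment binary treatment indicator, 0 = control, 1 = active.
#' @param outcome binary outcome, 0/1.
#' @param covariate optional binary baseline covariate, 0/1, or `NULL` when
#'   the analysis model carries no covariate.
#' @return A data frame of class `trial_data` with columns `center` (factor),
#'   `treatment`, `outcome` and, when supplied, `covariate` (integer 0/1).
#' @examples
#' td <- trial_data(center = rep(1:2, each = 4),
#'                  treatment = rep(c(0, 1), 4),
#'                  outcome = c(0, 1, 0, 0, 1, 1, 0, 1))
#' summarize_2x2(td)
#' @export
trial_data <- function(center, treatment, outcome, covariate = NULL) {
  n <- length(center)
  if (n == 0L) stop("empty trial data", call. = FALSE)
  if (length(treatment) != n || length(outcome) != n)
    stop("center, treatment and outcome must have equal length", call. = FALSE)
  if (!is.null(covariate) && length(covariate) != n)
    stop("covariate must have the same length as the other columns", call. = FALSE)
  check_binary(treatment, "treatment")
  check_binary(outcome, "outcome")
  if (!is.null(covariate)) check_binary(covariate, "covariate")
  center <- factor(center, levels = unique(as.character(center)))
  if (anyNA(center)) stop("missing center identifier", call. = FALSE)
  if (nlevels(center) < 2L)
    stop("at least 2 distinct centers are required (found ",
         nlevels(center), ")", call. = FALSE)
  df <- data.frame(center = center,
                   treatment = as.integer(treatment),
                   outcome = as.integer(outcome))
  if (!is.null(covariate)) df$covariate <- as.integer(covariate)
  class(df) <- c("trial_data", "data.frame")
  df
}

check_binary <- function(x, name) {
  if (anyNA(x))
    stop("missing value in column '", name, "' at row ",
         which(is.na(x))[1L], call. = FALSE)
  bad <- which(!(x %in% c(0, 1)))
  if (length(bad))
    stop("non-binary value in column '", name, "' at row ", bad[1L],
         " (", x[bad[1L]], ")", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.trial_data <- function(x, ...) {
  J <- nlevels(x$center)
  cat("Clustered binary trial data: ", nrow(x), " subjects in ", J,
      " centers", if (!is.null(x$covariate)) ", with baseline covariate",
      "\n", sep = "")
  s <- summarize_2x2(x)
  cat(sprintf("  active  %d/%d (%.3f)   control %d/%d (%.3f)\n",
              s["e1"], s["n1"], s["e1"] / s["n1"],
              s["e0"], s["n0"], s["e0"] / s["n0"]))
  invisible(x)
}

#' Read subject-level trial data from CSV
#'
#' Reads one-record-per-subject data.  Column names are configurable through
#' `columns`; the file must have a header.  A covariate column is used only
#' if it is named in the mapping and present in the file.
#'
#' @param path path to a CSV file.
#' @param columns named character vector mapping the roles `center`,
#'   `treatment`, `outcome` and optionally `covariate` to column names in the
#'   file.
#' @return A [trial_data] object, records in file order.
#' @export
read_subject_csv <- function(path,
                             columns = c(center = "center",
                                         treatment = "treatment",
                                         covariate = "covariate",
                                         outcome = "outcome")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (role in c("center", "treatment", "outcome")) {
    if (is.na(columns[role]))
      stop("column mapping must name a '", role, "' column", call. = FALSE)
    if (!columns[role] %in% names(df))
      stop("missing column '", columns[role], "' (role: ", role, ") in ",
           path, call. = FALSE)
  }
  cov <- NULL
  if (!is.na(columns["covariate"]) && columns["covariate"] %in% names(df))
    cov <- df[[columns["covariate"]]]
  trial_data(center = df[[columns["center"]]],
             treatment = df[[columns["treatment"]]],
             outcome = df[[columns["outcome"]]],
             covariate = cov)
}

#' Center-by-arm event count table
#'
#' Validates a table with one row per (center, arm) cell giving the number of
#' events and the number of subjects, the aggregated representation commonly
#' printed for multicenter binary-outcome trials.
#'
#' @param df data frame with columns `center`, `arm` (`"active"`/`"control"`,
#'   case-insensitive), `events`, `total`.
#' @return The validated data frame with class `center_counts`.
#' @export
center_counts <- function(df) {
  need <- c("center", "arm", "events", "total")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df$arm <- tolower(as.character(df$arm))
  if (!all(df$arm %in% c("active", "control")))
    stop("arm must be 'active' or 'control'", call. = FALSE)
  if (anyNA(df$events) || anyNA(df$total) ||
      any(df$events < 0) || any(df$total < 1) ||
      any(df$events != round(df$events)) || any(df$total != round(df$total)))
    stop("events must be non-negative integers and total positive integers",
         call. = FALSE)
  if (any(df$events > df$total)) {
    i <- which(df$events > df$total)[1L]
    stop("events > total for center ", df$center[i], ", ", df$arm[i],
         " arm", call. = FALSE)
  }
  if (anyDuplicated(df[c("center", "arm")]))
    stop("duplicated (center, arm) cell", call. = FALSE)
  df <- df[c("center", "arm", "events", "total")]
  class(df) <- c("center_counts", "data.frame")
  df
}

#' Read a center-by-arm count table from CSV
#'
#' @param path CSV with columns `center,arm,events,total`.
#' @return A [center_counts] table.
#' @export
read_count_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  center_counts(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Expand a count table to subject level
#'
#' Each (center, arm) cell of `events`/`total` becomes `events` records with
#' outcome 1 and `total - events` records with outcome 0; the active arm gets
#' treatment 1, control gets 0.  No covariate column is produced (count
#' tables carry none).
#'
#' @param counts a [center_counts] table (or a data frame coercible to one).
#' @return A [trial_data] object whose per-cell counts equal the input.
#' @export
expand_counts <- function(counts) {
  counts <- if (inherits(counts, "center_counts")) counts else center_counts(counts)
  reps <- counts$total
  center <- rep(as.character(counts$center), reps)
  treatment <- rep(as.integer(counts$arm == "active"), reps)
  outcome <- unlist(lapply(seq_len(nrow(counts)), function(i)
    rep(c(1L, 0L), c(counts$events[i], counts$total[i] - counts$events[i]))),
    use.names = FALSE)
  trial_data(center, treatment, outcome)
}

#' Aggregate subject-level data back to a count table
#'
#' Inverse of [expand_counts()]: tallies events and totals per (center, arm)
#' cell, rows ordered by center first appearance with active before control.
#'
#' @param data a [trial_data] object.
#' @return A [center_counts] table.
#' @export
aggregate_counts <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  key <- interaction(data$center, data$treatment, drop = TRUE)
  ev <- tapply(data$outcome, key, sum)
  tot <- tapply(data$outcome, key, length)
  parts <- strsplit(names(ev), ".", fixed = TRUE)
  cen <- vapply(parts, function(p) paste(p[-length(p)], collapse = "."), "")
  trt <- vapply(parts, function(p) p[length(p)], "")
  out <- data.frame(center = cen,
                    arm = ifelse(trt == "1", "active", "control"),
                    events = as.integer(ev), total = as.integer(tot),
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$center, levels(data$center)),
                   out$arm != "active"), ]
  rownames(out) <- NULL
  center_counts(out)
}

#' Pooled 2x2 summary of a trial
#'
#' Collapses the data over centers (and any covariate) into the four counts
#' used by the unadjusted analysis.
#'
#' @param data a [trial_data] object.
#' @return Named integer vector `c(n1, e1, n0, e0)`: subjects and events in
#'   the active arm, then in the control arm.
#' @export
summarize_2x2 <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  n1 <- sum(data$treatment == 1L); n0 <- sum(data$treatment == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both arms must be non-empty for a 2x2 summary (active n=", n1,
         ", control n=", n0, ")", call. = FALSE)
  c(n1 = n1, e1 = sum(data$outcome[data$treatment == 1L]),
    n0 = n0, e0 = sum(data$outcome[data$treatment == 0L]))
}

#' The Beitler & Landis 8-center infection trial
#'
#' Center-by-arm success counts from a randomized multicenter trial of an
#' active drug against control for curing an infection: 8 centers, 273
#' subjects, with success rates varying from 0 to 86 percent across centers.
#' A standard worked example for clustered binary data with few clusters.
#'
#' @param expand if `TRUE`, return the subject-level expansion instead of the
#'   count table.
#' @return A [center_counts] table (default) or a [trial_data] object.
#' @examples
#' beitler_landis()
#' @export
beitler_landis <- function(expand = FALSE) {
  path <- system.file("extdata", "beitler_landis_counts.csv",
                      package = "rdgee", mustWork = TRUE)
  counts <- read_count_csv(path)
  if (expand) expand_counts(counts) else counts
}
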