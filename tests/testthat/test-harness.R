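test_that("replicate seeds are deterministic, distinct and 31-bit", {
  s <- derive_seed(1, 1, 1)
  expect_identical(s, derive_seed(1, 1, 1))
  expect_true(s >= 1 && s < 2^31)
  grid <- expand.grid(m = c(1, 2), sc = 1:5, r = 1:20)
  seeds <- mapply(derive_seed, grid$m, grid$sc, grid$r)
  expect_equal(anyDuplicated(seeds), 0)
})

test_that("one replicate yields one disposition per method", {
  sp <- scenario_spec("identity", pi_c = 0.25, true_rd = 0.10, icc = 0.05)
  td <- simulate_trial(sp, seed = 42)
  res <- run_replicate(td, true_rd = 0.10)
  expect_equal(res$method, rd_methods())
  expect_true(res$converged[res$method == "unadjusted"])
  conv <- res[res$converged, ]
  expect_equal(conv$covered,
               conv$ci_low <= 0.10 & 0.10 <= conv$ci_high)
  expect_true(all(is.na(res$rd[!res$converged])))
})

test_that("scenario runs are reproducible and condition on convergence", {
  sp <- scenario_spec("identity", pi_c = 0.25, true_rd = 0.10, icc = 0.05,
                      n_per_center = 10L)
  a <- run_scenario(sp, n_reps = 30, seed = 5, scenario_id = 3)
  b <- run_scenario(sp, n_reps = 30, seed = 5, scenario_id = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(
    as.data.frame(run_scenario(sp, n_reps = 30, seed = 6, scenario_id = 3)),
    as.data.frame(a)))

  expect_equal(a$convergence_rate[a$method == "unadjusted"], 1)
  expect_true(all(a$coverage >= 0 & a$coverage <= 1, na.rm = TRUE))
  expect_equal(a$n_converged, as.integer(round(a$convergence_rate * 30)))
})

test_that("the factorial design enumerates the full grid", {
  expect_equal(nrow(factorial_grid()), 432)
  expect_equal(nrow(factorial_grid(true_link = "identity")), 216)
  expect_equal(nrow(factorial_grid(true_link = "log", true_rd = 0.1,
                                   pi_c = 0.25, icc = 0.05,
                                   n_per_center = 10,
                                   covariate_effect = "none")), 1)
  expect_error(factorial_grid(icc = numeric(0)), "empty factor")
})

test_that("grid execution isolates infeasible scenarios", {
  grid <- factorial_grid(true_link = "identity", true_rd = c(0.10, 0.45),
                         pi_c = 0.60, icc = 0.05, n_per_center = 10,
                         covariate_effect = "none")
  res <- run_grid(grid, n_reps = 5, seed = 2,
                  methods = c("binomial-identity", "unadjusted"))
  ok <- res[res$true_rd == 0.10, ]
  bad <- res[res$true_rd == 0.45, ]          # 0.60 + 0.45 > 1: infeasible
  expect_true(all(is.na(ok$error)))
  expect_true(all(!is.na(bad$error)))
  expect_true(all(is.na(bad$convergence_rate)))
  expect_true(all(ok$n_converged[ok$method == "unadjusted"] == 5))
})

test_that("results reshape to one row per scenario, method and metric", {
  grid <- factorial_grid(true_link = "identity", true_rd = 0.10, pi_c = 0.25,
                         icc = c(0.01, 0.05), n_per_center = 10,
                         covariate_effect = "none")
  res <- run_grid(grid, n_reps = 4, seed = 9)
  long <- summarize_results(res)
  expect_equal(nrow(long), 2 * length(rd_methods()) * 3)
  expect_setequal(unique(long$metric),
                  c("convergence_rate", "bias", "coverage"))
  expect_true(all(c("pi_c", "icc", "method", "value") %in% names(long)))
})

test_that("scenario and grid YAML configs round-trip", {
  sc_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("true_link: log", "pi_c: 0.25", "true_rd: 0.1",
               "icc: 0.05", "n_per_center: 10",
               "covariate_effect: fifty_percent"), sc_path)
  sp <- read_scenario_yaml(sc_path)
  expect_s3_class(sp, "scenario_spec")
  expect_equal(sp$pi_c, 0.25)
  expect_equal(sp$n_centers, 18L)

  writeLines("true_links: [log]", sc_path)
  expect_error(read_scenario_yaml(sc_path), "unknown scenario field")

  gr_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("true_link: [identity]", "true_rd: [0, 0.1]",
               "pi_c: [0.25]", "icc: [0.01, 0.05]",
               "n_per_center: [10]", "covariate_effect: [none]"), gr_path)
  expect_equal(nrow(read_grid_yaml(gr_path)), 4)

  writeLines(c("icc: [-0.1]"), gr_path)
  expect_error(read_grid_yaml(gr_path), "icc")
})

test_that("the command-line wrapper analyzes the packaged fixture", {
  cli <- system.file("cli", "rdgee.R", package = "rdgee")
  fixture <- system.file("extdata", "beitler_landis_counts.csv",
                         package = "rdgee")
  out <- withr::local_tempfile(fileext = ".csv")
  rscript <- file.path(R.home("bin"), "Rscript")

  status <- system2(rscript, c(cli, "analyze", "--input", fixture,
                               "--out", out),
                    stdout = TRUE, stderr = TRUE)
  expect_null(attr(status, "status"))
  tab <- utils::read.csv(out, comment.char = "#")
  expect_equal(nrow(tab), 7)
  expect_equal(round(tab$rd[tab$method == "unadjusted"], 3), 0.094)

  bad <- suppressWarnings(
    system2(rscript, c(cli, "analyze", "--input", fixture,
                       "--methods", "nope"), stdout = TRUE, stderr = TRUE))
  expect_equal(attr(bad, "status"), 2)
})
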