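# Config parsing, artifact writing, provenance, and the profile exporter.

write_tiny_config <- function(path, ..., mcic = NULL) {
  cfg <- list(formulations = list("sc", "sl"),
              doses_mg = list(sc = list(2), sl = list(30)),
              cv_levels = list(0.3),
              n_subjects = 12, seed = 314, t_end_min = 90, dt_min = 1)
  extra <- list(...)
  cfg[names(extra)] <- extra
  if (!is.null(mcic)) cfg$mcic <- mcic
  yaml::write_yaml(cfg, path)
  path
}

test_that("the shipped default configuration parses into the study design", {
  cfg <- read_scenario_config(system.file("extdata", "default_scenario.yaml",
                                          package = "apopkpd"))
  expect_s3_class(cfg$grid, "scenario_grid")
  expect_equal(cfg$grid$doses_mg, list(sc = c(1, 2, 3, 4),
                                       sl = c(20, 30, 40, 50)))
  expect_equal(cfg$grid$cv_levels, c(0.15, 0.30, 0.45))
  expect_equal(cfg$grid$n_subjects, 500L)
  expect_equal(cfg$grid$mcic, 3.25)
  expect_length(cfg$overrides, 0)
})

test_that("unknown configuration keys and parameters fail loudly", {
  p <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_subjects = 5, typo_key = 1), p)
  expect_error(read_scenario_config(p), "typo_key")
  p2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(parameters = list(sc = list(pk = list(zz = 1)))), p2)
  expect_error(read_scenario_config(p2), "unknown pk parameter")
})

test_that("simulate_study writes tables, profiles and provenance metadata", {
  cfgfile <- write_tiny_config(tempfile(fileext = ".yaml"))
  out <- file.path(tempdir(), "study_out")
  study <- simulate_study(cfgfile, out_dir = out, plots = FALSE, quiet = TRUE)
  expect_length(study$cells, 2)
  expect_true(file.exists(file.path(out, "summary_cv0.3.csv")))
  expect_true(file.exists(file.path(out, "subjects_sc_2_mg_cv0.3.csv")))
  expect_true(file.exists(file.path(out, "population_sl_30_mg_cv0.3.csv")))
  expect_true(file.exists(file.path(out, "profiles_sl_30_mg_cv0.3.csv")))
  meta <- yaml::read_yaml(file.path(out, "run_metadata.yaml"))
  expect_equal(meta$master_seed, 314)
  expect_equal(meta$n_subjects, 12)
  # rerunning from the same config reproduces the summary byte for byte
  out2 <- file.path(tempdir(), "study_out2")
  simulate_study(cfgfile, out_dir = out2, plots = FALSE, quiet = TRUE)
  expect_identical(readLines(file.path(out, "summary_cv0.3.csv")),
                   readLines(file.path(out2, "summary_cv0.3.csv")))
  # missing time_to_response is an empty field, never 0
  subj <- read.csv(file.path(out, "subjects_sc_2_mg_cv0.3.csv"))
  expect_true(all(is.na(subj$time_to_response) |
                    subj$time_to_response > 0))
  unlink(c(out, out2), recursive = TRUE)
})

test_that("raising the response threshold changes only the response endpoints", {
  cfg1 <- write_tiny_config(tempfile(fileext = ".yaml"))
  cfg2 <- write_tiny_config(tempfile(fileext = ".yaml"), mcic = 3.5)
  o1 <- file.path(tempdir(), "mcic_a")
  o2 <- file.path(tempdir(), "mcic_b")
  s1 <- simulate_study(cfg1, out_dir = o1, plots = FALSE, quiet = TRUE)
  s2 <- simulate_study(cfg2, out_dir = o2, plots = FALSE, quiet = TRUE)
  a <- s1$cells[[1]]$subjects
  b <- s2$cells[[1]]$subjects
  expect_identical(a$cmax, b$cmax)
  expect_identical(a$tmax, b$tmax)
  expect_identical(a$auc_0_90, b$auc_0_90)
  expect_identical(a$max_change, b$max_change)
  expect_false(identical(a$response_duration, b$response_duration))
  unlink(c(o1, o2), recursive = TRUE)
})

test_that("parameter overrides are applied, validated and logged", {
  p <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(formulations = list("sc"),
                        doses_mg = list(sc = list(1)),
                        cv_levels = list(0), n_subjects = 1,
                        parameters = list(sc = list(pk = list(ka = 20)))), p)
  cfg <- read_scenario_config(p)
  expect_equal(cfg$params$sc$pk$ka, 20)
  expect_equal(cfg$overrides, "sc.pk.ka")
})

test_that("the typical-subject profile export reproduces the closed-form peak", {
  path <- tempfile(fileext = ".csv")
  profile_table("sc", 1, path = path)
  tab <- read.csv(path)
  expect_named(tab, c("time_min", "cp", "ce", "d_updrs"))
  expect_equal(max(tab$cp), 5.21, tolerance = 1e-3)
  expect_equal(tab$cp[1], 0)
  sl <- profile_table("sl", 4)
  expect_true(all(sl$cp >= 0) && sl$cp[1] == 0)
  expect_gt(min(profile_table("sc", 4)$d_updrs), -24.3)
  expect_lt(min(profile_table("sc", 4)$d_updrs), 0)
  expect_error(profile_table("iv", 1))
})

test_that("the command-line wrapper script ships with the package", {
  cli <- system.file("cli", "apopkpd.R", package = "apopkpd")
  expect_true(nzchar(cli))
  expect_true(any(grepl("simulate_study", readLines(cli))))
})
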