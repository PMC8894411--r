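test_that("convert_table appends calculated version and flags degenerate rows", {
  angles <- tibble::tibble(
    hip_id = c("a", "b", "c"),
    ci_deg = c(50.0, 45, 90),
    si_deg = c(11.3, 45, 10)
  )
  out <- convert_table(angles)
  expect_equal(out$tv_calc_deg[1], 13.3947, tolerance = 0.01)
  expect_equal(out$tv_calc_deg[2], 45)
  expect_true(is.na(out$tv_calc_deg[3]))
  expect_equal(out$status, c("ok", "ok", "degenerate"))
  expect_error(convert_table(tibble::tibble(x = 1)), class = "femver_error_io")
})

test_that("angle summaries report mean, sample SD and range", {
  s <- summarize_angles(tibble::tibble(v = c(2, 2, 2)))
  expect_equal(unlist(s[1, c("mean", "sd", "min", "max")], use.names = FALSE),
               c(2, 0, 2, 2))
  s <- summarize_angles(tibble::tibble(v = c(1, 2, 3)))
  expect_equal(unlist(s[1, c("mean", "sd", "min", "max")], use.names = FALSE),
               c(2, 1, 1, 3))
  co <- sample_orientations(cohort_spec(n = 50000, seed = 14))
  s <- summarize_angles(co)
  m <- oracle_truncnorm_moments(50, 9, 26.1, 72)
  expect_equal(s$mean[s$angle == "ci_true"], m$mean, tolerance = 0.005)
  expect_equal(s$sd[s$angle == "ci_true"], m$sd, tolerance = 0.02)
})

test_that("noise-free orthogonal study shows the algorithm introduces no error", {
  cfg <- study_config(spec = cohort_spec(n = 500, seed = 5), sigma = 0,
                      misalignment = 0, seed = 5)
  rep <- suppressMessages(run_validation_study(cfg))
  mvc <- rep$agreement[rep$agreement$series == "manual_vs_calculated", ]
  expect_equal(mvc$icc, 1)
  expect_equal(mvc$median_abs_diff, 0, tolerance = 1e-9)
  expect_equal(mvc$bias, 0, tolerance = 1e-9)
})

test_that("agreement degrades monotonically with noise and misalignment", {
  med_at <- function(sigma, delta) {
    cfg <- study_config(spec = cohort_spec(n = 4000, seed = 17), sigma = sigma,
                        misalignment = delta, replicates = 2, seed = 17)
    rep <- suppressMessages(run_validation_study(cfg))
    ag <- rep$agreement
    list(
      icc_mvc = mean(ag$icc[ag$series == "manual_vs_calculated"]),
      mad_mvc = mean(ag$median_abs_diff[ag$series == "manual_vs_calculated"]),
      icc_non = mean(ag$icc[ag$series == "orthogonal_vs_nonorthogonal"]),
      mad_non = mean(ag$median_abs_diff[ag$series == "orthogonal_vs_nonorthogonal"])
    )
  }
  by_sigma <- lapply(c(0.5, 2, 4), med_at, delta = 0)
  expect_true(all(diff(sapply(by_sigma, `[[`, "icc_mvc")) < 0))
  expect_true(all(diff(sapply(by_sigma, `[[`, "mad_mvc")) > 0))
  by_delta <- lapply(c(0, 4, 8), function(d) med_at(1, d))
  expect_true(all(diff(sapply(by_delta, `[[`, "icc_non")) < 0))
  expect_true(all(diff(sapply(by_delta, `[[`, "mad_non")) > 0))
})

test_that("the study is reproducible and writes its report and log", {
  outdir <- withr::local_tempdir()
  cfg <- study_config(spec = cohort_spec(n = 800, seed = 20), sigma = 1.2,
                      misalignment = 5, outdir = outdir, seed = 20)
  rep1 <- run_validation_study(cfg)
  rep2 <- run_validation_study(study_config(spec = cohort_spec(n = 800, seed = 20),
                                            sigma = 1.2, misalignment = 5, seed = 20))
  expect_equal(rep1$agreement, rep2$agreement)
  expect_true(file.exists(file.path(outdir, "agreement.csv")))
  expect_true(file.exists(file.path(outdir, "angle_summary.csv")))
  log <- readLines(file.path(outdir, "study_log.txt"))
  expect_true(any(grepl("^seed 20$", log)))
  expect_true(any(grepl("^sigma 1.2", log)))
  back <- readr::read_csv(file.path(outdir, "agreement.csv"), show_col_types = FALSE)
  expect_equal(back$icc, rep1$agreement$icc, tolerance = 1e-12)
})

test_that("angle tables and config files round-trip through the readers", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_angles(tibble::tibble(hip_id = "h1", ci_deg = 50, si_deg = 11.3), path)
  df <- read_angles(path)
  expect_equal(df$ci_deg, 50)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("hip_id,ci_deg", "h1,50"), bad)
  expect_error(read_angles(bad), class = "femver_error_io")
  nonnum <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("hip_id,ci_deg,si_deg", "h1,50,eleven"), nonnum)
  expect_error(read_angles(nonnum), class = "femver_error_io")

  cfgfile <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# study settings", "n = 500", "delta = 5", "outdir = report"), cfgfile)
  cfg <- read_config(cfgfile)
  expect_identical(cfg$n, 500L)
  expect_identical(cfg$delta, 5L)
  expect_identical(cfg$outdir, "report")
  badcfg <- withr::local_tempfile(fileext = ".cfg")
  writeLines("just words", badcfg)
  expect_error(read_config(badcfg), class = "femver_error_io")
})
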