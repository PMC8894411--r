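#' Configuration of the synthetic validation study
#'
#' @param spec A [cohort_spec()] for the simulated cohort.
#' @param sigma Measurement-noise SD in degrees, or `NULL` (default) to
#'   calibrate it so the manual-vs-calculated median absolute difference of
#'   the transverse version equals `noise_target`.
#' @param noise_target Calibration target, degrees (default 1.3, the reported
#'   validity figure). Ignored when `sigma` is given.
#' @param misalignment Sagittal-plane rotation for the non-orthogonal series,
#'   degrees (default 5, i.e. views meeting at 85 degrees).
#' @param replicates Number of independent replicate cohorts (>= 1).
#' @param outdir Output directory for CSV reports and a parameter log, or
#'   `NULL` to skip writing.
#' @param seed Master seed; replicate cohorts and noise draws derive their
#'   seeds from it.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(spec = cohort_spec(), sigma = NULL, noise_target = 1.3,
                         misalignment = 5, replicates = 1L, outdir = NULL,
                         seed = spec$seed) {
  if (replicates < 1) abort("`replicates` must be >= 1.", class = "femver_error_spec")
  if (abs(misalignment) >= 45) {
    abort("`misalignment` must satisfy |delta| < 45 degrees.", class = "femver_error_spec")
  }
  if (!is.null(sigma) && (!is.numeric(sigma) || sigma < 0)) {
    abort("`sigma` must be NULL or a non-negative number.", class = "femver_error_spec")
  }
  structure(list(spec = spec, sigma = sigma, noise_target = noise_target,
                 misalignment = misalignment, replicates = as.integer(replicates),
                 outdir = outdir, seed = as.integer(seed)),
            class = "study_config")
}

#' Append the calculated transverse version to an angle table
#'
#' Applies the tangent-product equation row-wise to a table of measured
#' coronal and sagittal inclinations, the biplanar-radiograph use case: an
#' AP view gives `ci_deg`, a lateral view gives `si_deg`, and the transverse
#' version — otherwise requiring an axial view — is calculated. Rows with
#' degenerate inputs (CI within 0.01 degrees of 0 or 90, or SI at a tangent
#' pole) are flagged in a `status` column and get `NA`, never a silently huge
#' value.
#'
#' @param angles A data frame with numeric columns `ci_deg` and `si_deg`
#'   (degrees); other columns pass through.
#' @return The input tibble with `tv_calc_deg` and `status` (`"ok"` or
#'   `"degenerate"`) appended.
#' @examples
#' convert_table(data.frame(hip_id = "a", ci_deg = 50.0, si_deg = 11.3))
#' @export
convert_table <- function(angles) {
  if (!all(c("ci_deg", "si_deg") %in% names(angles))) {
    abort("`angles` must contain numeric columns `ci_deg` and `si_deg`.",
          class = "femver_error_io")
  }
  ci <- angles$ci_deg
  si <- angles$si_deg
  if (!is.numeric(ci) || !is.numeric(si)) {
    abort("`ci_deg` and `si_deg` must be numeric (degrees).", class = "femver_error_io")
  }
  ok <- !is.na(ci) & !is.na(si) &
    ci > DEG_TOL & ci < 90 - DEG_TOL & abs(si) < 90 - DEG_TOL
  tv <- rep(NA_real_, length(ci))
  if (any(ok)) tv[ok] <- tv_from_ci_si(ci[ok], si[ok])
  out <- as_tibble(angles)
  out$tv_calc_deg <- tv
  out$status <- ifelse(ok, "ok", "degenerate")
  out
}

#' Per-angle summaries in the mean +/- SD (range) format
#'
#' @param cohort A cohort tibble; all numeric angle columns are summarised.
#' @return A tibble with one row per angle column: `angle`, `mean`, `sd`
#'   (sample SD), `min`, `max`, `n`.
#' @export
summarize_angles <- function(cohort) {
  if (nrow(cohort) == 0) abort("`cohort` is empty.", class = "femver_error_spec")
  num <- dplyr::select(cohort, dplyr::where(is.numeric))
  tidyr::pivot_longer(num, dplyr::everything(),
                      names_to = "angle", values_to = "value") |>
    dplyr::group_by(.data$angle) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     min = min(.data$value), max = max(.data$value),
                     n = dplyr::n(), .groups = "drop")
}

#' Run the end-to-end synthetic validation study
#'
#' For each replicate: draw a cohort of true orientations, add calibrated (or
#' fixed-sigma) measurement noise on the orthogonal series and on the
#' non-orthogonal sagittal series, calculate the transverse version from each
#' measured pair, and compute agreement statistics for the two comparisons of
#' the reference validation design:
#' \describe{
#'   \item{`manual_vs_calculated`}{noisy manually measured TV against TV
#'     calculated from the noisy (CI, SI) pair — the validity analysis.}
#'   \item{`orthogonal_vs_nonorthogonal`}{calculated TV from the orthogonal
#'     series against calculated TV from the non-orthogonal series — the
#'     out-of-plane error analysis.}
#' }
#'
#' @param config A [study_config()].
#' @return An object of class `"study_report"`: a list with `agreement`
#'   (tibble, one row per replicate x series), `angle_summary` (per-replicate
#'   angle summaries), `sigma` (noise SD used) and `config`. When
#'   `config$outdir` is set, `agreement.csv`, `angle_summary.csv` and
#'   `study_log.txt` are written there.
#' @export
run_validation_study <- function(config) {
  if (!inherits(config, "study_config")) {
    abort("`config` must be a <study_config>.", class = "femver_error_spec")
  }
  sigma <- config$sigma
  if (is.null(sigma)) {
    sigma <- calibrate_noise(config$spec, config$noise_target,
                             seed = config$seed + 90000L)$sigma
  }

  one_rep <- function(r) {
    spec_r <- config$spec
    spec_r$seed <- config$seed + (r - 1L)
    cohort <- sample_orientations(spec_r)
    noisy <- apply_noise(cohort, noise_model(sigma, seed = config$seed + 10000L + r),
                         misalignment = config$misalignment)
    agreement <- dplyr::bind_rows(
      dplyr::mutate(agreement_report(noisy, "tv_meas", "tv_calc", model = "mixed"),
                    series = "manual_vs_calculated"),
      dplyr::mutate(agreement_report(noisy, "tv_calc", "tv_nonorth_calc", model = "mixed"),
                    series = "orthogonal_vs_nonorthogonal")
    )
    agreement$replicate <- r
    summary <- summarize_angles(noisy)
    summary$replicate <- r
    list(agreement = agreement, summary = summary)
  }

  reps <- lapply(seq_len(config$replicates), one_rep)
  report <- structure(
    list(
      agreement = dplyr::bind_rows(lapply(reps, `[[`, "agreement")) |>
        dplyr::relocate("replicate", "series"),
      angle_summary = dplyr::bind_rows(lapply(reps, `[[`, "summary")) |>
        dplyr::relocate("replicate"),
      sigma = sigma,
      config = config
    ),
    class = "study_report"
  )
  if (!is.null(config$outdir)) write_study_report(report, config$outdir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Synthetic validation study: n = %d hips x %d replicate(s), sigma = %.2f deg, misalignment = %.1f deg\n\n",
              x$config$spec$n, x$config$replicates, x$sigma, x$config$misalignment))
  # presentation rounding only: 0.1 degrees for angles, 0.01 for ICC
  shown <- dplyr::mutate(
    x$agreement,
    dplyr::across(c("icc", "icc_ci_low", "icc_ci_high"), ~ round(.x, 2)),
    dplyr::across(c("bias", "loa_low", "loa_high", "median_abs_diff",
                    "mad_iqr_low", "mad_iqr_high"), ~ round(.x, 1))
  )
  print(as.data.frame(shown[, c("replicate", "series", "icc", "icc_ci_low",
                                "icc_ci_high", "median_abs_diff", "mad_iqr_low",
                                "mad_iqr_high", "bias", "loa_low", "loa_high")]),
        row.names = FALSE)
  invisible(x)
}

#' @method tidy study_report
#' @export
tidy.study_report <- function(x, ...) x$agreement

#' @method glance study_report
#' @export
glance.study_report <- function(x, ...) {
  tibble(n = x$config$spec$n, replicates = x$config$replicates,
         sigma = x$sigma, misalignment = x$config$misalignment,
         seed = x$config$seed)
}

write_study_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$agreement, file.path(outdir, "agreement.csv"))
  readr::write_csv(report$angle_summary, file.path(outdir, "angle_summary.csv"))
  cfg <- report$config
  log_lines <- c(
    sprintf("femver %s", as.character(packageVersion("femver"))),
    sprintf("timestamp %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed %d", cfg$seed),
    sprintf("n %d", cfg$spec$n),
    sprintf("replicates %d", cfg$replicates),
    sprintf("sigma %.6f", report$sigma),
    sprintf("noise_target %s", ifelse(is.null(cfg$sigma), format(cfg$noise_target), "fixed-sigma")),
    sprintf("misalignment %.3f", cfg$misalignment),
    sprintf("ci_mean %.3f ci_sd %.3f ci_min %.3f ci_max %.3f",
            cfg$spec$ci_mean, cfg$spec$ci_sd, cfg$spec$ci_min, cfg$spec$ci_max),
    sprintf("tv_mean %.3f tv_sd %.3f tv_min %.3f tv_max %.3f",
            cfg$spec$tv_mean, cfg$spec$tv_sd, cfg$spec$tv_min, cfg$spec$tv_max)
  )
  writeLines(log_lines, file.path(outdir, "study_log.txt"))
  invisible(report)
}
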