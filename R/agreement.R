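ratings_matrix <- function(data, ...) {
  dots <- rlang::enquos(...)
  if (length(dots) > 0) {
    data <- dplyr::select(data, !!!dots)
  } else {
    data <- dplyr::select(data, dplyr::where(is.numeric))
  }
  m <- as.matrix(data)
  if (anyNA(m)) abort("Ratings must be complete: no missing values.", class = "femver_error_domain")
  m
}

#' Intraclass correlation for absolute agreement, ICC(A,1)
#'
#' Single-rater absolute-agreement ICC from the two-way ANOVA decomposition
#' (subject, rater and residual mean squares), with the F-distribution 95%
#' confidence interval. The point estimator is the same under the two-way
#' random and two-way mixed models; `model` records which interpretation the
#' analysis carries (random for intra-observer repeats, mixed for
#' method-validity and inter-observer comparisons).
#'
#' @param data A data frame whose rating columns (one per rater or
#'   measurement sitting, one row per subject) are selected by `...`; with no
#'   selection, all numeric columns are used.
#' @param ... <[`tidy-select`][dplyr::dplyr_tidy_select]> rating columns.
#' @param model `"mixed"` or `"random"`; recorded in the result.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `"femver_icc"`: a list with `icc`,
#'   `icc_ci_low`, `icc_ci_high`, the mean squares, `n` subjects, `k` raters
#'   and `model`. Has [tidy()] and [glance()] methods.
#' @examples
#' d <- data.frame(a = c(1, 2, 3), b = c(2, 3, 4))
#' icc_absolute_agreement(d, a, b, model = "mixed")
#' @export
icc_absolute_agreement <- function(data, ..., model = c("mixed", "random"),
                                   conf_level = 0.95) {
  model <- match.arg(model)
  m <- ratings_matrix(data, ...)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3) abort("At least 3 subjects are required.", class = "femver_error_samplesize")
  if (k < 2) abort("At least 2 raters/measurements per subject are required.",
                   class = "femver_error_samplesize")

  grand <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  if (var(rowm) < .Machine$double.eps) {
    abort("Between-subject variance is zero: the ICC is undefined.",
          class = "femver_error_undefined")
  }
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sse <- sum((m - outer(rowm, colm, "+") + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  if (1 - icc < 1e-12) {
    lo <- hi <- icc  # perfect agreement: degenerate interval
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  }

  structure(list(icc = icc, icc_ci_low = lo, icc_ci_high = hi,
                 msr = msr, msc = msc, mse = mse,
                 n = n, k = k, model = model, conf_level = conf_level),
            class = "femver_icc")
}

#' @export
print.femver_icc <- function(x, ...) {
  cat(sprintf("ICC(A,1), two-way %s model: %.3f (%d%% CI %.3f-%.3f), n = %d subjects, k = %d\n",
              x$model, x$icc, round(100 * x$conf_level), x$icc_ci_low, x$icc_ci_high,
              x$n, x$k))
  invisible(x)
}

#' @method tidy femver_icc
#' @export
tidy.femver_icc <- function(x, ...) {
  tibble(term = "icc_a1", estimate = x$icc,
         conf.low = x$icc_ci_low, conf.high = x$icc_ci_high, model = x$model)
}

#' @method glance femver_icc
#' @export
glance.femver_icc <- function(x, ...) {
  tibble(icc = x$icc, icc_ci_low = x$icc_ci_low, icc_ci_high = x$icc_ci_high,
         msr = x$msr, msc = x$msc, mse = x$mse, n = x$n, k = x$k, model = x$model)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' @param data A data frame of paired measurements.
#' @param a,b <[`tidy-select`][dplyr::dplyr_tidy_select]> the two measurement
#'   columns (differences are `a - b`).
#' @return An object of class `"femver_ba"` with `bias` (mean difference),
#'   `loa_low`/`loa_high` (`bias -/+ 1.96 * SD` of the differences, sample
#'   SD), `sd_diff`, `n`, and the per-pair means and differences for
#'   plotting. Has [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' d <- data.frame(x = c(2, 4, 6), y = c(1, 2, 3))
#' bland_altman(d, x, y)
#' @export
bland_altman <- function(data, a, b) {
  av <- dplyr::pull(data, {{ a }})
  bv <- dplyr::pull(data, {{ b }})
  if (length(av) < 2) abort("At least 2 pairs are required.", class = "femver_error_samplesize")
  if (anyNA(av) || anyNA(bv)) abort("Paired measurements must be complete.",
                                    class = "femver_error_domain")
  d <- av - bv
  bias <- mean(d)
  sdd <- sd(d)
  if (sdd == 0) {
    inform("bland_altman: zero difference SD; limits of agreement collapse to the bias.")
  }
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 n = length(d),
                 data = tibble(mean = (av + bv) / 2, diff = d)),
            class = "femver_ba")
}

#' @export
print.femver_ba <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, 95%% limits of agreement (%.3f, %.3f), n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' @method tidy femver_ba
#' @export
tidy.femver_ba <- function(x, ...) {
  tibble(bias = x$bias, loa_low = x$loa_low, loa_high = x$loa_high,
         sd_diff = x$sd_diff, n = x$n)
}

#' @method glance femver_ba
#' @export
glance.femver_ba <- function(x, ...) tidy(x)

#' Median absolute difference with interquartile range
#'
#' Median and 25th/75th percentiles (linear-interpolation rule, the default
#' quantile type) of `|a - b|`.
#'
#' @inheritParams bland_altman
#' @return A one-row tibble with `median_abs_diff`, `mad_iqr_low`,
#'   `mad_iqr_high`, `n`.
#' @export
median_abs_diff <- function(data, a, b) {
  av <- dplyr::pull(data, {{ a }})
  bv <- dplyr::pull(data, {{ b }})
  if (length(av) < 1) abort("At least 1 pair is required.", class = "femver_error_samplesize")
  d <- abs(av - bv)
  q <- quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble(median_abs_diff = q[2], mad_iqr_low = q[1], mad_iqr_high = q[3],
         n = length(d))
}

#' Full agreement report for one pair of measurement methods
#'
#' Combines the absolute-agreement ICC (with 95% CI), Bland-Altman bias and
#' limits of agreement, and the median absolute difference with IQR into one
#' row, the reporting format of a method-comparison table.
#'
#' @inheritParams bland_altman
#' @param model ICC model label, `"mixed"` (default) or `"random"`.
#' @return A one-row tibble: `icc`, `icc_ci_low`, `icc_ci_high`, `bias`,
#'   `loa_low`, `loa_high`, `median_abs_diff`, `mad_iqr_low`, `mad_iqr_high`,
#'   `n`, `model`.
#' @export
agreement_report <- function(data, a, b, model = c("mixed", "random")) {
  model <- match.arg(model)
  av <- dplyr::pull(data, {{ a }})
  bv <- dplyr::pull(data, {{ b }})
  pair <- tibble(a = av, b = bv)
  fit <- icc_absolute_agreement(pair, model = model)
  ba <- bland_altman(pair, a, b)
  mad <- median_abs_diff(pair, a, b)
  tibble(icc = fit$icc, icc_ci_low = fit$icc_ci_low, icc_ci_high = fit$icc_ci_high,
         bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
         median_abs_diff = mad$median_abs_diff,
         mad_iqr_low = mad$mad_iqr_low, mad_iqr_high = mad$mad_iqr_high,
         n = nrow(pair), model = model)
}
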