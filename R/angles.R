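#' @keywords internal
deg2rad <- function(x) x * pi / 180

#' @keywords internal
rad2deg <- function(x) x * 180 / pi

# Inputs closer than this (degrees) to a tangent pole or zero are rejected
# rather than propagated as huge or NaN values.
DEG_TOL <- 0.01

check_numeric <- function(x, arg) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite numeric, without missing values.", arg),
          class = "femver_error_domain")
  }
  invisible(x)
}

check_ci_open <- function(ci, arg = "ci") {
  check_numeric(ci, arg)
  if (any(ci <= DEG_TOL | ci >= 90 - DEG_TOL)) {
    abort(
      sprintf(
        "`%s` must lie strictly inside (0, 90) degrees and more than %g degrees from either boundary: the coronal-inclination tangent is degenerate there.",
        arg, DEG_TOL
      ),
      class = "femver_error_degenerate"
    )
  }
  invisible(ci)
}

check_halfturn_open <- function(x, arg) {
  check_numeric(x, arg)
  if (any(abs(x) >= 90 - DEG_TOL)) {
    abort(
      sprintf("`%s` must lie strictly inside (-90, 90) degrees (tangent pole at +/-90).", arg),
      class = "femver_error_degenerate"
    )
  }
  invisible(x)
}

#' Transverse version from coronal and sagittal inclination
#'
#' The three orthogonal-plane projection angles of a unit neck axis obey
#' `tan(TV) = tan(SI) * tan(CI)`; this evaluates that relation to recover the
#' transverse version that would be seen on an axial view from a pair of
#' biplanar (AP + lateral) measurements.
#'
#' @param ci Coronal inclination in degrees, strictly inside (0, 90).
#' @param si Sagittal inclination in degrees, strictly inside (-90, 90).
#'   Positive values indicate anterior tilt (ante-inclination).
#' @return Transverse version in degrees, inside (-90, 90), with the sign of
#'   `si` (positive = anteversion). Vectorised over `ci` and `si`.
#' @examples
#' tv_from_ci_si(50.0, 11.3) # ~ 13.4 degrees
#' @seealso [ci_from_tv_si()], [si_from_tv_ci()], [angles_from_axis()]
#' @export
tv_from_ci_si <- function(ci, si) {
  check_ci_open(ci, "ci")
  check_halfturn_open(si, "si")
  rad2deg(atan(tan(deg2rad(si)) * tan(deg2rad(ci))))
}

#' Coronal inclination from transverse version and sagittal inclination
#'
#' Evaluates `CI = arctan(tan(TV) / tan(SI))`. A physically realisable neck
#' axis with coronal inclination in (0, 90) has `tv` and `si` of equal sign;
#' a sign mismatch is rejected as inconsistent rather than silently folded.
#'
#' @param tv Transverse version in degrees, strictly inside (-90, 90), nonzero.
#' @param si Sagittal inclination in degrees, strictly inside (-90, 90),
#'   nonzero and of the same sign as `tv`.
#' @return Coronal inclination in degrees, inside (0, 90). Vectorised.
#' @export
ci_from_tv_si <- function(tv, si) {
  check_halfturn_open(tv, "tv")
  check_halfturn_open(si, "si")
  if (any(abs(si) <= DEG_TOL)) {
    abort("`si` within tolerance of 0 degrees: coronal inclination is undetermined (tan(si) ~ 0).",
          class = "femver_error_degenerate")
  }
  if (any(abs(tv) <= DEG_TOL)) {
    abort("`tv` within tolerance of 0 degrees: coronal inclination collapses to the 0-degree boundary.",
          class = "femver_error_degenerate")
  }
  if (any(sign(tv) != sign(si))) {
    abort("`tv` and `si` must have the same sign for a neck axis with coronal inclination in (0, 90).",
          class = "femver_error_inconsistent")
  }
  rad2deg(atan(tan(deg2rad(tv)) / tan(deg2rad(si))))
}

#' Sagittal inclination from transverse version and coronal inclination
#'
#' Evaluates `SI = arctan(tan(TV) / tan(CI))`.
#'
#' @param tv Transverse version in degrees, strictly inside (-90, 90).
#' @param ci Coronal inclination in degrees, strictly inside (0, 90).
#' @return Sagittal inclination in degrees, inside (-90, 90), with the sign
#'   of `tv`. Vectorised.
#' @export
si_from_tv_ci <- function(tv, ci) {
  check_halfturn_open(tv, "tv")
  check_ci_open(ci, "ci")
  rad2deg(atan(tan(deg2rad(tv)) / tan(deg2rad(ci))))
}

#' Construct a validated (CI, SI, TV) angle triple
#'
#' Bundles the three projection angles of one or more neck axes into a tibble
#' and enforces the geometric consistency of an exact triple: each coronal
#' inclination in (0, 90), the other two angles in (-90, 90), and the
#' tangent-product identity `tan(tv) = tan(si) * tan(ci)` to within `1e-9`.
#' Noisy *measured* angles do not satisfy the identity and should be kept as
#' plain columns, not passed through this constructor.
#'
#' @param ci,si,tv Angles in degrees (equal-length vectors).
#' @return A tibble with columns `ci`, `si`, `tv`.
#' @export
orientation_angles <- function(ci, si, tv) {
  check_numeric(ci, "ci"); check_numeric(si, "si"); check_numeric(tv, "tv")
  n <- max(length(ci), length(si), length(tv))
  ci <- rep_len(ci, n); si <- rep_len(si, n); tv <- rep_len(tv, n)
  if (any(ci <= 0 | ci >= 90)) {
    abort("`ci` must lie in (0, 90) degrees.", class = "femver_error_domain")
  }
  if (any(abs(si) >= 90) || any(abs(tv) >= 90)) {
    abort("`si` and `tv` must lie in (-90, 90) degrees.", class = "femver_error_domain")
  }
  gap <- abs(tan(deg2rad(tv)) - tan(deg2rad(si)) * tan(deg2rad(ci)))
  if (any(gap > 1e-9)) {
    abort("Angle triple violates tan(tv) = tan(si) * tan(ci) beyond 1e-9: not a consistent projection triple.",
          class = "femver_error_inconsistent")
  }
  tibble(ci = ci, si = si, tv = tv)
}
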