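#' Construct a unit neck axis
#'
#' The longitudinal axis of the neck of the femoral component, as a unit
#' 3-vector in an anatomical frame: `x` medio-lateral (the neck points
#' medially, so `x > 0` is enforced), `y` antero-posterior (anterior
#' positive), `z` vertical (superior positive). The input is normalized.
#'
#' @param x,y,z Components of the axis direction (any common scale).
#' @return A named unit 3-vector of class `"neck_axis"`.
#' @examples
#' neck_axis(1, tan(deg2rad(10.8)), tan(deg2rad(50)))
#' @export
neck_axis <- function(x, y, z) {
  v <- c(x = x, y = y, z = z)
  if (!is.numeric(v) || length(v) != 3 || anyNA(v) || any(!is.finite(v))) {
    abort("`x`, `y`, `z` must be single finite numbers.", class = "femver_error_domain")
  }
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) {
    abort("Neck axis must be a nonzero vector.", class = "femver_error_domain")
  }
  v <- v / nrm
  if (v[["x"]] <= 0) {
    abort("Neck axis must point medially: the x (medio-lateral) component must be positive.",
          class = "femver_error_domain")
  }
  structure(v, class = "neck_axis")
}

#' @export
print.neck_axis <- function(x, ...) {
  cat(sprintf("<neck_axis> (%.6f, %.6f, %.6f)\n", x[["x"]], x[["y"]], x[["z"]]))
  invisible(x)
}

#' Neck axis from coronal inclination and transverse version
#'
#' Inverts the projection-angle definitions: any two of the three angles
#' determine the axis, and (CI, TV) is the convenient pair because both are
#' referenced to the horizontal. Returns the unit vector proportional to
#' `(1, tan(tv), tan(ci))`.
#'
#' @param ci Coronal inclination in degrees, strictly inside (0, 90).
#' @param tv Transverse version in degrees, strictly inside (-90, 90).
#' @return A [neck_axis()].
#' @examples
#' axis_from_angles(45, 45) # (1, 1, 1) / sqrt(3)
#' @export
axis_from_angles <- function(ci, tv) {
  check_ci_open(ci, "ci")
  check_halfturn_open(tv, "tv")
  if (length(ci) != 1L || length(tv) != 1L) {
    abort("`ci` and `tv` must be single angles; use the cohort tools for tables.",
          class = "femver_error_domain")
  }
  neck_axis(1, tan(deg2rad(tv)), tan(deg2rad(ci)))
}

# Vectorised internal form: rows of unit axis components for angle vectors.
axis_components <- function(ci, tv) {
  x <- rep_len(1, max(length(ci), length(tv)))
  y <- tan(deg2rad(tv))
  z <- tan(deg2rad(ci))
  nrm <- sqrt(x^2 + y^2 + z^2)
  cbind(x = x / nrm, y = y / nrm, z = z / nrm)
}

# Re-express a world-coordinate direction in a frame's basis (directions only;
# the origin is irrelevant).
express_in_frame <- function(v, frame) {
  if (is.null(frame)) return(v)
  stopifnot(inherits(frame, "anatomical_frame"))
  out <- as.numeric(crossprod(frame$basis, as.numeric(v)))
  names(out) <- c("x", "y", "z")
  out
}

check_axis_projections <- function(v) {
  # sin(DEG_TOL degrees) bounds how close the axis may come to a plane normal
  stol <- sin(deg2rad(DEG_TOL))
  if (sqrt(v[["x"]]^2 + v[["z"]]^2) < stol) {
    abort("Axis is (anti)parallel to the coronal plane's normal: coronal projection degenerate.",
          class = "femver_error_degenerate")
  }
  if (sqrt(v[["y"]]^2 + v[["z"]]^2) < stol) {
    abort("Axis is (anti)parallel to the sagittal plane's normal: sagittal projection degenerate.",
          class = "femver_error_degenerate")
  }
  if (sqrt(v[["x"]]^2 + v[["y"]]^2) < stol) {
    abort("Axis is (anti)parallel to the transverse plane's normal: transverse projection degenerate.",
          class = "femver_error_degenerate")
  }
  invisible(v)
}

#' Projection angles of a neck axis
#'
#' Projects the axis onto the coronal, sagittal and transverse planes of an
#' anatomical frame and measures the three angles the way they are read off
#' radiographic views: coronal inclination against the horizontal, sagittal
#' inclination against the vertical, transverse version against the
#' horizontal. Computed with `atan2` on vector components, which stays
#' accurate where the tangent-product equations degrade (CI near 90).
#'
#' @param axis A [neck_axis()], expressed in `frame` coordinates if `frame`
#'   is `NULL`, otherwise in the world coordinates that `frame` is defined in.
#' @param frame Optional [anatomical_frame()] in which to re-express the axis
#'   (e.g. a mechanical-femoral frame from [mechanical_frame()]).
#' @return A one-row tibble with columns `ci`, `si`, `tv` (degrees), as from
#'   [orientation_angles()].
#' @examples
#' a <- axis_from_angles(50.0, 10.8)
#' angles_from_axis(a)
#' @export
angles_from_axis <- function(axis, frame = NULL) {
  if (!inherits(axis, "neck_axis")) {
    abort("`axis` must be a <neck_axis>.", class = "femver_error_domain")
  }
  v <- express_in_frame(axis, frame)
  if (v[["x"]] <= 0) {
    abort("After re-expression in `frame`, the axis must still point medially (x > 0).",
          class = "femver_error_domain")
  }
  check_axis_projections(v)
  ci <- rad2deg(atan2(v[["z"]], v[["x"]]))
  si <- rad2deg(atan2(v[["y"]], v[["z"]]))
  tv <- rad2deg(atan2(v[["y"]], v[["x"]]))
  if (ci <= DEG_TOL || ci >= 90 - DEG_TOL) {
    plane <- if (ci <= DEG_TOL) "sagittal (axis lies on the horizontal)" else "transverse (axis nearly vertical)"
    abort(sprintf("Coronal inclination %.4f degrees is at a domain boundary: %s projection degenerate.", ci, plane),
          class = "femver_error_degenerate")
  }
  orientation_angles(ci, si, tv)
}

#' Plane misalignment descriptor for non-orthogonal biplanar imaging
#'
#' @param delta Deviation, in degrees, of the angle between the sagittal and
#'   coronal viewing planes from 90 (so `delta = 5` means the planes meet at
#'   85 degrees). Positive `delta` reduces apparent anteversion. Must satisfy
#'   `|delta| < 45`.
#' @return An object of class `"plane_misalignment"`.
#' @export
plane_misalignment <- function(delta) {
  check_numeric(delta, "delta")
  if (length(delta) != 1L || abs(delta) >= 45) {
    abort("`delta` must be a single angle with |delta| < 45 degrees.",
          class = "femver_error_domain")
  }
  structure(list(delta = delta), class = "plane_misalignment")
}

#' Apparent projection angles under non-orthogonal biplanar imaging
#'
#' Models acquisition in which the sagittal (lateral) view is rotated by
#' `delta` degrees about the vertical axis while the coronal (AP) view stays
#' in place, so the two planes meet at `90 - delta` degrees. The coronal
#' inclination is unchanged; the sagittal inclination is measured on the
#' rotated plane; the returned transverse version is what the tangent-product
#' equation yields from that mismatched pair. In closed form,
#' `tan(tv') = tan(tv) * cos(delta) - sin(delta)`: positive `delta`
#' systematically understates anteversion.
#'
#' @inheritParams angles_from_axis
#' @param mis A [plane_misalignment()] (or a single number of degrees).
#' @return A one-row tibble with columns `ci`, `si`, `tv`: the *apparent*
#'   angle triple (internally consistent, hence still satisfying the
#'   tangent-product identity, but biased away from the true triple).
#' @examples
#' a <- axis_from_angles(50.0, 10.8)
#' apparent_angles_nonorthogonal(a, mis = plane_misalignment(5)) # tv ~ 5.87
#' @export
apparent_angles_nonorthogonal <- function(axis, frame = NULL, mis = plane_misalignment(5)) {
  if (is.numeric(mis)) mis <- plane_misalignment(mis)
  if (!inherits(mis, "plane_misalignment")) {
    abort("`mis` must be a <plane_misalignment> or a single number of degrees.",
          class = "femver_error_domain")
  }
  true <- angles_from_axis(axis, frame)
  app <- nonorth_apparent(true$ci, true$tv, mis$delta)
  orientation_angles(true$ci, app$si, app$tv)
}

# Vectorised core of the non-orthogonal model. Rotating the sagittal viewing
# plane by +delta about the vertical axis re-expresses the axis's
# antero-posterior component as y' = y cos(delta) - x sin(delta); the
# apparent SI is atan2(y', z) and the apparent TV follows from (CI, SI').
nonorth_apparent <- function(ci, tv, delta) {
  v <- axis_components(ci, tv)
  d <- deg2rad(delta)
  y2 <- v[, "y"] * cos(d) - v[, "x"] * sin(d)
  list(
    si = rad2deg(atan2(y2, v[, "z"])),
    tv = rad2deg(atan2(y2, v[, "x"]))
  )
}
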