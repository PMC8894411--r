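cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v, what) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) {
    abort(sprintf("%s has (near-)zero length.", what), class = "femver_error_frame")
  }
  v / n
}

#' Construct a validated anatomical frame
#'
#' A right-handed orthonormal triad with `e_x` medio-lateral horizontal
#' (pointing toward the side the neck points to), `e_y` antero-posterior
#' (anterior positive) and `e_z` vertical (superior positive), plus an origin.
#' The scanner frame is the identity triad; a mechanical-femoral frame comes
#' from [mechanical_frame()].
#'
#' @param e_x,e_y,e_z Basis vectors (unit norm within 1e-12, pairwise
#'   orthogonal within 1e-10, `e_x x e_y = e_z` within 1e-10).
#' @param origin Frame origin in mm, default `c(0, 0, 0)`.
#' @return An object of class `"anatomical_frame"` with elements `origin` and
#'   `basis` (3x3 matrix whose columns are `e_x`, `e_y`, `e_z`).
#' @export
anatomical_frame <- function(e_x = c(1, 0, 0), e_y = c(0, 1, 0), e_z = c(0, 0, 1),
                             origin = c(0, 0, 0)) {
  B <- cbind(e_x = e_x, e_y = e_y, e_z = e_z)
  if (!is.numeric(B) || nrow(B) != 3 || anyNA(B)) {
    abort("Basis vectors must be numeric 3-vectors.", class = "femver_error_frame")
  }
  if (any(abs(sqrt(colSums(B^2)) - 1) > 1e-12)) {
    abort("Basis vectors must have unit norm (within 1e-12).", class = "femver_error_frame")
  }
  dots <- c(sum(e_x * e_y), sum(e_x * e_z), sum(e_y * e_z))
  if (any(abs(dots) > 1e-10)) {
    abort("Basis vectors must be pairwise orthogonal (within 1e-10).", class = "femver_error_frame")
  }
  if (any(abs(cross3(e_x, e_y) - e_z) > 1e-10)) {
    abort("Frame must be right-handed: e_x x e_y = e_z (within 1e-10).",
          class = "femver_error_frame")
  }
  structure(list(origin = as.numeric(origin), basis = B), class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("<anatomical_frame>\n  origin:", sprintf("%.2f", x$origin), "\n")
  print(round(x$basis, 6))
  invisible(x)
}

#' Bundle femoral landmarks for mechanical-frame construction
#'
#' @param head_center,knee_center 3-vectors in mm; the mechanical femoral axis
#'   runs from the knee-joint center to the femoral-head center.
#' @param medial_posterior_condyle,lateral_posterior_condyle 3-vectors in mm;
#'   the posterior condylar line is the distal rotational reference.
#' @return An object of class `"femoral_landmarks"`.
#' @export
femoral_landmarks <- function(head_center, knee_center,
                              medial_posterior_condyle, lateral_posterior_condyle) {
  pts <- list(head_center = as.numeric(head_center),
              knee_center = as.numeric(knee_center),
              medial_posterior_condyle = as.numeric(medial_posterior_condyle),
              lateral_posterior_condyle = as.numeric(lateral_posterior_condyle))
  if (any(vapply(pts, function(p) length(p) != 3 || anyNA(p) || any(!is.finite(p)), logical(1)))) {
    abort("Each landmark must be a finite numeric 3-vector.", class = "femver_error_domain")
  }
  if (sqrt(sum((pts$head_center - pts$knee_center)^2)) < 1e-9) {
    abort("Head and knee centers coincide.", class = "femver_error_domain")
  }
  if (sqrt(sum((pts$medial_posterior_condyle - pts$lateral_posterior_condyle)^2)) < 1e-9) {
    abort("Condyle landmarks coincide.", class = "femver_error_domain")
  }
  structure(pts, class = "femoral_landmarks")
}

#' Mechanical-femoral anatomical frame from bony landmarks
#'
#' Builds the frame in which the primed angles (CI', SI', TV') are measured:
#' the vertical axis is the mechanical femoral axis (knee-joint center to
#' femoral-head center), the medio-lateral axis is the posterior condylar
#' direction (lateral to medial condyle) orthogonalized against it by
#' Gram-Schmidt, and the antero-posterior axis completes the right-handed
#' triad. The origin is placed at the femoral-head center.
#'
#' @param landmarks A [femoral_landmarks()] object.
#' @return An [anatomical_frame()].
#' @export
mechanical_frame <- function(landmarks) {
  if (!inherits(landmarks, "femoral_landmarks")) {
    abort("`landmarks` must be a <femoral_landmarks>.", class = "femver_error_domain")
  }
  e_z <- unit3(landmarks$head_center - landmarks$knee_center, "Mechanical axis")
  cdir <- landmarks$medial_posterior_condyle - landmarks$lateral_posterior_condyle
  resid <- cdir - sum(cdir * e_z) * e_z
  if (sqrt(sum(resid^2)) < 1e-9 * sqrt(sum(cdir^2))) {
    abort("Condylar direction is parallel to the mechanical axis: frame undefined.",
          class = "femver_error_frame")
  }
  e_x <- unit3(resid, "Condylar direction")
  e_y <- cross3(e_z, e_x)
  anatomical_frame(e_x = e_x, e_y = e_y, e_z = e_z, origin = landmarks$head_center)
}

#' Read femoral landmark tables
#'
#' Expects a CSV with a header row and columns `hip_id` plus `<landmark>_x`,
#' `<landmark>_y`, `<landmark>_z` in mm for each of `head`, `knee`,
#' `medial_condyle`, `lateral_condyle`.
#'
#' @param path Path to the CSV file.
#' @return A tibble, one row per femur.
#' @export
read_landmarks <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("hip_id", as.vector(outer(
    c("head", "knee", "medial_condyle", "lateral_condyle"),
    c("x", "y", "z"), paste, sep = "_")))
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("Landmark file is missing columns: ", paste(missing, collapse = ", ")),
          class = "femver_error_io")
  }
  as_tibble(df)
}

#' Mechanical frames for every femur in a landmark table
#'
#' @param data A landmark tibble as returned by [read_landmarks()].
#' @return A named list of [anatomical_frame()] objects keyed by `hip_id`.
#' @export
frames_from_landmarks <- function(data) {
  pick <- function(row, stem) as.numeric(row[paste(stem, c("x", "y", "z"), sep = "_")])
  frames <- lapply(seq_len(nrow(data)), function(i) {
    row <- data[i, ]
    lm <- femoral_landmarks(pick(row, "head"), pick(row, "knee"),
                            pick(row, "medial_condyle"), pick(row, "lateral_condyle"))
    mechanical_frame(lm)
  })
  names(frames) <- as.character(data$hip_id)
  frames
}
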