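#' Read a per-hip angle table
#'
#' Expects a CSV with a header and columns `hip_id`, `ci_deg`, `si_deg` and
#' optionally `tv_deg`, all angles in degrees.
#'
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_angles <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("hip_id", "ci_deg", "si_deg")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("Angle file is missing columns: ", paste(missing, collapse = ", ")),
          class = "femver_error_io")
  }
  for (col in intersect(c("ci_deg", "si_deg", "tv_deg"), names(df))) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      abort(sprintf("Column `%s` is not numeric (first bad row: %d).", col, bad),
            class = "femver_error_io")
    }
  }
  as_tibble(df)
}

#' Write a per-hip angle table
#'
#' @param data A data frame of angles.
#' @param path Output CSV path.
#' @return `data`, invisibly.
#' @export
write_angles <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}

#' Read a plain-text key = value configuration file
#'
#' One `key = value` pair per line; blank lines and lines starting with `#`
#' are ignored. Values are type-converted (numbers become numeric). Keys
#' mirror the command-line flags of the bundled CLI, which override them.
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(list())
  parts <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    abort(sprintf("Config line %d is not `key = value`: %s", bad[1], lines[bad[1]]),
          class = "femver_error_io")
  }
  keys <- trimws(vapply(parts, `[[`, "", 1))
  vals <- trimws(vapply(parts, `[[`, "", 2))
  out <- lapply(vals, function(v) utils::type.convert(v, as.is = TRUE))
  names(out) <- keys
  out
}
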