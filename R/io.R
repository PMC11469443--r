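#' @include inference.R
NULL

#' Load a condition-summary dataset
#'
#' Reads a CSV of per-condition steady-state summaries (columns
#' \code{condition_id}, \code{mean}, \code{fano}) for multi-condition
#' fitting, with row-level validation.
#'
#' @param path CSV path.
#' @return validated data.frame with the three columns, row order preserved.
#' @export
loadConditionData <- function(path) {
  df <- read.csv(path)
  need <- c("condition_id", "mean", "fano")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  bad <- which(!is.finite(df$mean) | df$mean <= 0 |
    !is.finite(df$fano) | df$fano <= 0)
  if (length(bad)) {
    stop(sprintf(
      "non-positive mean/fano in row(s): %s",
      paste(bad, collapse = ", ")
    ))
  }
  df[, need]
}

#' @rdname loadConditionData
#' @param data data.frame with columns \code{condition_id}, \code{mean},
#'   \code{fano}.
#' @export
writeConditionData <- function(data, path) {
  write.csv(data[, c("condition_id", "mean", "fano")], path,
    row.names = FALSE
  )
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' @param fit a [FitResult-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFitResult <- function(fit, path) {
  jsonlite::write_json(
    list(
      parameters = as.list(fit@thetaHat),
      ci = apply(fit@ci, 1, as.list),
      ci_standard = apply(fit@ciStandard, 1, as.list),
      loss_trace = fit@lossTrace,
      converged = fit@converged,
      seeds = fit@seeds,
      settings = fit@settings
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Serialize a design result to JSON (+ response CSV)
#'
#' @param design a [DesignResult-class].
#' @param path output JSON path; a sibling \code{.csv} with columns
#'   (concentration, target, achieved) is written alongside.
#' @return \code{path}, invisibly.
#' @export
writeDesignResult <- function(design, path) {
  jsonlite::write_json(
    list(
      parameters = as.list(design@thetaHat),
      achieved = design@achieved,
      target = design@target@values,
      concentrations = design@target@concGrid,
      sharpness = design@sharpness,
      drive = design@drive,
      flux = design@flux,
      power = design@power,
      power_midpoint = design@powerMid,
      loss_trace = design@lossTrace,
      engine = design@engine
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  csv <- sub("\\.json$", ".csv", path)
  write.csv(
    data.frame(
      concentration = design@target@concGrid,
      target = design@target@values, achieved = design@achieved
    ),
    csv,
    row.names = FALSE
  )
  invisible(path)
}
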