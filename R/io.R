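# Tabular and JSON plumbing: tracer CSV files, RTD summaries and curves.
# Canonical dialect: comma-separated with a header row; headerless
# two-column files are accepted for tracer input.

#' Read a tracer run from a delimited file
#'
#' Expects columns `time_s, concentration_mg_per_g` (header optional; a
#' headerless two-column numeric file is accepted).
#'
#' @param path CSV/TSV path (the delimiter is sniffed from the first line).
#' @return A [tracer_series()] labelled with the file name.
#' @export
read_tracer_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read '%s'", path), "extrurtd_io_error")
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    abort(sprintf("'%s' is empty", path), "extrurtd_io_error")
  }
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- grepl("[A-Za-z]", first)
  df <- tryCatch(
    utils::read.table(path, header = has_header, sep = sep,
                      stringsAsFactors = FALSE),
    error = function(e) {
      abort(sprintf("malformed delimited file '%s': %s", path,
                    conditionMessage(e)), "extrurtd_io_error")
    })
  if (has_header) {
    need <- c("time_s", "concentration_mg_per_g")
    if (!all(need %in% names(df))) {
      abort(sprintf("'%s' must have columns %s", path,
                    paste(need, collapse = ", ")), "extrurtd_io_error")
    }
    df <- df[, need]
  } else {
    if (ncol(df) < 2L) {
      abort(sprintf("'%s' needs two columns (time_s, concentration_mg_per_g)",
                    path), "extrurtd_io_error")
    }
    df <- df[, 1:2]
    names(df) <- c("time_s", "concentration_mg_per_g")
  }
  t <- suppressWarnings(as.numeric(df$time_s))
  conc <- suppressWarnings(as.numeric(df$concentration_mg_per_g))
  bad <- which(is.na(t) | is.na(conc))
  if (length(bad) > 0L) {
    abort(sprintf("non-numeric values in '%s' at data line(s) %s", path,
                  paste(utils::head(bad + has_header, 5L), collapse = ", ")),
          "extrurtd_io_error")
  }
  tracer_series(t, conc, run_label = basename(path))
}

#' Write a tracer run to CSV
#'
#' @param series A [tracer_series()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tracer_csv <- function(series, path) {
  stopifnot(inherits(series, "tracer_series"))
  df <- data.frame(time_s = series$times,
                   concentration_mg_per_g = series$concentrations)
  write_atomic(path, function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE)
  })
}

#' Write an RTD summary as JSON
#'
#' Fields: `run_label, mrt_s, variance_s2, sigma_theta2, peclet,
#' peclet_solvable`.
#'
#' @param summary An [analyze_run()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rtd_summary <- function(summary, path) {
  stopifnot(inherits(summary, "rtd_summary"))
  obj <- list(run_label = summary$run_label,
              mrt_s = summary$mrt,
              variance_s2 = summary$variance,
              sigma_theta2 = summary$sigma_theta2,
              peclet = if (summary$peclet_solvable) summary$peclet else NULL,
              peclet_solvable = summary$peclet_solvable)
  write_atomic(path, function(tmp) {
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  })
}

#' Write RTD curves as CSV
#'
#' Columns: `time_s, E, F, theta, E_theta, F_theta`.
#'
#' @param curves A completed `rtd_curves` object (e.g. from
#'   [analyze_run()]`$curves`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rtd_curves <- function(curves, path) {
  stopifnot(inherits(curves, "rtd_curves"))
  df <- data.frame(time_s = curves$times, E = curves$E,
                   F = curves$F, theta = curves$theta,
                   E_theta = curves$E_theta, F_theta = curves$F_theta)
  write_atomic(path, function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE)
  })
}
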