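#' Read a titration series from CSV
#'
#' Expects a comma-separated file with a header and columns
#' `quencher_conc_M` (molar; the column name carries the unit to avoid
#' micromolar/millimolar ambiguity) and `intensity` (arbitrary units).
#' All [titration_series()] invariants are validated with error messages
#' naming the offending row.
#'
#' @param path path to the CSV file.
#' @param sample_id label for the series; defaults to the file name.
#' @param condition optional [condition()] to attach.
#' @return A [titration_series()].
#' @export
read_titration_csv <- function(path, sample_id = NULL, condition = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("quencher_conc_M", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  Q <- suppressWarnings(as.numeric(df$quencher_conc_M))
  I <- suppressWarnings(as.numeric(df$intensity))
  bad <- which(is.na(Q) | is.na(I))
  if (length(bad)) {
    stop(sprintf("malformed numeric value in row %d ('%s', '%s')",
                 bad[1], df$quencher_conc_M[bad[1]], df$intensity[bad[1]]),
         call. = FALSE)
  }
  neg <- which(Q < 0)
  if (length(neg)) {
    stop(sprintf("negative quencher concentration in row %d", neg[1]),
         call. = FALSE)
  }
  nonpos <- which(I <= 0)
  if (length(nonpos)) {
    stop(sprintf("non-positive intensity in row %d", nonpos[1]), call. = FALSE)
  }
  dup <- which(duplicated(Q))
  if (length(dup)) {
    stop(sprintf("duplicate quencher concentration %g in row %d",
                 Q[dup[1]], dup[1]), call. = FALSE)
  }
  if (!any(Q == 0)) {
    stop("no zero-quencher baseline: a quencher_conc_M = 0 row defining I0 is required",
         call. = FALSE)
  }
  if (is.null(sample_id)) sample_id <- sub("\\.csv$", "", basename(path))
  titration_series(Q, I, sample_id = sample_id, condition = condition)
}

#' Write a titration series to CSV
#'
#' Inverse of [read_titration_csv()]; a write-then-read round trip
#' reproduces the series exactly (concentrations and intensities are
#' written with full double precision).
#'
#' @param series a [titration_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  df <- data.frame(
    quencher_conc_M = format(series$quencher_conc, digits = 17,
                             scientific = TRUE, trim = TRUE),
    intensity = format(series$intensity, digits = 17, scientific = TRUE,
                       trim = TRUE)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a calibration result as JSON
#' @param result a [fit_sv_constant()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  jsonlite::write_json(
    list(Kq_hat = result$Kq_hat, Kq_stderr = result$Kq_stderr,
         intercept = result$intercept, r_squared = result$r_squared,
         n_points = result$n_points, residuals = result$residuals),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration result back from JSON
#' @param path JSON file written by [write_calibration_json()].
#' @return A `calibration_result`.
#' @export
read_calibration_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$Kq_hat) || !is.numeric(obj$Kq_hat) || obj$Kq_hat <= 0) {
    stop("not a valid calibration file: ", path, call. = FALSE)
  }
  structure(obj, class = "calibration_result")
}

#' Write an orientation fit as JSON
#'
#' Results always carry both the point estimate and its uncertainty fields,
#' never bare numbers.
#'
#' @param fit a [fit_orientation_fraction()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "orientation_fit"))
  jsonlite::write_json(
    list(x_hat = fit$x_hat, x_stderr = fit$x_stderr, ci_low = fit$ci_low,
         ci_high = fit$ci_high, Kq_used = fit$Kq_used, rss = fit$rss,
         n_points = fit$n_points, converged = fit$converged,
         clipped = fit$clipped, warnings = as.list(fit$warnings)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a study report as CSV files and readable text
#'
#' @param report a `study_report` from [compare_conditions()] or
#'   [run_study()].
#' @param dir output directory (created if needed); writes
#'   `conditions.csv`, `contrasts.csv`, and `report.txt`.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$conditions, file.path(dir, "conditions.csv"),
                   row.names = FALSE)
  utils::write.csv(report$contrasts, file.path(dir, "contrasts.csv"),
                   row.names = FALSE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
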