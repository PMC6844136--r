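# CSV readers/writers for curves and scan stacks, and JSON fit reports.
# Comma- or tab-delimited, decimal point only (English-locale instrument
# exports); header row optional for two-column curve files.

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

read_numeric_table <- function(path) {
  sep <- sniff_sep(path)
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", strip.white = TRUE,
                           blank.lines.skip = TRUE)
  if (ncol(raw) < 2) stop("expected at least two columns in ", path)
  has_header <- suppressWarnings(any(is.na(as.numeric(raw[1, ]))))
  header <- if (has_header) as.character(raw[1, ]) else NULL
  body <- if (has_header) raw[-1, , drop = FALSE] else raw
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  num <- matrix(num, nrow = nrow(body))
  bad <- which(apply(num, 1, function(r) any(is.na(r))))
  if (length(bad))
    stop(sprintf("non-numeric cell in data row %d of %s", bad[1], path))
  list(values = num, header = header)
}

#' Read a thermal or chemical curve from a delimited text file
#'
#' Accepts two numeric columns (x, signal), comma- or tab-delimited, with an
#' optional header row. Rows are sorted by the x column; duplicate x values
#' are averaged with a warning.
#'
#' @param path Path to the file.
#' @param kind `"thermal"` (x = temperature) or `"chemical"` (x = molar
#'   denaturant concentration).
#' @param ... Passed to [thermal_curve()] or [chemical_curve()] (e.g. `unit`,
#'   `denaturant`, `probe_label`, `temperature`).
#' @return A validated [thermal_curve()] or [chemical_curve()].
#' @export
read_curve_csv <- function(path, kind = c("thermal", "chemical"), ...) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read_numeric_table(path)
  x <- tab$values[, 1]
  y <- tab$values[, 2]
  if (kind == "thermal") thermal_curve(x, y, ...)
  else chemical_curve(x, y, ...)
}

#' Write a curve to CSV
#'
#' Values are written with 17 significant digits so that reading the file back
#' reproduces the curve bit-for-bit.
#'
#' @param curve A `thermal_curve` or `chemical_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  if (inherits(curve, "thermal_curve")) {
    x <- curve$temperature; xname <- "temperature_K"
  } else if (inherits(curve, "chemical_curve")) {
    x <- curve$concentration; xname <- "concentration_M"
  } else stop("not a curve object")
  lines <- c(paste(xname, "signal", sep = ","),
             paste(sprintf("%.17g", x), sprintf("%.17g", curve$signal),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

parse_conc_header <- function(h) {
  cleaned <- sub("(?i)\\s*M\\s*$", "", trimws(h), perl = TRUE)
  suppressWarnings(as.numeric(cleaned))
}

#' Read a stack of emission scans from a wide CSV
#'
#' First column: wavelength (nm). Each remaining column: one sample, its
#' header giving the molar denaturant concentration (a bare number or with an
#' `M` suffix, e.g. `"3.5"` or `"3.5M"`).
#'
#' @param path Path to the wide CSV (comma- or tab-delimited).
#' @param probe Probe for all scans: `"Trp"`, `"ANS"` or `"CD"`.
#' @param excitation_nm Excitation wavelength passed to every scan; defaults
#'   to the probe convention (295 for Trp, 370 for ANS).
#' @return A list of [emission_scan()] objects, one per sample column.
#' @export
read_scan_stack <- function(path, probe = c("Trp", "ANS", "CD"),
                            excitation_nm = NULL) {
  probe <- match.arg(probe)
  if (is.null(excitation_nm))
    excitation_nm <- switch(probe, Trp = 295, ANS = 370, NA_real_)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- sniff_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, strip.white = TRUE)
  if (ncol(tab) < 2) stop("expected wavelength plus at least one sample column")
  headers <- colnames(tab)[-1]
  conc <- parse_conc_header(headers)
  if (anyNA(conc))
    stop("sample headers not parseable as molar concentrations: ",
         paste(headers[is.na(conc)], collapse = ", "))
  wl <- as.numeric(tab[[1]])
  lapply(seq_along(conc), function(i) {
    y <- as.numeric(tab[[i + 1]])
    if (all(is.na(y)))
      stop(sprintf("sample column '%s' is empty", headers[i]))
    emission_scan(wl, y, excitation_nm = excitation_nm,
                  sample_concentration = conc[i], probe = probe)
  })
}

# NaN standard errors (e.g. from a singular covariance) are serialized as JSON
# null and restored as NaN on read; this rule is part of the report schema.
# Report records hold scalars, named/unnamed atomic vectors and nested lists
# of those; named numeric vectors travel as JSON objects and are collapsed
# back to vectors on read.
nan_to_null <- function(x) {
  if (is.list(x)) return(lapply(x, nan_to_null))
  if (is.numeric(x) && any(is.nan(x))) {
    if (length(x) == 1 && is.null(names(x))) return(NULL)
    return(lapply(as.list(x), function(v) if (is.nan(v)) NULL else v))
  }
  # named vectors travel as JSON objects so the names survive
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

null_to_nan <- function(x) {
  if (is.null(x)) return(NaN)
  if (is.list(x)) {
    x <- lapply(x, null_to_nan)
    scalar_num <- vapply(x, function(v)
      is.numeric(v) && length(v) == 1, TRUE)
    if (length(x) > 1 && all(scalar_num)) return(unlist(x))
    return(x)
  }
  x
}

#' Write a fit report to JSON
#'
#' Serializes any fit record produced by this package (parameters, standard
#' errors, derived quantities, residual norm) together with the package
#' version and schema version. Numbers are written at full precision so the
#' report round-trips losslessly through [read_fit_report()]; `NaN` values
#' are stored as JSON `null` and restored as `NaN`.
#'
#' @param fit A fit record (e.g. from [fit_thermal_two_state()],
#'   [fit_chemical_three_state()], [characteristic_temperatures()]).
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  payload <- list(
    schema = "unfoldfit-report-1",
    package_version = as.character(utils::packageVersion("unfoldfit")),
    class = class(fit)[1],
    fit = nan_to_null(unclass(fit))
  )
  # I(17): 17 significant digits, enough to round-trip doubles bit-for-bit
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fit report written by [write_fit_report()]
#'
#' @param path Path to a report JSON file.
#' @return The fit record with its original class restored.
#' @export
read_fit_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "unfoldfit-report-1"))
    stop("not an unfoldfit report: ", path)
  fit <- lapply(payload$fit, null_to_nan)
  class(fit) <- payload$class
  fit
}
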