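# Domain containers: thermal melts, chemical titrations, emission scans.
# Constructors validate, sort by the x variable, and average duplicate x values
# (replicate scans at the same denaturant concentration are normal).

sort_and_dedupe <- function(x, y, what = "x") {
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  if (anyDuplicated(x)) {
    warning(sprintf("duplicate %s values averaged", what), call. = FALSE)
    y <- as.numeric(tapply(y, factor(x, levels = unique(x)), mean))
    x <- unique(x)
  }
  list(x = x, y = y)
}

#' Construct a thermal denaturation curve
#'
#' A temperature-indexed spectroscopic signal series for one melt, e.g. the
#' change in ellipticity (millidegree) at 222 nm followed between 20 and 70
#' degrees C. Temperatures are stored in kelvin; Celsius input is converted.
#'
#' @param temperature Numeric vector of temperatures. Interpreted per `unit`:
#'   `"auto"` assumes kelvin when the minimum exceeds 100 and Celsius
#'   otherwise, since no melt of a mesophilic protein is recorded below 100 K.
#' @param signal Numeric vector of instrument signal, same length as
#'   `temperature` (at least 8 points).
#' @param probe_label Free-text probe description, e.g. `"CD222"`.
#' @param wavelength_nm Optional monitoring wavelength in nm.
#' @param unit One of `"auto"`, `"kelvin"`, `"celsius"`.
#' @return An object of class `thermal_curve`: a list with elements
#'   `temperature` (kelvin, strictly increasing), `signal`, `probe_label`,
#'   `wavelength_nm`.
#' @examples
#' tc <- thermal_curve(seq(20, 70, 5), rnorm(11), probe_label = "CD222")
#' range(tc$temperature) # converted to kelvin
#' @export
thermal_curve <- function(temperature, signal, probe_label = "",
                          wavelength_nm = NA_real_,
                          unit = c("auto", "kelvin", "celsius")) {
  unit <- match.arg(unit)
  temperature <- as.numeric(temperature)
  signal <- as.numeric(signal)
  if (length(temperature) != length(signal))
    stop("temperature and signal must have equal length")
  if (!all(is.finite(temperature)) || !all(is.finite(signal)))
    stop("temperature and signal must be finite")
  if (unit == "celsius" || (unit == "auto" && min(temperature) <= 100))
    temperature <- temperature + 273.15
  s <- sort_and_dedupe(temperature, signal, "temperature")
  if (length(s$x) < 8)
    stop("a thermal curve needs at least 8 distinct temperatures")
  structure(list(temperature = s$x, signal = s$y, probe_label = probe_label,
                 wavelength_nm = wavelength_nm),
            class = "thermal_curve")
}

#' Construct a chemical denaturation titration
#'
#' A denaturant-concentration-indexed signal series for one equilibrium
#' titration (urea or guanidine hydrochloride), measured at a fixed
#' temperature (default 298.15 K, i.e. 25 degrees C).
#'
#' A curve is flagged (attribute `fittable`) when it lacks points below 0.5 M
#' and above 5 M (urea) or 3 M (GuHCl); such a curve cannot pin down both
#' baselines and the fits will warn.
#'
#' @param concentration Molar denaturant concentrations, non-negative.
#' @param signal Instrument signal, same length (at least 10 points).
#' @param denaturant `"urea"` or `"guhcl"`.
#' @param probe_label Free-text probe description, e.g. `"Trp F314"`.
#' @param temperature Temperature in kelvin. Default 298.15.
#' @return An object of class `chemical_curve`.
#' @export
chemical_curve <- function(concentration, signal,
                           denaturant = c("urea", "guhcl"),
                           probe_label = "", temperature = 298.15) {
  denaturant <- match.arg(tolower(denaturant), c("urea", "guhcl"))
  concentration <- as.numeric(concentration)
  signal <- as.numeric(signal)
  if (length(concentration) != length(signal))
    stop("concentration and signal must have equal length")
  if (!all(is.finite(concentration)) || !all(is.finite(signal)))
    stop("concentration and signal must be finite")
  if (any(concentration < 0))
    stop("denaturant concentrations must be non-negative")
  s <- sort_and_dedupe(concentration, signal, "concentration")
  if (length(s$x) < 10)
    stop("a titration needs at least 10 distinct concentrations")
  hi <- if (denaturant == "urea") 5 else 3
  fittable <- min(s$x) < 0.5 && max(s$x) > hi
  structure(list(concentration = s$x, signal = s$y, denaturant = denaturant,
                 probe_label = probe_label, temperature = temperature),
            class = "chemical_curve", fittable = fittable)
}

#' Construct a fluorescence emission scan or CD spectrum
#'
#' A wavelength-indexed intensity series for one sample at one denaturant
#' concentration. Probe conventions follow standard equilibrium unfolding
#' practice: intrinsic Trp fluorescence is excited at 295 nm with emission
#' collected over 300-400 nm; the hydrophobic-surface dye ANS is excited at
#' 370 nm with emission over 400-600 nm; `"CD"` marks a far-UV circular
#' dichroism spectrum (ellipticity, may be negative).
#'
#' @param wavelength_nm Strictly increasing wavelength grid (nm).
#' @param intensity Intensities (fluorescence, arbitrary units) or ellipticity
#'   (millidegree) for CD.
#' @param excitation_nm Excitation wavelength (nm); ignored for CD.
#' @param sample_concentration Molar denaturant concentration of the sample.
#' @param probe One of `"Trp"`, `"ANS"`, `"CD"`.
#' @return An object of class `emission_scan`.
#' @export
emission_scan <- function(wavelength_nm, intensity, excitation_nm = NA_real_,
                          sample_concentration = 0,
                          probe = c("Trp", "ANS", "CD")) {
  probe <- match.arg(probe)
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelength_nm) != length(intensity))
    stop("wavelength and intensity must have equal length")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (probe == "Trp") {
    if (!isTRUE(excitation_nm == 295))
      stop("Trp scans use excitation at 295 nm")
    if (min(wavelength_nm) > 300 || max(wavelength_nm) < 400)
      stop("Trp emission must cover 300-400 nm")
  } else if (probe == "ANS") {
    if (!isTRUE(excitation_nm == 370))
      stop("ANS scans use excitation at 370 nm")
    if (min(wavelength_nm) > 400 || max(wavelength_nm) < 600)
      stop("ANS emission must cover 400-600 nm")
  }
  structure(list(wavelength_nm = wavelength_nm, intensity = intensity,
                 excitation_nm = excitation_nm,
                 sample_concentration = as.numeric(sample_concentration),
                 probe = probe),
            class = "emission_scan")
}

#' @export
print.thermal_curve <- function(x, ...) {
  cat(sprintf("Thermal curve [%s]: %d points, %.2f-%.2f K\n",
              x$probe_label, length(x$temperature),
              min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' @export
print.chemical_curve <- function(x, ...) {
  cat(sprintf("%s titration [%s]: %d points, %.2f-%.2f M at %.2f K\n",
              x$denaturant, x$probe_label, length(x$concentration),
              min(x$concentration), max(x$concentration), x$temperature))
  invisible(x)
}

#' @export
print.emission_scan <- function(x, ...) {
  cat(sprintf("%s scan at %.3g M: %d points, %g-%g nm\n",
              x$probe, x$sample_concentration, length(x$wavelength_nm),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}
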