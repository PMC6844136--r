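# Reduction of emission scans and far-UV CD spectra to the scalar features
# tracked along a titration: emission maximum position and height, intensity
# at a wavelength, intensity ratios, ellipticity at a wavelength.

#' Subtract a blank scan
#'
#' Pointwise difference of two scans on the identical wavelength grid.
#' Fluorescence results are floored at zero (a message reports how many
#' points were floored); CD results are not floored, since ellipticity is
#' legitimately negative.
#'
#' @param scan,blank [emission_scan()] objects with identical grids.
#' @return The blank-subtracted [emission_scan()].
#' @export
blank_subtract <- function(scan, blank) {
  if (length(scan$wavelength_nm) != length(blank$wavelength_nm) ||
      any(scan$wavelength_nm != blank$wavelength_nm))
    stop("wavelength grids do not match")
  y <- scan$intensity - blank$intensity
  if (scan$probe != "CD") {
    n_floor <- sum(y < 0)
    if (n_floor > 0)
      message(sprintf("blank_subtract: floored %d negative point(s) at 0",
                      n_floor))
    y <- pmax(y, 0)
  }
  out <- scan
  out$intensity <- y
  out
}

moving_average <- function(y, window) {
  if (window <= 1) return(y)
  k <- rep(1 / window, window)
  sm <- stats::filter(y, k, sides = 2)
  sm <- as.numeric(sm)
  # edges where the window does not fit keep the raw values
  sm[is.na(sm)] <- y[is.na(sm)]
  sm
}

#' Wavelength of maximum emission
#'
#' Position of the maximum of the moving-average-smoothed intensities. Ties
#' break toward the shorter wavelength, so that blue-shift detection is
#' conservative. With `refine = TRUE` the vertex of the parabola through the
#' three points around the discrete maximum gives a sub-grid estimate.
#'
#' @param scan An [emission_scan()].
#' @param smoothing_window Odd number of points for the moving average
#'   (default 5); 1 disables smoothing.
#' @param refine Parabolic-vertex refinement (default `FALSE`).
#' @return Wavelength of maximum emission in nm.
#' @export
lambda_max <- function(scan, smoothing_window = 5, refine = FALSE) {
  y <- scan$intensity
  wl <- scan$wavelength_nm
  if (length(y) <= smoothing_window)
    stop("scan shorter than the smoothing window")
  if (smoothing_window %% 2 == 0) stop("smoothing window must be odd")
  if (diff(range(y)) == 0) stop("degenerate spectrum: all intensities equal")
  sm <- moving_average(y, smoothing_window)
  i <- which.max(sm) # first index on ties = shorter wavelength
  if (!refine || i == 1 || i == length(sm)) return(wl[i])
  y3 <- sm[(i - 1):(i + 1)]
  h <- wl[i + 1] - wl[i]
  denom <- y3[1] - 2 * y3[2] + y3[3]
  if (denom >= 0) return(wl[i])
  wl[i] + h * 0.5 * (y3[1] - y3[3]) / denom
}

#' Intensity at a wavelength
#'
#' Linear interpolation between the bracketing grid points; an exact grid hit
#' returns the stored value. No extrapolation outside the grid.
#'
#' @param scan An [emission_scan()].
#' @param wavelength Query wavelength in nm, inside the grid range.
#' @return Interpolated intensity.
#' @export
intensity_at <- function(scan, wavelength) {
  wl <- scan$wavelength_nm
  if (wavelength < min(wl) || wavelength > max(wl))
    stop(sprintf("wavelength %g nm outside scan range %g-%g nm",
                 wavelength, min(wl), max(wl)))
  stats::approx(wl, scan$intensity, xout = wavelength)$y
}

#' Ratio of intensities at two wavelengths
#'
#' `intensity_at(num_nm) / intensity_at(den_nm)`. Some figure conventions
#' label the ratio with the excitation wavelength (e.g. 295 nm for a Trp scan
#' recorded from 300 nm); `clamp_to_start = TRUE` maps a numerator request
#' below the grid to the first recorded emission wavelength instead of
#' erroring, as an explicit opt-in rather than silent extrapolation.
#'
#' @param scan An [emission_scan()].
#' @param num_nm,den_nm Numerator and denominator wavelengths in nm.
#' @param clamp_to_start Clamp `num_nm` up to the scan start when below it.
#' @return Dimensionless intensity ratio.
#' @export
intensity_ratio <- function(scan, num_nm, den_nm, clamp_to_start = FALSE) {
  if (clamp_to_start && num_nm < min(scan$wavelength_nm))
    num_nm <- min(scan$wavelength_nm)
  den <- intensity_at(scan, den_nm)
  if (den == 0) stop("denominator intensity is zero at ", den_nm, " nm")
  intensity_at(scan, num_nm) / den
}

#' Ellipticity at a wavelength of a far-UV CD spectrum
#'
#' Sign-preserving interpolation of a CD spectrum at a far-UV wavelength
#' (200-260 nm), e.g. 222 nm for helix content or the 219/221.8 nm channels
#' used to follow chemical unfolding.
#'
#' @param spectrum An [emission_scan()] with `probe = "CD"`.
#' @param wavelength Query wavelength in nm, within 200-260 and the grid.
#' @return Ellipticity in millidegree.
#' @export
ellipticity_at <- function(spectrum, wavelength) {
  if (spectrum$probe != "CD") stop("ellipticity_at needs a CD spectrum")
  if (wavelength < 200 || wavelength > 260)
    stop("wavelength outside the far-UV range 200-260 nm")
  intensity_at(spectrum, wavelength)
}

#' Assemble a titration profile from a stack of scans
#'
#' Evaluates one spectral feature per scan and assembles the values into a
#' [chemical_curve()] ordered by denaturant concentration, ready for
#' [fit_chemical_two_state()] / [fit_chemical_three_state()].
#'
#' @param stack List of [emission_scan()] objects with distinct
#'   `sample_concentration` values (at least 10).
#' @param feature One of `"lambda_max"`, `"I_max"`, `"I_at"`, `"ratio"`,
#'   `"ellipticity_at"`.
#' @param wavelength Wavelength for `"I_at"` / `"ellipticity_at"` (nm).
#' @param num_nm,den_nm Wavelengths for `"ratio"`.
#' @param denaturant Denaturant label for the resulting curve.
#' @param temperature Temperature of the titration, kelvin.
#' @param smoothing_window Moving-average window for `"lambda_max"` and
#'   `"I_max"` (default 5).
#' @param ... Further arguments passed to the feature function (e.g.
#'   `refine`, `clamp_to_start`).
#' @return A [chemical_curve()] of the feature against concentration.
#' @export
build_titration_profile <- function(stack,
                                    feature = c("lambda_max", "I_max", "I_at",
                                                "ratio", "ellipticity_at"),
                                    wavelength = NULL, num_nm = NULL,
                                    den_nm = NULL,
                                    denaturant = c("urea", "guhcl"),
                                    temperature = 298.15,
                                    smoothing_window = 5, ...) {
  feature <- match.arg(feature)
  denaturant <- match.arg(denaturant)
  if (length(stack) < 10)
    stop("need at least 10 scans for a fittable titration profile")
  conc <- vapply(stack, function(s) s$sample_concentration, 0)
  vals <- vapply(seq_along(stack), function(i) {
    s <- stack[[i]]
    tryCatch(switch(feature,
      lambda_max = lambda_max(s, smoothing_window = smoothing_window, ...),
      I_max = max(moving_average(s$intensity, smoothing_window)),
      I_at = intensity_at(s, wavelength),
      ratio = intensity_ratio(s, num_nm, den_nm, ...),
      ellipticity_at = ellipticity_at(s, wavelength)),
      error = function(e)
        stop(sprintf("feature '%s' failed at %g M: %s", feature, conc[i],
                     conditionMessage(e)), call. = FALSE))
  }, 0)
  label <- switch(feature,
    lambda_max = "lambda_max",
    I_max = "I_max",
    I_at = sprintf("I_%g", wavelength),
    ratio = sprintf("I_%g/%g", num_nm, den_nm),
    ellipticity_at = sprintf("CD_%g", wavelength))
  chemical_curve(conc, vals, denaturant = denaturant, probe_label = label,
                 temperature = temperature)
}
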