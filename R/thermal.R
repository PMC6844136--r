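# Two-state thermal denaturation: van't Hoff model with linear native and
# unfolded baselines, fitted by Levenberg-Marquardt least squares, and the
# per-point free-energy series over the transition region.

#' Predict the observed signal of a two-state thermal melt
#'
#' Signal model for a reversible N <-> U transition followed by an optical
#' probe with linearly temperature-dependent native and unfolded baselines:
#' \deqn{Y(T) = \frac{(A_n + b_N T) + (A_u + b_U T)\,e^{x}}{1 + e^{x}},
#'   \quad x = \frac{\Delta H_g}{R}\left(\frac{1}{T_g} - \frac{1}{T}\right)}
#' At `T = Tg` the exponent vanishes and the signal is the midpoint of the two
#' baselines.
#'
#' @param fit A list or `two_state_thermal_fit` with elements `An`, `bN`,
#'   `Au`, `bU`, `dHg` (kJ/mol), `Tg` (K) — or a `coef` vector so named.
#' @param temperature Temperatures in kelvin (vectorized).
#' @return Predicted signal values.
#' @examples
#' p <- list(An = 0, bN = 0, Au = 1, bU = 0, dHg = 779.20, Tg = 329)
#' predict_thermal_signal(p, 329) # exactly between the baselines: 0.5
#' @export
predict_thermal_signal <- function(fit, temperature) {
  p <- thermal_params(fit)
  stopifnot(all(temperature > 0))
  ex <- exp(clip_exp((p["dHg"] / RGAS) * (1 / p["Tg"] - 1 / temperature)))
  yn <- p["An"] + p["bN"] * temperature
  yu <- p["Au"] + p["bU"] * temperature
  unname((yn + yu * ex) / (1 + ex))
}

thermal_params <- function(fit) {
  nm <- c("An", "bN", "Au", "bU", "dHg", "Tg")
  if (!is.null(fit$coef)) return(fit$coef[nm])
  p <- unlist(fit[nm])
  if (anyNA(p)) stop("thermal parameters must include ",
                     paste(nm, collapse = ", "))
  p
}

#' Fraction of unfolded protein from signal and baselines
#'
#' \eqn{F_u = (Y_n - Y)/(Y_n - Y_u)}, where `Yn` and `Yu` are the native and
#' unfolded baseline signals extrapolated to the same temperature. The result
#' is clipped to `[eps, 1 - eps]` so that downstream logarithms stay finite;
#' clipping is reported via a message.
#'
#' @param Y Observed signal (vectorized).
#' @param Yn,Yu Native and unfolded baseline signals at the same points.
#' @param eps Clip margin, default 1e-6.
#' @return Fractions unfolded in `[eps, 1 - eps]`.
#' @export
fraction_unfolded <- function(Y, Yn, Yu, eps = 1e-6) {
  if (any(Yn == Yu)) stop("degenerate baselines: Yn == Yu")
  fu <- (Yn - Y) / (Yn - Yu)
  n_clip <- sum(fu < eps | fu > 1 - eps)
  if (n_clip > 0)
    message(sprintf("fraction_unfolded: clipped %d value(s) to [%g, %g]",
                    n_clip, eps, 1 - eps))
  pmin(pmax(fu, eps), 1 - eps)
}

#' Unfolding equilibrium constant from the fraction unfolded
#'
#' `k = Fu / (1 - Fu)`.
#'
#' @param Fu Fraction unfolded, strictly inside (0, 1).
#' @return Equilibrium constant(s).
#' @export
equilibrium_constant <- function(Fu) {
  if (any(Fu <= 0 | Fu >= 1)) stop("Fu must lie strictly inside (0, 1)")
  Fu / (1 - Fu)
}

#' Free energy of unfolding from an equilibrium constant
#'
#' \eqn{\Delta G = -R T \ln k}, in kJ/mol with R from [gas_constant()].
#'
#' @param k Equilibrium constant(s), > 0.
#' @param temperature Temperature(s) in kelvin.
#' @return Free energy in kJ/mol.
#' @export
free_energy_from_k <- function(k, temperature) {
  stopifnot(all(k > 0), all(temperature > 0))
  -RGAS * temperature * log(k)
}

# Robust straight line through a terminal segment of the curve; rlm guards
# against an outlier in a short baseline stretch, with lm as fallback.
baseline_line <- function(x, y) {
  fitted <- tryCatch(MASS::rlm(y ~ x, maxit = 50),
                     error = function(e) stats::lm(y ~ x),
                     warning = function(w) stats::lm(y ~ x))
  stats::coef(fitted)
}

thermal_init <- function(curve) {
  n <- length(curve$temperature)
  k <- max(2L, ceiling(0.15 * n))
  lo <- seq_len(k)
  hi <- seq.int(n - k + 1L, n)
  cn <- baseline_line(curve$temperature[lo], curve$signal[lo])
  cu <- baseline_line(curve$temperature[hi], curve$signal[hi])
  dy <- diff(curve$signal) / diff(curve$temperature)
  tm <- (curve$temperature[-1] + curve$temperature[-n]) / 2
  # central-difference slope magnitude peaks at the inflection, i.e. near Tg
  c(An = unname(cn[1]), bN = unname(cn[2]),
    Au = unname(cu[1]), bU = unname(cu[2]),
    dHg = 300, Tg = tm[which.max(abs(dy))])
}

#' Fit the two-state thermal denaturation model
#'
#' Nonlinear least squares of [predict_thermal_signal()] against a melt, by
#' Levenberg-Marquardt. Default starting values: native/unfolded baselines
#' from robust line fits to the first/last 15% of points, `Tg` at the
#' temperature of maximum absolute slope, `dHg` 300 kJ/mol. The fit is
#' deterministic given the curve and starting values.
#'
#' @param curve A [thermal_curve()].
#' @param init Optional named vector/list of starting values
#'   (`An, bN, Au, bU, dHg, Tg`); missing entries fall back to the defaults.
#' @return An object of class `two_state_thermal_fit`: list with `coef`
#'   (named estimates), `se` (asymptotic standard errors from the Jacobian at
#'   the optimum), `rss`, `n`, `temperature_range`, and `flags` (character
#'   vector, e.g. when `Tg` falls outside the data range or `dHg <= 0`).
#' @export
fit_thermal_two_state <- function(curve, init = NULL) {
  stopifnot(inherits(curve, "thermal_curve"))
  start <- thermal_init(curve)
  if (!is.null(init)) {
    init <- unlist(init)
    start[names(init)] <- init
  }
  resid_fn <- function(p) {
    names(p) <- names(start)
    curve$signal - predict_thermal_signal(as.list(p), curve$temperature)
  }
  out <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, maxfev = 10000,
                              ftol = 1e-12, ptol = 1e-12))
  if (out$info < 1 || out$info > 4)
    stop("thermal fit did not converge: ", out$message,
         " (last iterate: ", paste(signif(out$par, 6), collapse = ", "), ")")
  coefs <- out$par
  names(coefs) <- names(start)
  rss <- sum(out$fvec^2)
  se <- fit_standard_errors(out, length(curve$signal))
  names(se) <- names(start)
  flags <- character()
  if (coefs["Tg"] <= min(curve$temperature) ||
      coefs["Tg"] >= max(curve$temperature))
    flags <- c(flags, "Tg outside fitted temperature range")
  if (coefs["dHg"] <= 0)
    flags <- c(flags, "dHg <= 0: unfolding not endothermic at Tg")
  structure(list(coef = coefs, se = se, rss = rss,
                 n = length(curve$signal),
                 temperature_range = range(curve$temperature),
                 probe_label = curve$probe_label, flags = flags),
            class = "two_state_thermal_fit")
}

# Asymptotic SEs from the LM Jacobian: sqrt(diag((J'J)^-1) * rss / (n - p)).
fit_standard_errors <- function(lm_out, n) {
  p <- length(lm_out$par)
  rss <- sum(lm_out$fvec^2)
  covm <- tryCatch(solve(lm_out$hessian) * rss / max(n - p, 1),
                   error = function(e) NULL)
  if (is.null(covm)) return(rep(NaN, p))
  d <- diag(covm)
  ifelse(d >= 0, sqrt(d), NaN)
}

#' Restrict a melt to its transition region
#'
#' Keeps the points whose model-implied unfolding free energy
#' \eqn{\Delta G(T) = \Delta H_g (1 - T/T_g)} lies within `window_kJ` of zero
#' — the stretch of the melt where both species are populated enough for a
#' meaningful van't Hoff analysis.
#'
#' @param fit A `two_state_thermal_fit`.
#' @param curve The fitted [thermal_curve()].
#' @param window_kJ Half-width of the free-energy window, kJ/mol (default 5).
#' @return A [thermal_curve()] restricted to the transition region.
#' @export
transition_region <- function(fit, curve, window_kJ = 5) {
  p <- thermal_params(fit)
  dg <- p["dHg"] * (1 - curve$temperature / p["Tg"])
  keep <- abs(dg) <= window_kJ
  if (sum(keep) < 1)
    stop("no points inside the +/-", window_kJ,
         " kJ/mol window; widen the window")
  structure(list(temperature = curve$temperature[keep],
                 signal = curve$signal[keep],
                 probe_label = curve$probe_label,
                 wavelength_nm = curve$wavelength_nm),
            class = "thermal_curve")
}

#' Per-point van't Hoff series over a transition region
#'
#' For every point of `curve`, extrapolates the fitted native and unfolded
#' baselines, computes the fraction unfolded, the equilibrium constant and
#' \eqn{\Delta G = -RT\ln k}.
#'
#' @param fit A `two_state_thermal_fit`.
#' @param curve A [thermal_curve()], normally already restricted via
#'   [transition_region()].
#' @param eps Clip margin passed to [fraction_unfolded()].
#' @return A data frame of class `vant_hoff_series` with columns
#'   `temperature`, `Fu`, `k`, `dG`.
#' @export
vant_hoff_series <- function(fit, curve, eps = 1e-6) {
  p <- thermal_params(fit)
  yn <- p["An"] + p["bN"] * curve$temperature
  yu <- p["Au"] + p["bU"] * curve$temperature
  fu <- fraction_unfolded(curve$signal, yn, yu, eps = eps)
  k <- equilibrium_constant(fu)
  dg <- free_energy_from_k(k, curve$temperature)
  structure(data.frame(temperature = curve$temperature, Fu = fu, k = k,
                       dG = dg),
            class = c("vant_hoff_series", "data.frame"))
}

#' @export
print.two_state_thermal_fit <- function(x, ...) {
  cat("Two-state thermal fit\n")
  cat(sprintf("  Tg  = %.3f K (se %.3g)\n", x$coef["Tg"], x$se["Tg"]))
  cat(sprintf("  dHg = %.2f kJ/mol (se %.3g)\n", x$coef["dHg"], x$se["dHg"]))
  cat(sprintf("  RSS = %.4g over %d points\n", x$rss, x$n))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
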