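# Two- and three-state chemical (urea/GuHCl) equilibrium unfolding under the
# linear extrapolation method (LEM): each step's free energy varies linearly
# with denaturant, dG_step(D) = dG_step - m_step * D. The three-state scheme
# N <-> I <-> U has step equilibrium constants
#   K1 = exp(-(dG_NI - m_NI*D)/(R*T)),  K2 = exp(-(dG_IU - m_IU*D)/(R*T))
# and species populations from the partition function Z = 1 + K1 + K1*K2,
# which keeps the three fractions non-negative and summing to one. (Typeset
# versions of the signal equation sometimes carry a minus sign in the
# denominator; only the all-plus partition function normalizes populations.)

#' Species fractions of a three-state unfolding equilibrium
#'
#' Populations of native, intermediate and unfolded states at denaturant
#' concentration `D` under the LEM, from the Boltzmann weights
#' `1 : K1 : K1*K2` of the partition function `Z = 1 + K1 + K1*K2`.
#' At `D = dG_NI/m_NI` the first step is at its midpoint and `fN == fI`.
#'
#' @param dG_NI,m_NI Free energy (kJ/mol) and m-value (kJ/mol/M) of the
#'   native-to-intermediate step at zero denaturant.
#' @param dG_IU,m_IU Same for the intermediate-to-unfolded step.
#' @param temperature Temperature in kelvin (default 298.15).
#' @param D Molar denaturant concentration(s), >= 0 (vectorized).
#' @return A data frame with columns `D`, `fN`, `fI`, `fU`; rows sum to 1.
#' @examples
#' species_fractions(30.88, 13.11, 35.04, 7.99, D = c(0, 2.35, 4.5, 8))
#' @export
species_fractions <- function(dG_NI, m_NI, dG_IU, m_IU,
                              temperature = 298.15, D) {
  stopifnot(temperature > 0, all(D >= 0))
  rt <- RGAS * temperature
  K1 <- exp(clip_exp(-(dG_NI - m_NI * D) / rt))
  K2 <- exp(clip_exp(-(dG_IU - m_IU * D) / rt))
  z <- 1 + K1 + K1 * K2
  data.frame(D = D, fN = 1 / z, fI = K1 / z, fU = K1 * K2 / z)
}

chemical3_params <- function(fit) {
  nm <- c("An", "bN", "Ai", "bI", "Au", "bU", "dG_NI", "m_NI", "dG_IU", "m_IU")
  if (!is.null(fit$coef)) p <- fit$coef[nm] else p <- unlist(fit[nm])
  if (anyNA(p)) stop("three-state parameters must include ",
                     paste(nm, collapse = ", "))
  p
}

chemical2_params <- function(fit) {
  nm <- c("An", "bN", "Au", "bU", "dG", "m")
  if (!is.null(fit$coef)) p <- fit$coef[nm] else p <- unlist(fit[nm])
  if (anyNA(p)) stop("two-state parameters must include ",
                     paste(nm, collapse = ", "))
  p
}

#' Predict the observed signal of a three-state titration
#'
#' Population-weighted signal with linear per-state baselines:
#' \deqn{Y(D) = (A_n + b_N D) f_N + (A_i + b_I D) f_I + (A_u + b_U D) f_U}
#' with fractions from [species_fractions()]. This equals the usual explicit
#' ratio form of the three-state LEM signal equation written with the
#' normalizing partition function `1 + K1 + K1*K2`.
#'
#' @param fit A `three_state_chemical_fit` or list with the ten parameters
#'   `An, bN, Ai, bI, Au, bU, dG_NI, m_NI, dG_IU, m_IU` and optionally
#'   `temperature` (default 298.15 K).
#' @param D Molar denaturant concentration(s).
#' @return Predicted signal values.
#' @export
predict_chemical_signal <- function(fit, D) {
  p <- chemical3_params(fit)
  temperature <- if (!is.null(fit$temperature)) fit$temperature else 298.15
  f <- species_fractions(p["dG_NI"], p["m_NI"], p["dG_IU"], p["m_IU"],
                         temperature, D)
  unname((p["An"] + p["bN"] * D) * f$fN +
         (p["Ai"] + p["bI"] * D) * f$fI +
         (p["Au"] + p["bU"] * D) * f$fU)
}

predict_chemical_two_state <- function(fit, D) {
  p <- chemical2_params(fit)
  temperature <- if (!is.null(fit$temperature)) fit$temperature else 298.15
  K <- exp(clip_exp(-(p["dG"] - p["m"] * D) / (RGAS * temperature)))
  unname(((p["An"] + p["bN"] * D) + (p["Au"] + p["bU"] * D) * K) / (1 + K))
}

#' Denaturation midpoint of an unfolding step
#'
#' Under the LEM the two states of a step are equally populated where the
#' step free energy vanishes: `Cm = dG / m`.
#'
#' @param dG Step free energy at zero denaturant, kJ/mol.
#' @param m Step m-value, kJ/mol/M; must be positive.
#' @return Midpoint concentration in molar.
#' @examples
#' midpoint(30.88, 13.11) # urea Trp-fluorescence N-I midpoint, approx 2.36 M
#' @export
midpoint <- function(dG, m) {
  if (any(m <= 0)) stop("m must be positive")
  dG / m
}

# Shared initialization helpers -------------------------------------------

terminal_baselines <- function(D, Y) {
  n <- length(D)
  k <- max(2L, ceiling(0.15 * n))
  cn <- baseline_line(D[seq_len(k)], Y[seq_len(k)])
  cu <- baseline_line(D[seq.int(n - k + 1L, n)], Y[seq.int(n - k + 1L, n)])
  list(An = unname(cn[1]), bN = unname(cn[2]),
       Au = unname(cu[1]), bU = unname(cu[2]))
}

local_slopes <- function(D, Y) {
  list(mid = (D[-1] + D[-length(D)]) / 2, slope = diff(Y) / diff(D))
}

chemical_init3 <- function(curve) {
  D <- curve$concentration
  Y <- curve$signal
  bl <- terminal_baselines(D, Y)
  sl <- local_slopes(D, Y)
  n_s <- length(sl$slope)
  # the two steepest, well-separated slopes bracket the two midpoints
  steep1 <- which.max(abs(sl$slope))
  sep <- max(diff(range(D)) / 4, 0.5)
  far <- which(abs(sl$mid - sl$mid[steep1]) >= sep)
  steep2 <- if (length(far)) far[which.max(abs(sl$slope[far]))] else steep1
  cms <- sort(c(sl$mid[steep1], sl$mid[steep2]))
  # intermediate baseline: flattest stretch between the two transitions
  interior <- which(sl$mid > cms[1] & sl$mid < cms[2])
  if (!length(interior))
    interior <- which(sl$mid > min(D) + 0.15 * diff(range(D)) &
                      sl$mid < max(D) - 0.15 * diff(range(D)))
  if (!length(interior)) interior <- seq_len(n_s)
  flat <- interior[which.min(abs(sl$slope[interior]))]
  win <- intersect(max(1, flat - 2):min(n_s, flat + 2), interior)
  iD <- sl$mid[win]
  iY <- (Y[win] + Y[win + 1]) / 2
  ib <- if (length(iD) >= 2) baseline_line(iD, iY) else c(mean(iY), 0)
  m0 <- if (curve$denaturant == "urea") 10 else 25
  c(An = bl$An, bN = bl$bN, Ai = unname(ib[1]), bI = unname(ib[2]),
    Au = bl$Au, bU = bl$bU,
    dG_NI = m0 * max(cms[1], 0.2), m_NI = m0,
    dG_IU = m0 * max(cms[2], 0.4), m_IU = m0)
}

chemical_init2 <- function(curve) {
  D <- curve$concentration
  Y <- curve$signal
  bl <- terminal_baselines(D, Y)
  sl <- local_slopes(D, Y)
  cm <- sl$mid[which.max(abs(sl$slope))]
  m0 <- if (curve$denaturant == "urea") 10 else 25
  c(An = bl$An, bN = bl$bN, Au = bl$Au, bU = bl$bU,
    dG = m0 * max(cm, 0.2), m = m0)
}

# One LM solve; returns NULL on non-convergence so the caller can try the
# next start of the ladder.
lm_solve <- function(curve, start, lower, upper, predict) {
  resid_fn <- function(p) {
    names(p) <- names(start)
    fit <- c(as.list(p), list(temperature = curve$temperature))
    curve$signal - predict(fit, curve$concentration)
  }
  out <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, maxfev = 10000,
                         ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  # info 1-4: converged; 6-7: tolerance-limited at the optimum (accepted);
  # 0 (bad input) and 5 (iteration limit) are failures
  if (is.null(out) || !(out$info %in% c(1:4, 6, 7))) return(NULL)
  out
}

# Deterministic multistart: the default start plus fixed m-value variants.
# Sigmoid-plus-baselines least squares is multimodal (ridges along constant
# Cm, collapse of an unresolved step); restarting from a few spread m-values
# and keeping the lowest converged RSS reaches the global optimum reliably
# while staying deterministic given the curve.
run_chemical_fit <- function(curve, starts, lower, upper, predict) {
  best <- NULL
  best_rss <- Inf
  agree <- 0L
  for (start in starts) {
    start <- pmin(pmax(start, lower), upper)
    out <- lm_solve(curve, start, lower, upper, predict)
    if (is.null(out)) next
    rss <- sum(out$fvec^2)
    if (rss < best_rss * (1 - 1e-6)) {
      best <- out
      best_rss <- rss
      agree <- 1L
    } else if (abs(rss - best_rss) <= 1e-6 * max(best_rss, 1e-300)) {
      agree <- agree + 1L
    }
    # two independent starts agreeing on the optimum: stop the ladder
    if (agree >= 2L) break
  }
  if (is.null(best))
    stop("chemical fit did not converge from any starting point")
  best
}

m_ladder <- function(start, m_names, factors = c(1, 0.5, 2)) {
  lapply(factors, function(f) {
    s <- start
    s[m_names] <- s[m_names] * f
    # keep the implied midpoints fixed while scaling the slopes
    dg <- sub("^m", "dG", m_names)
    s[dg] <- s[dg] * f
    s
  })
}

#' Fit the three-state LEM model to a denaturant titration
#'
#' Levenberg-Marquardt least squares of [predict_chemical_signal()] against a
#' titration at the curve's temperature. Energetic parameters are bounded to
#' the physical region (`dG` in [0, 200] kJ/mol, `m` in (0, 200] kJ/mol/M).
#' Default starting values: terminal 15% segments for the native/unfolded
#' baselines, the flattest interior stretch for the intermediate baseline,
#' midpoints from the two steepest, well-separated local slopes, and m-values
#' of 10 (urea) or 25 (GuHCl) kJ/mol/M.
#'
#' @param curve A [chemical_curve()] spanning pre-, mid- and post-transition.
#' @param init Optional named starting values overriding the defaults.
#' @return An object of class `three_state_chemical_fit`: `coef`, `se`,
#'   `rss`, `n`, `Cm_NI = dG_NI/m_NI`, `Cm_IU = dG_IU/m_IU`, `temperature`,
#'   `denaturant`, `flags` (e.g. unresolved intermediate when
#'   `Cm_NI >= Cm_IU`, or an m-value pinned at its lower bound).
#' @export
fit_chemical_three_state <- function(curve, init = NULL) {
  stopifnot(inherits(curve, "chemical_curve"))
  if (!isTRUE(attr(curve, "fittable")))
    warning("titration does not span both baselines; fit may be unreliable")
  start <- chemical_init3(curve)
  if (!is.null(init)) {
    init <- unlist(init)
    start[names(init)] <- init
  }
  lower <- c(rep(-Inf, 6), 0, 1e-3, 0, 1e-3)
  upper <- c(rep(Inf, 6), 200, 200, 200, 200)
  starts <- m_ladder(start, c("m_NI", "m_IU"))
  # an early first transition can corrupt the terminal native-baseline
  # segment; a start with a flat native baseline through the first point
  # covers that case
  alt <- start
  alt["An"] <- curve$signal[1]
  alt["bN"] <- 0
  starts <- c(starts, m_ladder(alt, c("m_NI", "m_IU")))
  out <- run_chemical_fit(curve, starts, lower, upper,
                          predict_chemical_signal)
  coefs <- out$par
  names(coefs) <- names(start)
  se <- fit_standard_errors(out, length(curve$signal))
  names(se) <- names(start)
  flags <- character()
  if (coefs["m_NI"] <= 1e-3 || coefs["m_IU"] <= 1e-3)
    flags <- c(flags, "m-value pinned at lower bound")
  cm_ni <- coefs["dG_NI"] / coefs["m_NI"]
  cm_iu <- coefs["dG_IU"] / coefs["m_IU"]
  if (cm_ni >= cm_iu)
    flags <- c(flags, "Cm_NI >= Cm_IU: intermediate not resolved")
  structure(list(coef = coefs, se = se, rss = sum(out$fvec^2),
                 n = length(curve$signal),
                 Cm_NI = unname(cm_ni), Cm_IU = unname(cm_iu),
                 temperature = curve$temperature,
                 denaturant = curve$denaturant,
                 probe_label = curve$probe_label, flags = flags),
            class = "three_state_chemical_fit")
}

#' Fit the two-state LEM model to a denaturant titration
#'
#' Single-transition reduction of the three-state model: signal
#' \eqn{Y(D) = ((A_n + b_N D) + (A_u + b_U D) K)/(1 + K)} with
#' \eqn{K = \exp(-(\Delta G - mD)/(RT))}.
#'
#' @inheritParams fit_chemical_three_state
#' @return An object of class `two_state_chemical_fit` with `coef`, `se`,
#'   `rss`, `n`, `Cm = dG/m`, `temperature`, `denaturant`, `flags`.
#' @export
fit_chemical_two_state <- function(curve, init = NULL) {
  stopifnot(inherits(curve, "chemical_curve"))
  start <- chemical_init2(curve)
  if (!is.null(init)) {
    init <- unlist(init)
    start[names(init)] <- init
  }
  lower <- c(rep(-Inf, 4), 0, 1e-3)
  upper <- c(rep(Inf, 4), 200, 200)
  starts <- m_ladder(start, "m")
  out <- run_chemical_fit(curve, starts, lower, upper,
                          predict_chemical_two_state)
  coefs <- out$par
  names(coefs) <- names(start)
  se <- fit_standard_errors(out, length(curve$signal))
  names(se) <- names(start)
  flags <- if (coefs["m"] <= 1e-3) "m pinned at lower bound" else character()
  structure(list(coef = coefs, se = se, rss = sum(out$fvec^2),
                 n = length(curve$signal),
                 Cm = unname(coefs["dG"] / coefs["m"]),
                 temperature = curve$temperature,
                 denaturant = curve$denaturant,
                 probe_label = curve$probe_label, flags = flags),
            class = "two_state_chemical_fit")
}

#' Compare two- and three-state fits of the same titration
#'
#' Reports residual sums of squares, the AIC difference (parameter counts 6
#' vs 10) and the nested F-test, and recommends the three-state model when
#' the AIC improves by more than `aic_margin` and the F-test is significant
#' at `alpha`. Formalizes the usual visual judgement that a titration "fits
#' satisfactorily" to one scheme or the other.
#'
#' @param two A `two_state_chemical_fit`.
#' @param three A `three_state_chemical_fit` of the same curve.
#' @param n_points Number of data points both fits used.
#' @param aic_margin Required AIC improvement (default 2).
#' @param alpha F-test significance level (default 0.05).
#' @return A list of class `model_comparison`: `rss_two`, `rss_three`,
#'   `aic_two`, `aic_three`, `delta_aic` (two minus three), `F`, `p_value`,
#'   `selected` (`"two_state"` or `"three_state"`).
#' @export
compare_models <- function(two, three, n_points,
                           aic_margin = 2, alpha = 0.05) {
  stopifnot(inherits(two, "two_state_chemical_fit"),
            inherits(three, "three_state_chemical_fit"))
  if (two$n != n_points || three$n != n_points)
    stop("fits were not computed on the same ", n_points, "-point curve")
  k2 <- 6L
  k3 <- 10L
  if (n_points <= k3)
    stop("need more than ", k3, " points to test the three-state model")
  aic2 <- n_points * log(two$rss / n_points) + 2 * k2
  aic3 <- n_points * log(three$rss / n_points) + 2 * k3
  f <- ((two$rss - three$rss) / (k3 - k2)) / (three$rss / (n_points - k3))
  p <- if (f <= 0) 1 else stats::pf(f, k3 - k2, n_points - k3,
                                    lower.tail = FALSE)
  selected <- if ((aic2 - aic3) > aic_margin && p < alpha)
    "three_state" else "two_state"
  structure(list(rss_two = two$rss, rss_three = three$rss,
                 aic_two = aic2, aic_three = aic3,
                 delta_aic = aic2 - aic3, F = f, p_value = p,
                 selected = selected),
            class = "model_comparison")
}

#' Fit a titration with automatic model choice
#'
#' Fits both the two- and three-state LEM models and applies
#' [compare_models()]. When the three-state fit fails to converge — typical
#' for data without a resolvable intermediate, where the extra step is
#' unidentifiable — the two-state model is selected.
#'
#' @inheritParams fit_chemical_three_state
#' @param ... Passed to [compare_models()] (`aic_margin`, `alpha`).
#' @return A list: `selected` (`"two_state"`/`"three_state"`), `fit` (the
#'   selected fit), `two`, `three` (possibly `NULL`), `comparison` (possibly
#'   `NULL`).
#' @export
fit_chemical_auto <- function(curve, ...) {
  two <- fit_chemical_two_state(curve)
  three <- tryCatch(suppressWarnings(fit_chemical_three_state(curve)),
                    error = function(e) NULL)
  if (is.null(three))
    return(list(selected = "two_state", fit = two, two = two,
                three = NULL, comparison = NULL))
  cmp <- compare_models(two, three, length(curve$concentration), ...)
  list(selected = cmp$selected,
       fit = if (cmp$selected == "three_state") three else two,
       two = two, three = three, comparison = cmp)
}

#' Denaturant window where the intermediate dominates
#'
#' Finds the concentration interval where the intermediate fraction
#' `fI(D)` is at least `threshold`, by locating the maximum of `fI` and
#' bracketed root-finding of `fI(D) - threshold` on each side. When the
#' maximum never reaches the threshold the window is empty and the location
#' and height of the maximum are reported instead.
#'
#' @param fit A `three_state_chemical_fit` (or parameter list) with
#'   `Cm_NI < Cm_IU`.
#' @param threshold Population threshold in (0, 1); default 0.5. A threshold
#'   of 0 returns the whole axis `(0, Inf)`.
#' @param D_max Upper search bound in molar; default three times `Cm_IU`
#'   plus 1.
#' @return A list: `D_low`, `D_high` (NA when empty), `argmax`, `max_fI`,
#'   `empty`.
#' @export
intermediate_window <- function(fit, threshold = 0.5, D_max = NULL) {
  p <- chemical3_params(fit)
  temperature <- if (!is.null(fit$temperature)) fit$temperature else 298.15
  fI <- function(D) species_fractions(p["dG_NI"], p["m_NI"],
                                      p["dG_IU"], p["m_IU"],
                                      temperature, D)$fI
  if (is.null(D_max)) D_max <- 3 * (p["dG_IU"] / p["m_IU"]) + 1
  if (threshold <= 0)
    return(list(D_low = 0, D_high = Inf, argmax = NA_real_,
                max_fI = NA_real_, empty = FALSE))
  opt <- stats::optimize(fI, c(0, D_max), maximum = TRUE, tol = 1e-9)
  argmax <- opt$maximum
  max_fI <- opt$objective
  if (max_fI < threshold)
    return(list(D_low = NA_real_, D_high = NA_real_, argmax = argmax,
                max_fI = max_fI, empty = TRUE))
  g <- function(D) fI(D) - threshold
  D_low <- if (g(0) >= 0) 0 else
    stats::uniroot(g, lower = 0, upper = argmax, tol = 1e-9)$root
  hi <- argmax
  while (g(hi) >= 0 && hi < D_max * 10) hi <- hi + max(1, argmax)
  D_high <- if (g(hi) >= 0) Inf else
    stats::uniroot(g, lower = argmax, upper = hi, tol = 1e-9)$root
  list(D_low = D_low, D_high = D_high, argmax = argmax, max_fI = max_fI,
       empty = FALSE)
}

#' @export
print.three_state_chemical_fit <- function(x, ...) {
  cat(sprintf("Three-state %s fit [%s]\n", x$denaturant, x$probe_label))
  cat(sprintf("  N-I: dG = %.2f kJ/mol (se %.3g), m = %.2f, Cm = %.2f M\n",
              x$coef["dG_NI"], x$se["dG_NI"], x$coef["m_NI"], x$Cm_NI))
  cat(sprintf("  I-U: dG = %.2f kJ/mol (se %.3g), m = %.2f, Cm = %.2f M\n",
              x$coef["dG_IU"], x$se["dG_IU"], x$coef["m_IU"], x$Cm_IU))
  cat(sprintf("  RSS = %.4g over %d points\n", x$rss, x$n))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.two_state_chemical_fit <- function(x, ...) {
  cat(sprintf("Two-state %s fit [%s]\n", x$denaturant, x$probe_label))
  cat(sprintf("  dG = %.2f kJ/mol (se %.3g), m = %.2f, Cm = %.2f M\n",
              x$coef["dG"], x$se["dG"], x$coef["m"], x$Cm))
  cat(sprintf("  RSS = %.4g over %d points\n", x$rss, x$n))
  invisible(x)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (two- vs three-state)\n")
  cat(sprintf("  RSS: %.4g vs %.4g;  dAIC (2 - 3) = %.2f;  F p = %.3g\n",
              x$rss_two, x$rss_three, x$delta_aic, x$p_value))
  cat("  selected:", x$selected, "\n")
  invisible(x)
}
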