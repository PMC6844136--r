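# Gibbs-Helmholtz protein stability curve. With a temperature-independent
# heat-capacity change dCp, the fitted pair (dHg, Tg) from a melt determines
# dH(T), dS(T) and dG(T) over the whole temperature axis, including the
# cold-denaturation branch.

#' Stability-curve parameter set
#'
#' The triple (dHg, Tg, dCp) defining a protein stability curve: the van't
#' Hoff unfolding enthalpy at the melting temperature, the melting
#' temperature itself, and the unfolding heat-capacity change assumed
#' constant over the transition.
#'
#' @param dHg Unfolding enthalpy at `Tg`, kJ/mol (>= 0).
#' @param Tg Melting temperature, kelvin (> 0).
#' @param dCp Heat-capacity change of unfolding, kJ/mol/K; must be positive
#'   for a globular protein — a negative value is rejected.
#' @return An object of class `stability_parameters`.
#' @examples
#' stability_parameters(dHg = 779.20, Tg = 329, dCp = 17.57)
#' @export
stability_parameters <- function(dHg, Tg, dCp) {
  if (Tg <= 0) stop("Tg must be positive (kelvin)")
  if (dCp <= 0) stop("dCp must be positive for unfolding of a globular protein")
  if (dHg < 0) stop("dHg must be non-negative")
  structure(list(dHg = dHg, Tg = Tg, dCp = dCp),
            class = "stability_parameters")
}

#' Unfolding enthalpy at a temperature
#'
#' \eqn{\Delta H(T) = \Delta H_g + \Delta C_p (T - T_g)}.
#'
#' @param params A [stability_parameters()] object (or compatible list).
#' @param temperature Temperature(s) in kelvin.
#' @return Enthalpy in kJ/mol.
#' @export
enthalpy_at <- function(params, temperature) {
  stopifnot(all(temperature > 0))
  params$dHg + params$dCp * (temperature - params$Tg)
}

#' Unfolding entropy at a temperature
#'
#' \eqn{\Delta S(T) = \Delta H_g / T_g + \Delta C_p \ln(T / T_g)}.
#'
#' @inheritParams enthalpy_at
#' @return Entropy in kJ/mol/K.
#' @export
entropy_at <- function(params, temperature) {
  stopifnot(all(temperature > 0))
  params$dHg / params$Tg + params$dCp * log(temperature / params$Tg)
}

#' Stabilization free energy of the native state at a temperature
#'
#' The Gibbs-Helmholtz stability curve
#' \deqn{\Delta G(T) = \Delta H_g\left(1 - \frac{T}{T_g}\right) +
#'   \Delta C_p\left(T - T_g - T \ln\frac{T}{T_g}\right)}
#' which equals \eqn{\Delta H(T) - T \Delta S(T)} with the enthalpy and
#' entropy of [enthalpy_at()] and [entropy_at()]. With `dCp = 0` it reduces
#' to the linear van't Hoff form \eqn{\Delta H_g (1 - T/T_g)}.
#'
#' @inheritParams enthalpy_at
#' @return Free energy in kJ/mol; zero at `Tg` by construction.
#' @export
gibbs_at <- function(params, temperature) {
  stopifnot(all(temperature > 0))
  params$dHg * (1 - temperature / params$Tg) +
    params$dCp * (temperature - params$Tg -
                    temperature * log(temperature / params$Tg))
}

#' Characteristic temperatures of the stability curve
#'
#' Locates, for a stability curve with `dHg > 0` and `dCp > 0`:
#' \itemize{
#'   \item `Th = Tg - dHg/dCp`, where the unfolding enthalpy is zero
#'     (closed form);
#'   \item `Ts = Tg * exp(-dHg / (dCp * Tg))`, where the unfolding entropy is
#'     zero and the stability is maximal (closed form);
#'   \item `Tg_prime`, the cold-denaturation root of the stability curve
#'     below `Ts`, found by bracketed root-finding to 1e-6 K (the bracket is
#'     grown downward from `Ts` in 10 K steps to a floor of 150 K; if no sign
#'     change is found, `Tg_prime` is `NA` and a note records that no cold
#'     denaturation lies in range);
#'   \item `dGs_max = gibbs_at(params, Ts)`, the maximal stabilization free
#'     energy, and `dSm = dHg/Tg`, the unfolding entropy at `Tg`.
#' }
#' A sampled grid of (T, dH, dS, dG) spanning `[Tg_prime - 20, Tg + 20]` K at
#' 0.1 K is attached for plotting.
#'
#' @param params A [stability_parameters()] object.
#' @param grid_step Grid spacing in kelvin for the sampled curve (default 0.1).
#' @return An object of class `stability_curve`: list with `Th`, `Ts`, `Tg`,
#'   `Tg_prime`, `dGs_max`, `dSm`, `params`, `note` (only when the cold root
#'   is absent) and `grid` (data frame).
#' @examples
#' characteristic_temperatures(stability_parameters(779.20, 329, 17.57))
#' @export
characteristic_temperatures <- function(params, grid_step = 0.1) {
  stopifnot(inherits(params, "stability_parameters") || is.list(params))
  if (params$dCp <= 0) stop("dCp must be positive")
  Th <- params$Tg - params$dHg / params$dCp
  Ts <- params$Tg * exp(-params$dHg / (params$dCp * params$Tg))
  note <- NULL
  if (params$dHg == 0) {
    # degenerate curve: dG == 0 at Tg == Ts == Th
    Tg_prime <- params$Tg
  } else {
    lo <- Ts
    repeat {
      lo <- max(lo - 10, 150)
      if (gibbs_at(params, lo) <= 0 || lo <= 150) break
    }
    if (gibbs_at(params, lo) > 0) {
      Tg_prime <- NA_real_
      note <- "no cold denaturation in range (no sign change above 150 K)"
    } else {
      Tg_prime <- stats::uniroot(function(T) gibbs_at(params, T),
                                 lower = lo, upper = Ts,
                                 tol = 1e-6)$root
    }
  }
  dGs_max <- gibbs_at(params, Ts)
  g_lo <- if (is.na(Tg_prime)) Th - 20 else Tg_prime - 20
  grid_T <- seq(max(g_lo, 1), params$Tg + 20, by = grid_step)
  grid <- data.frame(temperature = grid_T,
                     dH = enthalpy_at(params, grid_T),
                     dS = entropy_at(params, grid_T),
                     dG = gibbs_at(params, grid_T))
  structure(list(Th = Th, Ts = Ts, Tg = params$Tg, Tg_prime = Tg_prime,
                 dGs_max = dGs_max, dSm = params$dHg / params$Tg,
                 params = unclass(params), note = note, grid = grid),
            class = "stability_curve")
}

#' Residual of the triangular relation Ts - Th = dGs / dCp
#'
#' For a stability curve with constant `dCp`, the distance between the
#' temperatures of zero entropy and zero enthalpy relates to the maximal
#' stability as \eqn{T_s - T_h = \Delta G_s / \Delta C_p}; the relation is
#' exact when `Ts` and `Th` are the exact roots, and acquires a small
#' residual when rounded inputs are used. This returns the residual
#' \eqn{(T_s - T_h) - \Delta G_s/\Delta C_p} for the caller to judge.
#'
#' @param result A `stability_curve` from [characteristic_temperatures()].
#' @return Residual in kelvin.
#' @export
triangular_relation_check <- function(result) {
  (result$Ts - result$Th) - result$dGs_max / result$params$dCp
}

#' @export
print.stability_curve <- function(x, ...) {
  cat("Protein stability curve\n")
  cat(sprintf("  Tg  = %.2f K   Tg' = %s K\n", x$Tg,
              if (is.na(x$Tg_prime)) "NA" else sprintf("%.2f", x$Tg_prime)))
  cat(sprintf("  Th  = %.2f K   Ts  = %.2f K\n", x$Th, x$Ts))
  cat(sprintf("  max dG = %.2f kJ/mol at Ts;  dSm = %.3f kJ/mol/K\n",
              x$dGs_max, x$dSm))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
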