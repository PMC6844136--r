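# Unfolding heat-capacity change from the change in accessible surface area,
# via the empirical affine correlation dCp = -251 + 0.19 * dASA. The
# coefficients carry an energy unit per mol per K per A^2; the convention
# ("cal" or "J") must be stated explicitly because the two readings differ by
# a factor of 4.184 and a silent default would be a classic unit bug.

#' Heat-capacity change of unfolding from the accessible-surface-area change
#'
#' Empirical estimate \eqn{\Delta C_p = -251 + 0.19\,\Delta ASA} in the
#' stated unit convention, converted to kJ/mol/K. For a ~36 kDa globular
#' protein, a plausible \eqn{\Delta ASA} of roughly 23,000 \eqn{\AA^2} under
#' the cal convention gives a \eqn{\Delta C_p} near 17.6 kJ/mol/K; the J
#' reading would require an implausibly large surface change, which is why
#' cal is the physically sensible choice — but the convention is still a
#' required argument.
#'
#' @param dASA Change in solvent-accessible surface area from the native to
#'   the unfolded conformation, in square angstroms; must be positive.
#'   (Computing it from structure, e.g. with an unfolded-ensemble server, is
#'   outside this package; the number is an input.)
#' @param unit_convention `"cal"` (coefficients in cal/mol/K) or `"J"`
#'   (J/mol/K). No default: state it.
#' @return A list of class `dcp_estimate`: `dCp_kJ` (kJ/mol/K), `raw` (in
#'   the convention's unit), `unit_convention`, `dASA`, and `flags`
#'   (non-empty when the result is non-positive, which is physically
#'   implausible for unfolding).
#' @examples
#' delta_cp_from_dasa(23421, unit_convention = "cal")
#' @export
delta_cp_from_dasa <- function(dASA, unit_convention) {
  if (missing(unit_convention))
    stop("unit_convention must be given explicitly: \"cal\" or \"J\"")
  unit_convention <- match.arg(unit_convention, c("cal", "J"))
  if (!is.finite(dASA) || dASA <= 0) stop("dASA must be a positive number")
  raw <- -251 + 0.19 * dASA
  dcp <- raw * if (unit_convention == "cal") 4.184e-3 else 1e-3
  flags <- if (dcp <= 0)
    "non-positive dCp: physically implausible for unfolding" else character()
  structure(list(dCp_kJ = dcp, raw = raw, unit_convention = unit_convention,
                 dASA = dASA, flags = flags),
            class = "dcp_estimate")
}

#' @export
print.dcp_estimate <- function(x, ...) {
  cat(sprintf("dCp = %.3f kJ/mol/K (raw %.1f %s/mol/K at dASA = %.0f A^2)\n",
              x$dCp_kJ, x$raw, x$unit_convention, x$dASA))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
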