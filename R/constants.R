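# Single source of truth for the gas constant. Every thermodynamic routine in
# the package reads R from here; units fix the package-wide conventions:
# energies in kJ/mol, entropies and heat capacities in kJ/mol/K, temperatures
# in kelvin, denaturant concentrations in molar.
RGAS <- 8.3145e-3

#' Gas constant used throughout the package
#'
#' Returns the molar gas constant in kJ mol^-1 K^-1. All free energies,
#' enthalpies and equilibrium constants computed by this package use this one
#' value, so ratios such as \eqn{\Delta G / RT} are consistent everywhere.
#'
#' @return The gas constant, 8.3145e-3 kJ mol^-1 K^-1.
#' @examples
#' gas_constant() * 298.15 # RT at 25 degrees C, approx. 2.479 kJ/mol
#' @export
gas_constant <- function() RGAS

# Clip an exponent argument before exp() so extreme parameter values saturate
# populations instead of overflowing to Inf/NaN.
clip_exp <- function(x, limit = 700) pmin(pmax(x, -limit), limit)
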