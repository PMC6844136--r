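# Synthetic melts, titrations and emission-scan stacks with known ground
# truth: the forward models of the fitting modules plus seeded homoscedastic
# Gaussian noise (standard deviation expressed as a fraction of the noiseless
# signal range, so probes with different absolute scales are comparable).
#
# Seeding: every generator takes one integer seed and restores the caller's
# RNG state afterwards. make_fixture_suite() derives a fixed per-fixture
# offset from its base seed (stream splitting by table), so adding a fixture
# never changes the ones already generated.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Reference parameter presets for human aldose reductase unfolding
#'
#' Ground-truth parameter sets used as generator defaults: the two-state
#' thermal parameters of the hAR melt followed by far-UV CD at 222 nm, and
#' the six self-consistent three-state titration parameter rows (denaturant x
#' probe) from the equilibrium unfolding of hAR, with per-probe baseline
#' choices appropriate to each signal type. Names: `"thermal"`,
#' `"urea_trp"`, `"urea_ans"`, `"urea_cd"`, `"guhcl_trp"`, `"guhcl_ans"`,
#' `"guhcl_cd"`.
#'
#' @param name Preset name; omit to get the list of all presets.
#' @return A named list of ground-truth parameters (or list of lists).
#' @examples
#' unfolding_presets("urea_trp")$dG_NI
#' names(unfolding_presets())
#' @export
unfolding_presets <- function(name = NULL) {
  fluor <- list(An = 1.0, bN = -0.010, Ai = 0.55, bI = -0.005,
                Au = 0.20, bU = -0.002)
  ans <- list(An = 0.30, bN = -0.005, Ai = 1.50, bI = -0.020,
              Au = 0.10, bU = -0.001)
  cd <- list(An = -20, bN = 0.05, Ai = -12, bI = 0.05, Au = -3, bU = 0.02)
  chem <- function(bl, dG_NI, m_NI, dG_IU, m_IU, denaturant, probe_label)
    c(bl, list(dG_NI = dG_NI, m_NI = m_NI, dG_IU = dG_IU, m_IU = m_IU,
               temperature = 298.15, denaturant = denaturant,
               probe_label = probe_label))
  presets <- list(
    thermal = list(An = -2, bN = 0.001, Au = -20, bU = 0.01,
                   dHg = 779.20, Tg = 329, probe_label = "CD222"),
    urea_trp = chem(fluor, 30.88, 13.11, 35.04, 7.99, "urea", "Trp F314"),
    urea_ans = chem(ans, 28.61, 12.10, 38.60, 8.95, "urea", "ANS F480"),
    urea_cd = chem(cd, 30.53, 14.12, 24.43, 5.99, "urea", "CD 221.8"),
    guhcl_trp = chem(fluor, 9.47, 48.34, 58.34, 23.56, "guhcl", "Trp F314"),
    guhcl_ans = chem(ans, 16.48, 38.99, 57.26, 22.38, "guhcl", "ANS F480"),
    guhcl_cd = chem(cd, 13.68, 32.17, 34.13, 14.90, "guhcl", "CD 219")
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' Gaussian emission-peak models per state
#'
#' Per-state peak models (center, width, amplitude) for synthetic
#' emission-scan stacks. The `"ans"` preset gives the intermediate a peak 20
#' nm blue of the native one with three times its amplitude — the classic
#' molten-globule ANS signature of enhanced, blue-shifted dye emission; the
#' `"trp"` preset red-shifts and quenches from native (337 nm) to unfolded
#' (350 nm), as buried tryptophans become solvent-exposed.
#'
#' @param name `"trp"` or `"ans"`.
#' @return A list with elements `N`, `I`, `U`, each `c(center, width, amp)`
#'   in (nm, nm, arbitrary units).
#' @export
spectral_presets <- function(name = c("trp", "ans")) {
  name <- match.arg(name)
  switch(name,
    trp = list(N = c(center = 337, width = 25, amp = 1.00),
               I = c(center = 341, width = 25, amp = 0.85),
               U = c(center = 350, width = 28, amp = 0.60)),
    ans = list(N = c(center = 520, width = 40, amp = 1.0),
               I = c(center = 500, width = 40, amp = 3.0),
               U = c(center = 535, width = 45, amp = 0.4)))
}

add_noise <- function(y, noise, seed) {
  if (noise <= 0) return(y)
  rng <- diff(range(y))
  with_seed(seed, y + stats::rnorm(length(y), sd = noise * rng))
}

#' Generate a synthetic thermal melt
#'
#' Forward model of [predict_thermal_signal()] over a temperature grid plus
#' seeded Gaussian noise. The generated curve carries its ground truth
#' (including noise level and seed) as attribute `"ground_truth"`.
#'
#' @param truth Thermal parameter list (`An, bN, Au, bU, dHg, Tg`); default
#'   the `"thermal"` preset of [unfolding_presets()].
#' @param T_grid Temperature grid in kelvin; default 293-343 K at 0.5 K,
#'   the 20-70 degrees C window of a typical melt.
#' @param noise Noise standard deviation as a fraction of the noiseless
#'   signal range (default 0).
#' @param seed Integer seed for the noise stream.
#' @return A [thermal_curve()] with attribute `ground_truth`.
#' @export
generate_thermal_curve <- function(truth = unfolding_presets("thermal"),
                                   T_grid = seq(293, 343, by = 0.5),
                                   noise = 0, seed = 1) {
  stopifnot(length(T_grid) >= 8)
  y <- predict_thermal_signal(truth, T_grid)
  y <- add_noise(y, noise, seed)
  curve <- thermal_curve(T_grid, y, unit = "kelvin",
                         probe_label = if (!is.null(truth$probe_label))
                           truth$probe_label else "synthetic")
  attr(curve, "ground_truth") <- c(truth, list(noise = noise, seed = seed))
  curve
}

default_D_grid <- function(denaturant)
  if (denaturant == "urea") seq(0, 8, by = 0.25) else seq(0, 6, by = 0.2)

#' Generate a synthetic denaturant titration
#'
#' Forward model of [predict_chemical_signal()] (three-state truth) or the
#' two-state reduction (when the truth has `dG`/`m` instead of the step
#' parameters) over a concentration grid, plus seeded Gaussian noise.
#'
#' @param truth Chemical parameter list; default the `"urea_trp"` preset.
#'   Three-state truths carry `dG_NI, m_NI, dG_IU, m_IU`; two-state truths
#'   `dG, m` (with baselines `An, bN, Au, bU` either way).
#' @param D_grid Concentration grid in molar; defaults to 0-8 M step 0.25
#'   (urea) or 0-6 M step 0.2 (GuHCl).
#' @param noise Fraction-of-range noise standard deviation (default 0).
#' @param seed Integer seed.
#' @return A [chemical_curve()] with attribute `ground_truth`.
#' @export
generate_chemical_curve <- function(truth = unfolding_presets("urea_trp"),
                                    D_grid = NULL, noise = 0, seed = 1) {
  denaturant <- if (!is.null(truth$denaturant)) truth$denaturant else "urea"
  if (is.null(D_grid)) D_grid <- default_D_grid(denaturant)
  y <- if (!is.null(truth$dG_NI)) predict_chemical_signal(truth, D_grid)
       else predict_chemical_two_state(truth, D_grid)
  y <- add_noise(y, noise, seed)
  curve <- chemical_curve(D_grid, y, denaturant = denaturant,
                          probe_label = if (!is.null(truth$probe_label))
                            truth$probe_label else "synthetic",
                          temperature = if (!is.null(truth$temperature))
                            truth$temperature else 298.15)
  attr(curve, "ground_truth") <- c(truth, list(noise = noise, seed = seed))
  curve
}

gaussian_peak <- function(wl, p)
  p["amp"] * exp(-((wl - p["center"])^2) / (2 * p["width"]^2))

#' Generate a synthetic emission-scan stack along a titration
#'
#' Each scan is the population-weighted sum of per-state Gaussian emission
#' peaks, with state populations from the three-state chemical truth at that
#' concentration, plus seeded noise. Gaussian band shapes are a pragmatic
#' stand-in for real (asymmetric) emission bands; the features extracted
#' downstream — peak position, peak height, channel intensities — do not
#' depend on the true band shape.
#'
#' @param truth Three-state chemical truth (energetics + temperature);
#'   default the `"urea_trp"` preset.
#' @param spectral Per-state peak models as from [spectral_presets()];
#'   default the `"ans"` preset.
#' @param D_grid Concentration grid; defaults as in
#'   [generate_chemical_curve()].
#' @param wavelength_grid Wavelength grid in nm; default chosen from the
#'   probe implied by `spectral` (400-600 nm for ANS-like, 300-400 for
#'   Trp-like centers).
#' @param noise Fraction-of-range noise per scan (default 0).
#' @param seed Integer seed; scan `i` uses `seed + i`.
#' @return List of [emission_scan()] objects with attribute `ground_truth`.
#' @export
generate_emission_stack <- function(truth = unfolding_presets("urea_trp"),
                                    spectral = spectral_presets("ans"),
                                    D_grid = NULL, wavelength_grid = NULL,
                                    noise = 0, seed = 1) {
  denaturant <- if (!is.null(truth$denaturant)) truth$denaturant else "urea"
  if (is.null(D_grid)) D_grid <- default_D_grid(denaturant)
  ans_like <- spectral$N["center"] > 450
  if (is.null(wavelength_grid))
    wavelength_grid <- if (ans_like) seq(400, 600, by = 1)
                       else seq(300, 400, by = 1)
  probe <- if (ans_like) "ANS" else "Trp"
  excitation <- if (ans_like) 370 else 295
  temperature <- if (!is.null(truth$temperature)) truth$temperature else 298.15
  f <- species_fractions(truth$dG_NI, truth$m_NI, truth$dG_IU, truth$m_IU,
                         temperature, D_grid)
  stack <- lapply(seq_along(D_grid), function(i) {
    y <- f$fN[i] * gaussian_peak(wavelength_grid, spectral$N) +
         f$fI[i] * gaussian_peak(wavelength_grid, spectral$I) +
         f$fU[i] * gaussian_peak(wavelength_grid, spectral$U)
    y <- add_noise(y, noise, seed + i)
    emission_scan(wavelength_grid, pmax(y, 0), excitation_nm = excitation,
                  sample_concentration = D_grid[i], probe = probe)
  })
  attr(stack, "ground_truth") <- c(truth, list(spectral = spectral,
                                               noise = noise, seed = seed))
  stack
}

write_stack_csv <- function(stack, path) {
  wl <- stack[[1]]$wavelength_nm
  cols <- vapply(stack, function(s) s$sample_concentration, 0)
  mat <- vapply(stack, function(s) s$intensity, numeric(length(wl)))
  lines <- c(paste(c("wavelength_nm", sprintf("%gM", cols)), collapse = ","),
             vapply(seq_along(wl), function(i)
               paste(sprintf("%.17g", c(wl[i], mat[i, ])), collapse = ","),
               ""))
  writeLines(lines, path)
  invisible(path)
}

truth_sidecar <- function(obj, path) {
  gt <- attr(obj, "ground_truth")
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the standard synthetic fixture suite
#'
#' Generates and writes the package's standard test bed: one thermal melt,
#' six titrations (urea and GuHCl for Trp-, ANS- and CD-like probes, using
#' the reference hAR parameter rows) and two emission stacks (Trp and ANS
#' presets with the urea energetics), each as CSV with a ground-truth JSON
#' sidecar. Fixture noise is 1% of range. Per-fixture seeds are
#' `seed + offset` with a fixed offset table, so the suite is byte-identical
#' across runs with the same seed and insensitive to fixture additions.
#'
#' @param output_dir Writable output directory (created if needed).
#' @param seed Base integer seed (default 42).
#' @param noise Fraction-of-range noise for all fixtures (default 0.01).
#' @return Invisibly, a character vector of the files written.
#' @export
make_fixture_suite <- function(output_dir, seed = 42, noise = 0.01) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  put <- function(x) written <<- c(written, x)

  melt <- generate_thermal_curve(noise = noise, seed = seed + 1)
  put(write_curve_csv(melt, file.path(output_dir, "thermal_melt.csv")))
  put(truth_sidecar(melt, file.path(output_dir, "thermal_melt.truth.json")))

  chems <- c("urea_trp", "urea_ans", "urea_cd",
             "guhcl_trp", "guhcl_ans", "guhcl_cd")
  for (i in seq_along(chems)) {
    cur <- generate_chemical_curve(unfolding_presets(chems[i]),
                                   noise = noise, seed = seed + 1 + i)
    base <- file.path(output_dir, paste0("titration_", chems[i]))
    put(write_curve_csv(cur, paste0(base, ".csv")))
    put(truth_sidecar(cur, paste0(base, ".truth.json")))
  }

  stacks <- list(trp = spectral_presets("trp"), ans = spectral_presets("ans"))
  for (i in seq_along(stacks)) {
    st <- generate_emission_stack(unfolding_presets("urea_trp"),
                                  spectral = stacks[[i]],
                                  noise = noise, seed = seed + 100 * i)
    base <- file.path(output_dir, paste0("stack_", names(stacks)[i]))
    put(write_stack_csv(st, paste0(base, ".csv")))
    put(truth_sidecar(st, paste0(base, ".truth.json")))
  }
  invisible(written)
}
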