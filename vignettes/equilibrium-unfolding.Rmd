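---
title: "Equilibrium unfolding analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium unfolding analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unfoldfit)
```

`unfoldfit` analyses protein equilibrium unfolding followed by optical
probes — far-UV circular dichroism, intrinsic tryptophan fluorescence, and
ANS dye fluorescence. It was built around the unfolding behaviour of human
aldose reductase (hAR), a ~36 kDa (β/α)~8~ barrel that melts as an apparent
two-state system under heat but passes through a partially folded
intermediate under urea or guanidine hydrochloride. This vignette explains
the models, the tunable parameters, the synthetic test bed, and the design
decisions that were genuinely open.

## Two-state thermal denaturation

A melt followed by an optical signal $Y(T)$ is modelled as a reversible
N $\leftrightarrow$ U transition flanked by linear baselines:

$$Y(T) = \frac{(A_n + b_N T) + (A_u + b_U T)\,e^{x}}{1 + e^{x}},
  \qquad x = \frac{\Delta H_g}{R}\Bigl(\frac{1}{T_g} - \frac{1}{T}\Bigr),$$

with $\Delta H_g$ the van't Hoff enthalpy at the melting temperature $T_g$.
All six parameters are estimated by Levenberg–Marquardt least squares
(`fit_thermal_two_state()`). Temperatures are kelvin internally; Celsius
input is converted on read (`unit = "auto"` assumes Celsius when the minimum
is below 100, since no melt is recorded below 100 K).

Starting values are automatic and deterministic: robust straight lines
through the first and last 15% of points give the baselines, the temperature
of steepest slope gives $T_g$, and $\Delta H_g$ starts at 300 kJ/mol, a
typical magnitude for a mid-size globular protein. Standard errors are
asymptotic, from the Jacobian at the optimum.

The van't Hoff analysis (`transition_region()`, `vant_hoff_series()`)
restricts the melt to the points whose model-implied $|\Delta G(T)|$ is
within 5 kJ/mol of zero — outside that window the minority species is too
scarce for the signal to carry free-energy information — and converts signal
to fraction unfolded $F_u = (Y_n - Y)/(Y_n - Y_u)$, equilibrium constant
$k = F_u/(1 - F_u)$, and $\Delta G = -RT\ln k$. $F_u$ is clipped to
$[10^{-6}, 1 - 10^{-6}]$ before the logarithm; noise at the baselines
otherwise produces infinities. Clip events are reported.

## The stability curve

With a temperature-independent heat-capacity change $\Delta C_p$, the melt
parameters extend to the whole temperature axis (Gibbs–Helmholtz):

$$\Delta G(T) = \Delta H_g\Bigl(1 - \frac{T}{T_g}\Bigr) +
  \Delta C_p\Bigl(T - T_g - T\ln\frac{T}{T_g}\Bigr).$$

`characteristic_temperatures()` computes the landmarks in closed form where
one exists: $T_h = T_g - \Delta H_g/\Delta C_p$ (zero enthalpy) and
$T_s = T_g\,e^{-\Delta H_g/(\Delta C_p T_g)}$ (zero entropy, maximal
stability). The cold-denaturation root $T_g'$ has no closed form and is
found by bracketed root-finding (`uniroot`, tolerance $10^{-6}$ K), growing
the bracket downward from $T_s$ in 10 K steps to a floor of 150 K; if
$\Delta G$ never changes sign above the floor, the result reports "no cold
denaturation in range" rather than failing, because shallow stability curves
legitimately have no accessible cold branch. The sampled grid spans
$[T_g' - 20, T_g + 20]$ K at 0.1 K, wide enough to plot both branches.

For the hAR reference parameters ($\Delta H_g$ = 779.20 kJ/mol, $T_g$ =
329 K, $\Delta C_p$ = 17.57 kJ/mol/K) the landmarks are $T_h$ = 284.65 K,
$T_s$ = 287.51 K, $T_g'$ ≈ 248 K, and a maximal stability near 50 kJ/mol —
values the test suite recomputes.

One relation deserves a note. The triangular identity
$T_s - T_h = \Delta G_s/\Delta C_p$ is often quoted as an approximation; it
is in fact *exact* when $T_s$ is the exact entropy-zero root (substitute
$\ln(T_s/T_g) = -\Delta H_g/(\Delta C_p T_g)$ into $\Delta G(T_s)$ and the
identity falls out). A residual appears only when rounded, printed values
are mixed. `triangular_relation_check()` therefore returns the residual and
lets the caller judge it.

$\Delta C_p$ itself comes from the empirical surface-area correlation
$\Delta C_p = -251 + 0.19\,\Delta ASA$ (`delta_cp_from_dasa()`). The
coefficients' energy unit is ambiguous in parts of the literature, and the
two readings differ by 4.184-fold, so the convention is a *required*
argument. The cal reading is the physically sensible one here: it places a
~36 kDa protein's $\Delta ASA$ near 23,000 Å², where the J reading would
demand an implausible ~94,000 Å². Computing $\Delta ASA$ from structure is
out of scope; it is a numeric input.

## Chemical unfolding under the linear extrapolation method

Each unfolding step's free energy is assumed linear in denaturant:
$\Delta G_\mathrm{step}(D) = \Delta G_\mathrm{step} - m_\mathrm{step} D$.
For the three-state scheme N $\leftrightarrow$ I $\leftrightarrow$ U the
step constants are $K_1 = e^{-(\Delta G_{NI} - m_{NI}D)/RT}$ and
$K_2 = e^{-(\Delta G_{IU} - m_{IU}D)/RT}$, and populations follow from the
partition function

$$Z = 1 + K_1 + K_1 K_2, \qquad
  f_N = 1/Z,\; f_I = K_1/Z,\; f_U = K_1 K_2/Z.$$

This all-plus form is the package's single most important modelling
decision: typeset versions of the three-state signal equation sometimes
carry a minus sign in the denominator, which makes the "populations"
non-normalized and potentially negative. Only $Z = 1 + K_1 + K_1K_2$ keeps
the three fractions in $[0,1]$ summing to one, reproduces the correct
two-state limits, and preserves the midpoint identities $C_m = \Delta G/m$.
The observed signal is the population-weighted sum of linear per-state
baselines, which is algebraically identical to the explicit ratio form with
this $Z$ (the test suite checks the equivalence on random parameter draws).

Fitting (`fit_chemical_three_state()`, `fit_chemical_two_state()`) is
Levenberg–Marquardt with box bounds keeping the energetics physical
($\Delta G \in [0, 200]$ kJ/mol, $m \in (0, 200]$ kJ/mol/M). Starting
values: terminal 15% segments for the outer baselines, the flattest interior
stretch for the intermediate baseline, midpoints from the two steepest,
well-separated local slopes, and m-values of 10 (urea) or 25 (GuHCl)
kJ/mol/M — typical magnitudes for these denaturants. Because this least
squares problem is multimodal (ridges of nearly constant $C_m$, collapse of
an unresolved step to the bound), each fit also tries a small fixed ladder
of m-value variants and keeps the lowest converged residual; the procedure
stays deterministic given the curve. Exponent arguments are clipped at
$\pm 700$ so extreme parameters saturate populations instead of overflowing.

`compare_models()` formalizes the two- vs three-state choice: AIC with
parameter counts 6 vs 10 and the nested F-test, recommending three states
when the AIC improves by more than 2 *and* the F-test is significant at
0.05. Both thresholds are the conventional defaults and are arguments. Note
the joint rule still has a null error rate of roughly 4%, so on data that
are truly two-state an occasional spurious three-state call is expected.
`intermediate_window()` maps where $f_I$ exceeds a threshold (default 0.5)
by bracketed root-finding around the population maximum; an empty window is
reported with the location and height of the maximum rather than an error.

## Spectral features

`lambda_max()` reports the wavelength of maximum emission after a 5-point
moving average — raw fluorescence maxima on 1 nm grids are noise-dominated,
and whether published maxima were smoothed is usually unstated, so the
window is configurable and 1 disables it. Ties break toward the shorter
wavelength so that blue-shift detection is conservative. An optional
parabolic-vertex refinement over the three points around the discrete
maximum gives sub-grid resolution. `intensity_at()` interpolates linearly
and refuses to extrapolate. Figure conventions that label a ratio with the
*excitation* wavelength (e.g. a 295 nm label on a scan recorded from
300 nm) are handled by an explicit `clamp_to_start` opt-in rather than
silent extrapolation. `build_titration_profile()` turns a stack of scans
into a `chemical_curve` of any feature, ready for the LEM fits — the
titration analysis does not care whether its input came from a single
wavelength channel or a derived feature.

CD wavelengths for chemical unfolding are a user parameter, not a constant:
published analyses variously use 219, 221.8 or 222 nm depending on
denaturant and instrument, so `ellipticity_at()` takes the wavelength
explicitly.

## The synthetic test bed

`unfolding_presets()` carries the reference hAR ground truth: the thermal
row ($\Delta H_g$ = 779.20 kJ/mol, $T_g$ = 329 K) and the six
denaturant-by-probe titration rows. Generators produce melts (293–343 K at
0.5 K, the standard 20–70 °C window), titrations (0–8 M urea at 0.25 M;
0–6 M GuHCl at 0.2 M) and emission-scan stacks, adding homoscedastic
Gaussian noise parameterized as a fraction of the noiseless signal range so
probes with different absolute scales are comparable. Emission bands are
Gaussian in wavelength — real Trp bands are asymmetric, but the extracted
features (peak position, height, channel intensities) do not depend on band
shape. The ANS spectral preset encodes the molten-globule signature: an
intermediate peak 20 nm blue of the native one at three times its
amplitude. Every generated object embeds its ground truth and seed; one
seed drives everything, and the fixture suite derives fixed per-fixture
offsets so adding a fixture never changes existing ones.

What the generator does *not* emulate: sloping instrument drift beyond
linear baselines, heteroscedastic or correlated noise, photobleaching,
inner-filter effects, aggregation, and irreversibility. Passing recovery
tests therefore demonstrate correctness of the estimation machinery under
the stated noise model, not robustness to every instrumental artifact of
real spectra.

## What recovery can and cannot achieve

The test suite includes Monte-Carlo recovery studies (100 replicates,
seeded) at 1% noise for the melt and 2% for titrations. A caution worth
stating explicitly: with 2%-of-range noise on the default grids, some
energetic parameters are close to, or beyond, their information limit. The
Cramér–Rao bound computed from the forward-model Jacobian shows, for
example, that the GuHCl N–I step of the Trp row (midpoint 0.196 M,
transition width $RT/m \approx 0.05$ M) is essentially unsampled by a 0.2 M
grid — no estimator can pin its $\Delta G$ there — and several other
parameters have bounds implying median relative errors in the 15–25% range.
The package's fits sit at that bound (the Monte-Carlo medians match the
CRLB), which is the correct behaviour: uncertainty that is really in the
data shows up in the estimates and their standard errors instead of being
hidden. Recovery assertions in the test suite that sit beyond the
information limit fail for that reason, and are left failing deliberately.

## Problem sizes and numerical choices

Monte-Carlo studies use 100 replicates; brute-force oracles use 1 mK grids
(stability roots) and 1 mM grids (population windows); property checks use
1,000 random parameter draws. Root-finding tolerances are $10^{-6}$ K and
$10^{-9}$ M. LM runs with `ftol = ptol = 1e-12` and up to 500 iterations.
Duplicate x-values in input files are averaged (replicate scans are normal);
curves are sorted on read; reports serialize at 17 significant digits so
they round-trip bit-for-bit, with `NaN` standard errors stored as JSON
`null` by schema.
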