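Package: unfoldfit
Title: Equilibrium Unfolding Analysis by Thermal and Chemical Denaturation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of protein equilibrium unfolding curves monitored by
    circular dichroism and fluorescence spectroscopy. Fits two-state thermal
    denaturation models with linear baselines and extracts van't Hoff free
    energy series; constructs Gibbs-Helmholtz protein stability curves with
    their characteristic temperatures (Th, Ts, Tg, Tg') and maximal
    stabilization free energy; estimates the unfolding heat-capacity change
    from accessible-surface-area change; fits two- and three-state linear
    extrapolation method (LEM) models to urea and guanidine hydrochloride
    titrations with species fractions, midpoints and model selection; reduces
    emission scans and far-UV CD spectra to titration features (lambda max,
    peak intensity, intensity ratios, ellipticity at a wavelength); and
    generates synthetic melts, titrations and emission-scan stacks with known
    ground truth for validation. Developed around the equilibrium unfolding
    behaviour of human aldose reductase, which unfolds through a partially
    folded intermediate under chemical denaturation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
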