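#!/usr/bin/env Rscript
# Generate the synthetic study data: one far-UV CD melt, six denaturant
# titrations (urea/GuHCl x Trp/ANS/CD probes) and two emission-scan stacks,
# all from the reference hAR ground-truth parameter sets with 1% noise.
# Everything downstream (02-05) works from these files alone.

library(unfoldfit)

out <- file.path("results", "fixtures")
files <- make_fixture_suite(out, seed = 42)

cat("Wrote", length(files), "files to", out, "\n")
cat("Ground-truth parameter sets:\n")
for (nm in names(unfolding_presets())) {
  p <- unfolding_presets(nm)
  if (!is.null(p$dHg)) {
    cat(sprintf("  %-10s dHg = %.2f kJ/mol, Tg = %.0f K\n", nm, p$dHg, p$Tg))
  } else {
    cat(sprintf("  %-10s dG = %.2f/%.2f kJ/mol, m = %.2f/%.2f kJ/mol/M\n",
                nm, p$dG_NI, p$dG_IU, p$m_NI, p$m_IU))
  }
}
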