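# Shared fixtures built in code: reference parameter sets and tiny builders.

har_thermal <- list(dHg = 779.20, Tg = 329, dCp = 17.57)

# the six self-consistent titration rows (dG_NI, m_NI, dG_IU, m_IU)
har_rows <- c("urea_trp", "urea_ans", "urea_cd",
              "guhcl_trp", "guhcl_ans", "guhcl_cd")

energetics <- function(truth)
  unlist(truth[c("dG_NI", "m_NI", "dG_IU", "m_IU")])

# simple synthetic Gaussian emission scan on a 1 nm grid
gaussian_scan <- function(center, width = 20, amp = 1, conc = 0,
                          grid = seq(300, 400, 1), probe = "Trp",
                          excitation = 295) {
  emission_scan(grid, amp * exp(-(grid - center)^2 / (2 * width^2)),
                excitation_nm = excitation, sample_concentration = conc,
                probe = probe)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
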