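urea_trp <- unfolding_presets("urea_trp")
guhcl_trp <- unfolding_presets("guhcl_trp")

test_that("species fractions normalize and respect the step midpoints", {
  D <- seq(0, 8, 0.05)
  f <- species_fractions(urea_trp$dG_NI, urea_trp$m_NI,
                         urea_trp$dG_IU, urea_trp$m_IU, D = D)
  expect_true(all(abs(f$fN + f$fI + f$fU - 1) < 1e-12))
  expect_true(all(f$fN >= 0 & f$fI >= 0 & f$fU >= 0))
  # fN falls, fU rises, fI is unimodal along the titration
  expect_true(all(diff(f$fN) <= 0))
  expect_true(all(diff(f$fU) >= 0))
  peak <- which.max(f$fI)
  expect_true(all(diff(f$fI[seq_len(peak)]) >= 0))
  expect_true(all(diff(f$fI[peak:length(D)]) <= 0))
  # at the N-I midpoint the first step is balanced: fN == fI
  cm1 <- urea_trp$dG_NI / urea_trp$m_NI
  fmid <- species_fractions(urea_trp$dG_NI, urea_trp$m_NI,
                            urea_trp$dG_IU, urea_trp$m_IU, D = cm1)
  expect_equal(fmid$fN, fmid$fI, tolerance = 1e-12)
  # strongly native at zero denaturant: K1 = exp(-30.88/RT) ~ 3.9e-6
  f0 <- species_fractions(30.88, 13.11, 35.04, 7.99, 298.15, 0)
  expect_gt(f0$fN, 0.9999)
})

test_that("fractions match brute-force Boltzmann weights on random draws", {
  set.seed(4)
  rt <- gas_constant() * 298.15
  for (i in 1:200) {
    dg1 <- runif(1, 1, 60); m1 <- runif(1, 2, 50)
    dg2 <- runif(1, 1, 60); m2 <- runif(1, 2, 50)
    D <- runif(1, 0, 8)
    # oracle: enumerate the two-equilibrium Boltzmann weights directly
    w <- c(1, exp(-(dg1 - m1 * D) / rt),
           exp(-(dg1 - m1 * D) / rt) * exp(-(dg2 - m2 * D) / rt))
    f <- species_fractions(dg1, m1, dg2, m2, 298.15, D)
    expect_equal(unlist(f[c("fN", "fI", "fU")], use.names = FALSE),
                 w / sum(w), tolerance = 1e-12)
  }
})

test_that("the signal model composes baselines with populations", {
  flat <- list(An = 0, bN = 0, Ai = 0.5, bI = 0, Au = 1, bU = 0,
               dG_NI = 30.88, m_NI = 13.11, dG_IU = 35.04, m_IU = 7.99,
               temperature = 298.15)
  f <- species_fractions(30.88, 13.11, 35.04, 7.99, 298.15, 3.3)
  expect_equal(predict_chemical_signal(flat, 3.3),
               0 * f$fN + 0.5 * f$fI + 1 * f$fU)
  # strongly native limit at D = 0 sits on the native baseline
  expect_equal(predict_chemical_signal(flat, 0), 0, tolerance = 1e-5)
  # far past the second midpoint the signal sits on the unfolded baseline
  expect_equal(predict_chemical_signal(flat, 20), 1, tolerance = 1e-6)
})

test_that("population-weighted signal equals the explicit ratio form", {
  set.seed(9)
  rt <- gas_constant() * 298.15
  for (i in 1:100) {
    p <- list(An = rnorm(1), bN = rnorm(1, 0, 0.05), Ai = rnorm(1),
              bI = rnorm(1, 0, 0.05), Au = rnorm(1), bU = rnorm(1, 0, 0.05),
              dG_NI = runif(1, 1, 60), m_NI = runif(1, 2, 50),
              dG_IU = runif(1, 1, 60), m_IU = runif(1, 2, 50),
              temperature = 298.15)
    D <- runif(1, 0, 8)
    K1 <- exp(-(p$dG_NI - p$m_NI * D) / rt)
    K2 <- exp(-(p$dG_IU - p$m_IU * D) / rt)
    ratio_form <- ((p$An + p$bN * D) + (p$Ai + p$bI * D) * K1 +
                     (p$Au + p$bU * D) * K1 * K2) / (1 + K1 + K1 * K2)
    expect_equal(predict_chemical_signal(p, D), ratio_form,
                 tolerance = 1e-12)
  }
})

test_that("a stabilized first step reduces three-state to two-state", {
  # with dG_NI = 500 the intermediate never populates, so unfolding is a
  # single N <-> U step with the combined energetics of the two steps
  three <- list(An = 1, bN = -0.01, Ai = (1 + 0.2) / 2,
                bI = (-0.01 - 0.002) / 2, Au = 0.2, bU = -0.002,
                dG_NI = 500, m_NI = 13.11, dG_IU = 35.04, m_IU = 7.99,
                temperature = 298.15)
  two <- list(An = 1, bN = -0.01, Au = 0.2, bU = -0.002,
              dG = 500 + 35.04, m = 13.11 + 7.99, temperature = 298.15)
  D <- seq(0, 40, 0.25) # spans the combined midpoint near 25 M
  f <- species_fractions(500, 13.11, 35.04, 7.99, 298.15, D)
  expect_lt(max(f$fI), 1e-10)
  expect_equal(predict_chemical_signal(three, D),
               unfoldfit:::predict_chemical_two_state(two, D),
               tolerance = 1e-10)
})

test_that("midpoints are dG/m with a guarded domain", {
  expect_equal(round(midpoint(16.48, 38.99), 2), 0.42)
  expect_equal(round(midpoint(30.88, 13.11), 2), 2.36)
  expect_equal(midpoint(0, 5), 0)
  expect_error(midpoint(10, 0), "positive")
  expect_error(midpoint(10, -3), "positive")
})

test_that("noiseless titrations refit to the generator truth", {
  for (row in c("urea_trp", "guhcl_ans")) {
    truth <- unfolding_presets(row)
    cc <- generate_chemical_curve(truth, noise = 0, seed = 1)
    fit <- fit_chemical_three_state(cc)
    tv <- energetics(truth)
    expect_true(all(rel_err(fit$coef[names(tv)], tv) < 1e-4))
    expect_equal(fit$Cm_NI, truth$dG_NI / truth$m_NI, tolerance = 1e-6)
    expect_equal(fit$Cm_IU, truth$dG_IU / truth$m_IU, tolerance = 1e-6)
  }
  # two-state generator round-trip
  two_truth <- list(An = 1, bN = -0.01, Au = 0.2, bU = -0.002,
                    dG = 20, m = 8, temperature = 298.15,
                    denaturant = "urea")
  cc <- generate_chemical_curve(two_truth, noise = 0, seed = 1)
  fit <- fit_chemical_two_state(cc)
  expect_true(all(rel_err(fit$coef[c("dG", "m")], c(20, 8)) < 1e-6))
  expect_equal(fit$Cm, 2.5, tolerance = 1e-6)
})

test_that("a three-state curve fits worse under the two-state model", {
  cc <- generate_chemical_curve(unfolding_presets("urea_ans"),
                                noise = 0.01, seed = 5)
  f2 <- fit_chemical_two_state(cc)
  f3 <- fit_chemical_three_state(cc)
  expect_gt(f2$rss, f3$rss)
  cmp <- compare_models(f2, f3, length(cc$concentration))
  expect_identical(cmp$selected, "three_state")
})

test_that("model comparison guards its degrees of freedom and inputs", {
  cc <- generate_chemical_curve(noise = 0.01, seed = 2)
  f2 <- fit_chemical_two_state(cc)
  f3 <- fit_chemical_three_state(cc)
  expect_error(compare_models(f2, f3, 999), "same")
  # too few points for the 10-parameter model: degrees-of-freedom guard
  f2_small <- f2; f2_small$n <- 10L
  f3_small <- f3; f3_small$n <- 10L
  expect_error(compare_models(f2_small, f3_small, 10), "more than 10")
  # identical residuals: the parameter penalty must favour two states
  f3_same <- f3
  f3_same$rss <- f2$rss
  cmp <- compare_models(f2, f3_same, length(cc$concentration))
  expect_identical(cmp$selected, "two_state")
})

test_that("intermediate window matches a brute-force population scan", {
  iw <- intermediate_window(list(dG_NI = guhcl_trp$dG_NI,
                                 m_NI = guhcl_trp$m_NI,
                                 dG_IU = guhcl_trp$dG_IU,
                                 m_IU = guhcl_trp$m_IU,
                                 temperature = 298.15))
  # oracle: dense scan of fI at 0.001 M resolution
  D <- seq(0, 6, 0.001)
  fI <- species_fractions(guhcl_trp$dG_NI, guhcl_trp$m_NI,
                          guhcl_trp$dG_IU, guhcl_trp$m_IU, D = D)$fI
  above <- range(D[fI >= 0.5])
  expect_equal(iw$D_low, above[1], tolerance = 1e-3)
  expect_equal(iw$D_high, above[2], tolerance = 1e-3)
  # the window lies between the two midpoints (to root-finder resolution:
  # fI passes through 1/2 essentially at each midpoint here, since the two
  # steps are far apart)
  expect_gte(iw$D_low, guhcl_trp$dG_NI / guhcl_trp$m_NI - 1e-6)
  expect_lte(iw$D_high, guhcl_trp$dG_IU / guhcl_trp$m_IU + 1e-6)

  # threshold 0 spans the whole axis; unreachable threshold reports the peak
  expect_identical(intermediate_window(guhcl_trp, threshold = 0)$D_high, Inf)
  # urea Trp steps overlap more, so fI peaks near 0.97: 0.99 is unreachable
  hi <- intermediate_window(unfolding_presets("urea_trp"), threshold = 0.99)
  expect_true(hi$empty)
  expect_lt(hi$max_fI, 0.99)

  # symmetric energetics centre the window on the shared midpoint
  sym <- list(dG_NI = 20, m_NI = 10, dG_IU = 20, m_IU = 10,
              temperature = 298.15)
  iws <- intermediate_window(sym, threshold = 0.3)
  expect_equal((iws$D_low + iws$D_high) / 2, 2, tolerance = 1e-6)
  expect_equal(iws$argmax, 2, tolerance = 1e-4)
})
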