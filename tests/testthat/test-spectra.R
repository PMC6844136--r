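test_that("blank subtraction floors fluorescence but not CD", {
  s <- gaussian_scan(340)
  zero <- s
  zero$intensity <- rep(0, length(s$intensity))
  expect_equal(blank_subtract(s, s)$intensity, zero$intensity)
  expect_equal(blank_subtract(s, zero)$intensity, s$intensity)
  big <- s
  big$intensity <- s$intensity + 1
  expect_message(res <- blank_subtract(s, big), "floored")
  expect_true(all(res$intensity == 0))
  # CD spectra keep negative values
  cd <- emission_scan(200:260, -(200:260) / 10, probe = "CD")
  cd_blank <- emission_scan(200:260, rep(0, 61), probe = "CD")
  expect_true(all(blank_subtract(cd, cd_blank)$intensity < 0))
  # offset grids are a hard error
  s2 <- gaussian_scan(340, grid = seq(299, 400, 1))
  expect_error(blank_subtract(s, s2), "grids")
})

test_that("lambda_max finds peaks, breaks ties blue, refines sub-grid", {
  expect_equal(lambda_max(gaussian_scan(340)), 340)
  # two equal maxima: the shorter wavelength wins
  twin <- gaussian_scan(335)
  twin$intensity <- twin$intensity +
    gaussian_scan(345)$intensity
  peak_vals <- twin$intensity
  expect_equal(lambda_max(twin, smoothing_window = 1),
               min(twin$wavelength_nm[peak_vals == max(peak_vals)]))
  # off-grid centre recovered by parabolic refinement
  off <- gaussian_scan(337.4)
  expect_equal(lambda_max(off, refine = TRUE), 337.4, tolerance = 0.2 / 337.4)
  expect_error(lambda_max(gaussian_scan(340, amp = 0)), "degenerate")
})

test_that("intensity queries interpolate linearly without extrapolation", {
  s <- emission_scan(seq(300, 400, 2),
                     rep(c(2, 4), length.out = 51),
                     excitation_nm = 295, probe = "Trp")
  expect_equal(intensity_at(s, 300), 2)  # grid hit
  expect_equal(intensity_at(s, 301), 3)  # midpoint of 2 and 4
  expect_error(intensity_at(s, 299), "outside")

  g <- gaussian_scan(340)
  expect_equal(intensity_at(g, 314),
               g$intensity[g$wavelength_nm == 314])
})

test_that("intensity ratios are scale invariant and guard the denominator", {
  s <- gaussian_scan(340)
  r1 <- intensity_ratio(s, 330, 350)
  scaled <- s
  scaled$intensity <- s$intensity * 7.3
  expect_equal(intensity_ratio(scaled, 330, 350), r1)
  # known channel values: 10 and 4 give 2.5
  s2 <- emission_scan(seq(300, 400, 1), rep(1, 101), excitation_nm = 295,
                      probe = "Trp")
  s2$intensity[s2$wavelength_nm == 310] <- 10
  s2$intensity[s2$wavelength_nm == 320] <- 4
  expect_equal(intensity_ratio(s2, 310, 320), 2.5)
  zero <- emission_scan(seq(300, 400, 1), c(rep(1, 50), 0, rep(1, 50)),
                        excitation_nm = 295, probe = "Trp")
  expect_error(intensity_ratio(zero, 310, 350), "zero")
  # excitation-wavelength convention: 295 clamps to the scan start on request
  expect_error(intensity_ratio(s, 295, 350), "outside")
  expect_equal(intensity_ratio(s, 295, 350, clamp_to_start = TRUE),
               intensity_ratio(s, 300, 350))
})

test_that("ellipticity is interpolated sign-preserving in the far UV", {
  cd <- emission_scan(seq(200, 260, 0.5), seq(-30, 30, by = 0.5),
                      probe = "CD")
  expect_equal(ellipticity_at(cd, 222), cd$intensity[cd$wavelength_nm == 222])
  # 221.8 nm on a 0.5 nm grid: hand interpolation between 221.5 and 222
  y1 <- cd$intensity[cd$wavelength_nm == 221.5]
  y2 <- cd$intensity[cd$wavelength_nm == 222.0]
  expect_equal(ellipticity_at(cd, 221.8), y1 + 0.6 * (y2 - y1))
  expect_error(ellipticity_at(cd, 199), "far-UV")
  expect_error(ellipticity_at(gaussian_scan(340), 222), "CD")
})

test_that("titration profiles assemble features in concentration order", {
  st <- generate_emission_stack(noise = 0, seed = 1)
  prof <- build_titration_profile(st, "I_at", wavelength = 480,
                                  denaturant = "urea")
  expect_s3_class(prof, "chemical_curve")
  expect_true(all(diff(prof$concentration) > 0))
  expect_equal(prof$signal[1], intensity_at(st[[1]], 480))

  # constant spectra give a flat profile
  flat_stack <- lapply(seq(0, 8, 0.5), function(d)
    gaussian_scan(520, conc = d, grid = seq(400, 600, 1),
                  probe = "ANS", excitation = 370))
  fl <- build_titration_profile(flat_stack, "lambda_max",
                                denaturant = "urea")
  expect_true(all(fl$signal == 520))

  # per-scan failures are annotated with the concentration
  expect_error(build_titration_profile(st, "I_at", wavelength = 9999,
                                       denaturant = "urea"),
               "at 0 M")
  expect_error(build_titration_profile(st[1:5], "I_max"), "at least 10")
})
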