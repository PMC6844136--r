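test_that("curve CSV round-trips bit-for-bit, with and without header", {
  tc <- generate_thermal_curve(noise = 0.01, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(tc, path)
  back <- read_curve_csv(path, "thermal", unit = "kelvin")
  expect_identical(back$temperature, tc$temperature)
  expect_identical(back$signal, tc$signal)

  cc <- generate_chemical_curve(noise = 0.02, seed = 7)
  write_curve_csv(cc, path)
  back <- read_curve_csv(path, "chemical", denaturant = "urea")
  expect_identical(back$concentration, cc$concentration)
  expect_identical(back$signal, cc$signal)

  # headerless, tab-delimited
  writeLines(paste(seq(293, 300), 1:8, sep = "\t"), path)
  tc2 <- read_curve_csv(path, "thermal", unit = "kelvin")
  expect_length(tc2$temperature, 8)
})

test_that("rows are sorted and duplicate x values averaged", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("T,Y", "305,5", "293,1", "300,1", "300,3",
               "297,2", "310,6", "315,7", "320,8", "325,9"), path)
  expect_warning(tc <- read_curve_csv(path, "thermal", unit = "kelvin"),
                 "duplicate")
  expect_identical(tc$temperature[tc$temperature == 300], 300)
  expect_identical(tc$signal[tc$temperature == 300], 2) # mean of 1 and 3
  expect_true(all(diff(tc$temperature) > 0))

  # shuffled input gives the same curve as sorted input
  writeLines(c("T,Y", paste(c(300, 293, 297, 305, 310, 315, 320, 325),
                            c(3, 1, 2, 5, 6, 7, 8, 9), sep = ",")), path)
  shuffled <- read_curve_csv(path, "thermal", unit = "kelvin")
  expect_identical(shuffled$temperature, c(293, 297, 300, 305, 310, 315,
                                           320, 325) + 0)
  expect_identical(shuffled$signal, as.numeric(c(1, 2, 3, 5, 6, 7, 8, 9)))
})

test_that("parse errors name the offending row; short files are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("T,Y", "293,1", "295,oops", "297,2", "299,3", "301,4",
               "303,5", "305,6", "307,7"), path)
  expect_error(read_curve_csv(path, "thermal"), "row 2")
  writeLines(c("T,Y", "293,1", "295,2"), path)
  expect_error(read_curve_csv(path, "thermal"), "at least 8")
})

test_that("Celsius and kelvin temperature units are resolved", {
  celsius <- thermal_curve(seq(20, 70, 5), 1:11)           # auto: min <= 100
  kelvin <- thermal_curve(seq(293.15, 343.15, 5), 1:11)    # auto: min > 100
  expect_equal(celsius$temperature, kelvin$temperature)
  forced <- thermal_curve(seq(20, 70, 5), 1:11, unit = "celsius")
  expect_equal(forced$temperature, celsius$temperature)
})

test_that("scan stacks read back with concentrations parsed from headers", {
  st <- generate_emission_stack(noise = 0, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  unfoldfit:::write_stack_csv(st, path)
  back <- read_scan_stack(path, probe = "ANS")
  expect_length(back, length(st))
  expect_equal(vapply(back, function(s) s$sample_concentration, 0),
               vapply(st, function(s) s$sample_concentration, 0))
  expect_equal(back[[3]]$intensity, st[[3]]$intensity)

  # "3.5M" and "3.5" both parse to 3.5
  expect_equal(unfoldfit:::parse_conc_header(c("3.5M", "3.5", "0 M")),
               c(3.5, 3.5, 0))

  # unparseable header is reported by name
  writeLines(c("wl,first,2.0", "400,1,2", "401,1,2"), path)
  expect_error(read_scan_stack(path, probe = "CD"), "first")
})

test_that("fit reports round-trip losslessly, NaN as null", {
  tc <- generate_thermal_curve(noise = 0.01, seed = 3)
  fit <- fit_thermal_two_state(tc)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, path)
  back <- read_fit_report(path)
  expect_identical(back$coef, fit$coef)
  expect_identical(back$se, fit$se)
  expect_identical(back$rss, fit$rss)
  expect_s3_class(back, "two_state_thermal_fit")

  # a three-state report carries both midpoints
  cc <- generate_chemical_curve(noise = 0, seed = 1)
  f3 <- fit_chemical_three_state(cc)
  write_fit_report(f3, path)
  back3 <- read_fit_report(path)
  expect_identical(back3$Cm_NI, f3$Cm_NI)
  expect_identical(back3$Cm_IU, f3$Cm_IU)

  # NaN standard error -> JSON null -> NaN
  fit$se[2] <- NaN
  write_fit_report(fit, path)
  expect_true(grepl("null", paste(readLines(path), collapse = "")))
  expect_identical(read_fit_report(path)$se, fit$se)
})

test_that("the gas constant has a single numeric source", {
  expect_identical(gas_constant(), 8.3145e-3)
  rdir <- testthat::test_path("..", "..", "R")
  if (dir.exists(rdir)) {
    hits <- vapply(list.files(rdir, pattern = "\\.R$", full.names = TRUE),
                   function(f) {
                     code <- grep("^\\s*#", readLines(f), value = TRUE,
                                  invert = TRUE)
                     sum(grepl("8\\.3145", code))
                   }, 0L)
    expect_identical(sum(hits), 1L)
  }
})
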