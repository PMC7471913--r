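test_that("titration_series enforces its invariants and sorts by concentration", {
  s <- titration_series(298.15, c(32e-6, 8e-6, 16e-6), c(770, 930, 870),
                        f0 = 1000)
  expect_equal(s$quencher_conc, c(8e-6, 16e-6, 32e-6))
  expect_equal(s$intensity, c(930, 870, 770))

  expect_error(titration_series(-1, 1e-6, 900, 1000), "temperature")
  expect_error(titration_series(298, c(1e-6, 2e-6), 900, 1000), "length")
  expect_error(titration_series(298, c(1e-6, 1e-6), c(900, 900), 1000),
               "strictly increasing")
  expect_error(titration_series(298, 1e-6, -5, 1000), "positive")
  expect_error(titration_series(298, 1e-6, 900, 0), "f0")
})

test_that("titration_set requires distinct temperatures", {
  a <- titration_series(298.15, design_grid, 1000 / (1 + 4000 * design_grid),
                        f0 = 1000)
  b <- titration_series(310.15, design_grid, 1000 / (1 + 2000 * design_grid),
                        f0 = 1000)
  expect_length(titration_set(list(b, a))$series, 2)
  # sorted by temperature regardless of input order
  expect_equal(titration_set(list(b, a))$series[[1]]$temperature, 298.15)
  expect_error(titration_set(list(a, a)), "distinct")
  expect_error(titration_set(list()), "non-empty")
})

test_that("read_titration_csv parses, converts units, and consumes the zero row as f0", {
  path <- write_fixture_csv(data.frame(
    temperature_K = 298.15,
    quencher_conc = c(0, 8, 16, 32, 64, 128),
    intensity = c(1000, 930, 870, 770, 630, 470)))
  ts <- read_titration_csv(path, conc_unit = "uM")
  expect_length(ts$series, 1)
  s <- ts$series[[1]]
  expect_equal(s$f0, 1000)
  expect_length(s$quencher_conc, 5)
  # exact power-of-ten unit conversion
  expect_identical(s$quencher_conc[1], 8 * 1e-6)
  expect_identical(read_titration_csv(path, "nM")$series[[1]]$quencher_conc[1],
                   8 * 1e-9)
})

test_that("read_titration_csv error paths name the problem", {
  no_int <- write_fixture_csv(data.frame(temperature_K = 298, quencher_conc = 1))
  expect_error(read_titration_csv(no_int, "uM"), "missing column: intensity",
               class = "quenchfit_format_error")

  no_f0 <- write_fixture_csv(data.frame(
    temperature_K = 298, quencher_conc = c(8, 16, 32),
    intensity = c(900, 800, 700)))
  expect_error(read_titration_csv(no_f0, "uM"), "no f0",
               class = "quenchfit_validation_error")

  bad_int <- write_fixture_csv(data.frame(
    temperature_K = 298, quencher_conc = c(0, 8, 16),
    intensity = c(1000, -5, 700)))
  expect_error(read_titration_csv(bad_int, "uM"), "row 2",
               class = "quenchfit_validation_error")
})

test_that("explicit f0 column overrides the zero row but must agree with it", {
  agree <- write_fixture_csv(data.frame(
    temperature_K = 298, quencher_conc = c(0, 8, 16, 32),
    intensity = c(1000, 900, 800, 700), f0 = 1000))
  expect_equal(read_titration_csv(agree, "uM")$series[[1]]$f0, 1000)

  clash <- write_fixture_csv(data.frame(
    temperature_K = 298, quencher_conc = c(0, 8, 16, 32),
    intensity = c(1000, 900, 800, 700), f0 = 1050))
  expect_error(read_titration_csv(clash, "uM"), "disagrees",
               class = "quenchfit_validation_error")
})

test_that("CSV write/read round trip is lossless to 12 significant digits", {
  ts <- generate_titration_set(vant_hoff_spec(-16100, 13.3), hill_n = 0.89,
                               noise_rel = 0.02, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_titration_csv(ts, path, conc_unit = "M")
  back <- read_titration_csv(path, conc_unit = "M")
  for (i in seq_along(ts$series)) {
    expect_equal(back$series[[i]]$quencher_conc,
                 ts$series[[i]]$quencher_conc, tolerance = 1e-12)
    expect_equal(back$series[[i]]$intensity,
                 ts$series[[i]]$intensity, tolerance = 1e-12)
    expect_equal(back$series[[i]]$f0, ts$series[[i]]$f0, tolerance = 1e-12)
  }
})

test_that("validate_set warns (not errors) on unusable points and thin designs", {
  clean <- generate_titration_set(vant_hoff_spec(-16100, 13.3))
  expect_identical(validate_set(clean), character(0))

  risen <- titration_set(list(titration_series(
    298.15, design_grid[1:4], c(1001, 900, 800, 700), f0 = 1000)))
  w <- validate_set(risen)
  expect_true(any(grepl("8e-06", w) & grepl(">= F0", w)))
  expect_true(any(grepl("van't Hoff analysis unavailable", w)))

  thin <- titration_set(list(titration_series(
    298.15, design_grid[1:2], c(900, 800), f0 = 1000)))
  expect_true(any(grepl("fewer than 3", validate_set(thin))))
})
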