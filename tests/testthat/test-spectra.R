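test_that("emission_spectrum enforces its grid invariants", {
  expect_s3_class(emission_spectrum(310:500, rep(1, 191), 295),
                  "emission_spectrum")
  expect_error(emission_spectrum(c(310, 311, 311), c(1, 1, 1)),
               class = "invalid_grid")
  expect_error(emission_spectrum(c(310, 311, 313), c(1, 1, 1)),
               class = "invalid_grid")
  expect_error(emission_spectrum(310:312, c(1, 1)), class = "grid_mismatch")
  expect_error(emission_spectrum(310:312, c(1, NA, 1)), class = "invalid_data")
  expect_error(emission_spectrum(numeric(0), numeric(0)), class = "empty_input")
})

test_that("average_scans is the pointwise mean and accumulates scan counts", {
  wl <- 310:311
  s1 <- emission_spectrum(wl, c(2, 4), 295)
  s2 <- emission_spectrum(wl, c(4, 8), 295)
  s3 <- emission_spectrum(wl, c(3, 6), 295)

  expect_equal(average_scans(list(s1))$intensities, c(2, 4))
  expect_equal(average_scans(list(s1, s2))$intensities, c(3, 6))
  avg <- average_scans(list(flat_spectrum(1, wl), flat_spectrum(2, wl),
                            flat_spectrum(3, wl)))
  expect_equal(avg$intensities, rep(2, 2))
  expect_identical(avg$n_scans_averaged, 3L)
  expect_equal(average_scans(list(s1, s2, s3))$intensities, c(3, 6))

  expect_error(average_scans(list()), class = "empty_input")
  expect_error(average_scans(list(s1, flat_spectrum(1, 311:312))),
               class = "grid_mismatch")
  expect_error(average_scans(list(s1, emission_spectrum(wl, c(1, 1), 360))),
               class = "grid_mismatch")
})

test_that("subtract_background is pointwise and flags negatives instead of clipping", {
  wl <- 310:311
  sample <- emission_spectrum(wl, c(5, 5), 295)
  self <- subtract_background(sample, sample)
  expect_equal(self$intensities, c(0, 0))
  expect_false(any(self$intensities < 0))

  diff <- subtract_background(sample, emission_spectrum(wl, c(1, 2), 295))
  expect_equal(diff$intensities, c(4, 3))
  expect_false(diff$negative)

  over <- subtract_background(sample, emission_spectrum(wl, c(1, 6), 295))
  expect_equal(over$intensities, c(4, -1))  # negatives kept, not clipped
  expect_true(over$negative)

  expect_error(subtract_background(sample, flat_spectrum(1, 311:312)),
               class = "grid_mismatch")
})

test_that("moving-average smoothing matches a direct convolution oracle", {
  # identity and constant cases
  sp <- gaussian_spectrum()
  expect_equal(smooth_moving_average(sp, 1)$intensities, sp$intensities)
  flat <- flat_spectrum(7, 310:330)
  expect_equal(smooth_moving_average(flat, 5)$intensities, rep(7, 21))

  # unit impulse: direct convolution oracle computed here, independently
  n <- 21L
  y <- rep(0, n); y[11L] <- 1
  imp <- emission_spectrum(310:330, y, 295)
  sm <- smooth_moving_average(imp, 5)
  oracle <- vapply(seq_len(n), function(i) {
    r <- min(2L, i - 1L, n - i)
    mean(y[(i - r):(i + r)])
  }, numeric(1))
  expect_equal(sm$intensities, oracle)
  expect_equal(sm$intensities[9:13], rep(1 / 5, 5))
  expect_equal(sum(sm$intensities[9:13]), 1)

  # symmetric shrinking at the edges: first point untouched, second is a
  # 3-point mean
  ramp <- emission_spectrum(310:319, 1:10, 295)
  smr <- smooth_moving_average(ramp, 5)
  expect_equal(smr$intensities[1], 1)
  expect_equal(smr$intensities[2], mean(1:3))
  expect_equal(smr$intensities[3], mean(1:5))

  expect_error(smooth_moving_average(sp, 4), class = "invalid_parameter")
  expect_error(smooth_moving_average(sp, 0), class = "invalid_parameter")
  expect_error(smooth_moving_average(flat, 23), class = "invalid_parameter")
})

test_that("smoothing and averaging commute with scalar rescaling", {
  sp <- gaussian_spectrum(amp = 3)
  for (k in c(0.5, 2, 17)) {
    scaled <- emission_spectrum(sp$wavelengths, k * sp$intensities, 295)
    expect_equal(smooth_moving_average(scaled, 5)$intensities,
                 k * smooth_moving_average(sp, 5)$intensities)
    expect_equal(average_scans(list(scaled, scaled))$intensities,
                 k * average_scans(list(sp, sp))$intensities)
  }
})

test_that("peak_emission finds the band centre with a low-wavelength tie-break", {
  pk <- peak_emission(gaussian_spectrum(center = 328))
  expect_equal(pk$lambda_max, 328)

  # monotone decreasing: argmax forced to the first grid point
  dec <- emission_spectrum(310:320, 11:1, 295)
  expect_equal(peak_emission(dec)$lambda_max, 310)

  # two equal maxima at 330 and 340 -> 330
  wl <- 310:350
  y <- rep(0, length(wl)); y[wl == 330] <- 5; y[wl == 340] <- 5
  expect_equal(peak_emission(emission_spectrum(wl, y, 295))$lambda_max, 330)

  # search range restriction
  expect_equal(peak_emission(emission_spectrum(wl, y, 295),
                             search_range = c(335, 350))$lambda_max, 340)
  expect_error(peak_emission(emission_spectrum(wl, y, 295),
                             search_range = c(600, 700)),
               class = "invalid_parameter")

  expect_warning(pkf <- peak_emission(flat_spectrum(1)),
                 class = "degenerate_peak")
  expect_equal(pkf$lambda_max, 310)
})

test_that("noiseless synthetic band peaks at the configured centre", {
  for (centre in c(320, 328, 340)) {
    ts <- simulate_titration(band_center_nm = centre, noise_sd = 0,
                             Q_uM = c(0, 10))
    pk <- peak_emission(ts$spectra[[1]])
    expect_lte(abs(pk$lambda_max - centre), 1)  # within one grid step
  }
})

test_that("spectra CSV round-trips through the documented dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  sps <- list(a = gaussian_spectrum(amp = 10), b = gaussian_spectrum(amp = 20))
  write_spectra_csv(sps, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "wavelength_nm,a,b")
  back <- read_spectra_csv(path, excitation_nm = 295)
  expect_equal(back$a$intensities, sps$a$intensities)
  expect_equal(back$b$wavelengths, sps$b$wavelengths)
  expect_error(read_spectra_csv("no/such/file.csv"), class = "io_error")
})
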