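test_that("titration_series enforces its invariants", {
  expect_error(titration_series(c(0, 10, 5), rep(1, 3)), class = "invalid_data")
  expect_error(titration_series(c(5, 10, 20), rep(1, 3)), class = "missing_F0")
  expect_error(titration_series(c(0, 0, 10), rep(1, 3)), class = "invalid_data")
  expect_error(titration_series(c(0, 10), c(1, 0)), class = "invalid_data")
  expect_error(titration_series(c(0, 10), c(1, 1), tau0_ns = 0),
               class = "invalid_parameter")
  ts <- titration_series(c(0, 5, 10), c(10, 9, 8), tau0_ns = 2.5)
  expect_equal(ts$Q_M, c(0, 5e-6, 1e-5))
  expect_equal(ts$tau0_s, 2.5e-9)
})

test_that("relative intensity is F/F0 with a warning on non-monotone series", {
  flatish <- titration_series(c(0, 5, 10, 15), c(10, 10, 10, 10))
  expect_equal(relative_intensity(flatish)$F_over_F0, rep(1, 4))

  halved <- titration_series(c(0, 5), c(10, 5))
  expect_equal(relative_intensity(halved)$F_over_F0, c(1, 0.5))

  # forward model: f_a = 1, K_SV = 2e4 1/M at Q = 50 uM -> 1/(1+1) = 0.5
  ts <- simulate_titration(f_a = 1, K_SV = 2e4, Q_uM = c(0, 50), noise_sd = 0)
  expect_equal(relative_intensity(ts)$F_over_F0[2], 0.5, tolerance = 1e-12)

  wob <- titration_series(c(0, 5, 10), c(10, 8, 9))
  expect_warning(relative_intensity(wob), class = "non_monotone")
})

test_that("the linearised Stern-Volmer fit recovers noiseless parameters exactly", {
  for (pars in list(c(f_a = 1.0, K = 2.5e4), c(f_a = 0.5, K = 1e4))) {
    ts <- make_titration(f_a = pars[["f_a"]], K_SV = pars[["K"]])
    fit <- stern_volmer_fit(ts)
    expect_equal(fit$f_a, pars[["f_a"]], tolerance = 1e-6)
    expect_equal(fit$K_SV, pars[["K"]], tolerance = 1e-6)
    expect_equal(fit$K_q, fit$K_SV / 2.5e-9, tolerance = 1e-12)  # identity
    expect_equal(fit$R, 1, tolerance = 1e-9)
    expect_equal(fit$n_points_used, 10L)
    expect_equal(fit$n_excluded, 0L)
  }
})

test_that("unquenched or short series are rejected with informative errors", {
  flat <- titration_series(seq(0, 50, 5), rep(100, 11))
  expect_error(stern_volmer_fit(flat), class = "insufficient_data")
  short <- titration_series(c(0, 5, 10), c(10, 9, 8))
  expect_error(stern_volmer_fit(short), class = "insufficient_data")
  expect_error(scatchard_fit(flat), class = "insufficient_data")
})

test_that("non-physical transformed regressions carry the raw fit in the error", {
  # increasing F with Q produces a negative-slope transformed regression
  ts <- titration_series(seq(0, 20, 5), c(100, 99, 97, 94, 90))
  ts$intensity <- c(100, 99.9, 99.95, 99.99, 99.999)  # nearly flat, noisy order
  ts2 <- titration_series(seq(0, 20, 5), ts$intensity)
  err <- tryCatch(stern_volmer_fit(ts2), error = function(e) e)
  if (inherits(err, "non_physical_fit"))
    expect_true(is.list(err$regression))
  else succeed("series fit despite near-flat quenching")
})

test_that("K_q arithmetic matches the reference worked values", {
  # HTF-MFC row: K_SV = 1.70e4 1/M, tau0 = 2.5 ns -> 6.80e12 1/(M s)
  expect_equal(bimolecular_quenching_constant(1.70e4, 2.5), 6.80e12)
  # HTF-MFB row: K_SV = 2.58e4 -> 1.032e13 = 10.3e12 to 3 s.f.
  expect_equal(bimolecular_quenching_constant(2.58e4, 2.5), 1.032e13)
  expect_equal(signif(bimolecular_quenching_constant(2.58e4, 2.5), 3), 10.3e12)
  expect_equal(bimolecular_quenching_constant(0, 2.5), 0)
  expect_error(bimolecular_quenching_constant(1e4, 0), class = "invalid_parameter")
})

test_that("mechanism classification uses a strict threshold", {
  expect_identical(as.character(classify_mechanism(6.8e12)), "static")
  expect_identical(as.character(classify_mechanism(1e9)), "dynamic")
  expect_identical(as.character(classify_mechanism(2e10)), "dynamic")  # boundary
  expect_equal(attr(classify_mechanism(4e10), "margin"), 2)
  expect_error(classify_mechanism(-1), class = "invalid_parameter")
})

test_that("Scatchard fit matches the closed form for 1:1 static quenching", {
  # f_a = 1: F = F0/(1 + K Q) so F0/F - 1 = K Q -> slope 1, intercept log10 K
  ts <- make_titration(f_a = 1, K_SV = 1e4)
  fit <- scatchard_fit(ts)
  expect_equal(fit$n, 1, tolerance = 1e-9)
  expect_equal(fit$K_a, 1e4, tolerance = 1e-5)
  expect_equal(fit$R, 1, tolerance = 1e-9)

  # doubling the concentration grid leaves the fitted model unchanged
  ts2 <- make_titration(f_a = 1, K_SV = 1e4, Q_uM = seq(0, 100, 10))
  fit2 <- scatchard_fit(ts2)
  expect_equal(fit2$n, fit$n, tolerance = 1e-9)
  expect_equal(fit2$K_a, fit$K_a, tolerance = 1e-5)
})

test_that("linearised and nonlinear Stern-Volmer routes agree at zero noise", {
  for (pars in list(c(f_a = 1, K = 2.5e4), c(f_a = 0.7, K = 5e4))) {
    ts <- make_titration(f_a = pars[["f_a"]], K_SV = pars[["K"]])
    lin <- stern_volmer_fit(ts)
    nl <- stern_volmer_fit_nls(ts)
    expect_equal(lin$K_SV, nl$K_SV, tolerance = 1e-6)
    expect_equal(lin$f_a, nl$f_a, tolerance = 1e-6)
  }
})

test_that("F/F0 from the forward model is strictly decreasing for f_a > 0", {
  Q <- seq(0, 50, 5) * 1e-6
  for (fa in c(0.2, 0.6, 1)) {
    F <- forward_F(Q, 1000, fa, 2.5e4)
    expect_true(all(diff(F / F[1]) < 0))
  }
  # f_a = 0: no accessible fluorophore, spectra identical to F0
  ts0 <- simulate_titration(f_a = 0, Q_uM = c(0, 25, 50), noise_sd = 0)
  expect_equal(relative_intensity(ts0)$F_over_F0, rep(1, 3))
})

test_that("smoothing a noiseless titration leaves F/F0 and fits exactly unchanged", {
  ts <- simulate_titration(f_a = 0.8, K_SV = 3e4, noise_sd = 0)
  sm <- smooth_titration(ts, 5)
  expect_equal(relative_intensity(sm)$F_over_F0,
               relative_intensity(ts)$F_over_F0, tolerance = 1e-12)
  expect_equal(stern_volmer_fit(sm)$K_SV, 3e4, tolerance = 1e-6)
  expect_identical(sm$preprocessing, "moving_average_5")
  expect_error(smooth_titration(make_titration()), class = "invalid_parameter")
})

test_that("weighted and unweighted fits coincide at zero noise and both stay unbiased", {
  ts <- make_titration(f_a = 0.7, K_SV = 2e4)
  fw <- stern_volmer_fit(ts, weights = "model")
  fu <- stern_volmer_fit(ts, weights = "none")
  expect_equal(fw$K_SV, fu$K_SV, tolerance = 1e-9)
  expect_equal(fw$f_a, fu$f_a, tolerance = 1e-9)
  sw <- scatchard_fit(make_titration(), weights = "model")
  su <- scatchard_fit(make_titration(), weights = "none")
  expect_equal(sw$K_a, su$K_a, tolerance = 1e-6)
  expect_equal(sw$n, su$n, tolerance = 1e-9)
  # under noise both recover the truth, the weighted fit more tightly
  set.seed(99)
  errs <- replicate(40, {
    tn <- simulate_titration(f_a = 1, K_SV = 2.5e4, noise_sd = 0.01,
                             spectra = FALSE)
    c(w = abs(stern_volmer_fit(tn, "model")$K_SV - 2.5e4),
      u = abs(suppressWarnings(stern_volmer_fit(tn, "none"))$K_SV - 2.5e4))
  })
  expect_lt(median(errs["w", ]), median(errs["u", ]))
})

test_that("emission shift detection reads spectra and tolerates small drift", {
  still <- simulate_titration(noise_sd = 0, peak_drift_nm = 0)
  s <- detect_emission_shift(still)
  expect_true(s$applicable)
  expect_equal(s$max_shift_nm, 0)
  expect_false(s$shifted)

  drifted <- simulate_titration(noise_sd = 0, peak_drift_nm = 5)
  sd_ <- detect_emission_shift(drifted)
  expect_equal(sd_$max_shift_nm, 5, tolerance = 0.5)
  expect_true(sd_$shifted)

  small <- simulate_titration(noise_sd = 0, peak_drift_nm = 1)
  expect_false(detect_emission_shift(small)$shifted)

  plain <- make_titration()
  na <- detect_emission_shift(plain)
  expect_false(na$applicable)
  expect_true(is.na(na$max_shift_nm))
})

test_that("absorption ratio check warns only below the guard", {
  r <- absorption_ratio_check(8.4e4, 7e3)
  expect_equal(r$ratio, 12)
  expect_false(r$warning)
  expect_true(absorption_ratio_check(1, 1)$warning)
  expect_false(absorption_ratio_check(1, 1e-9)$warning)
  expect_error(absorption_ratio_check(0, 1), class = "invalid_parameter")
})

test_that("dilution and inner-filter corrections rescale intensities as documented", {
  ts <- titration_series(c(0, 5, 10, 15), c(100, 80, 60, 50),
                         V0_L = 2.1e-3,
                         added_volumes_L = c(0, 2.1e-5, 4.2e-5, 6.3e-5))
  corr <- correct_dilution(ts)
  expect_equal(corr$intensity,
               c(100, 80, 60, 50) * (2.1e-3 + c(0, 2.1e-5, 4.2e-5, 6.3e-5)) / 2.1e-3)
  ifc <- correct_inner_filter(ts, A_ex = 0.2, A_em = 0.1)
  expect_equal(ifc$intensity, c(100, 80, 60, 50) * 10^(0.15))
  expect_error(correct_dilution(make_titration()), class = "invalid_parameter")
})

test_that("titration CSV dialects round-trip (intensities and spectra)", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  ts <- make_titration()
  write_titration_csv(ts, p1)
  expect_identical(readLines(p1, n = 1), "Q_uM,intensity")
  back <- read_titration_csv(p1)
  expect_equal(back$intensity, ts$intensity)

  p2 <- withr::local_tempfile(fileext = ".csv")
  tss <- simulate_titration(noise_sd = 0, Q_uM = seq(0, 50, 10))
  write_titration_csv(tss, p2)
  back2 <- read_titration_csv(p2)
  expect_equal(back2$Q_uM, seq(0, 50, 10))
  fit <- stern_volmer_fit(back2)
  expect_equal(fit$K_SV, 2.5e4, tolerance = 1e-6)
})
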