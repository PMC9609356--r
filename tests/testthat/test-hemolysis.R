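test_that("percent hemolysis is the clamped supernatant ratio", {
  expect_equal(as.numeric(percent_hemolysis(0.9, 0.9)), 100)
  expect_equal(as.numeric(percent_hemolysis(0, 0.9)), 0)
  expect_equal(as.numeric(percent_hemolysis(0.27, 0.90)), 30)
  over <- percent_hemolysis(1.0, 0.9)
  expect_equal(as.numeric(over), 100)
  expect_true(attr(over, "out_of_range"))
  expect_error(percent_hemolysis(0.5, 0), class = "reference_error")
  expect_error(percent_hemolysis(-0.1, 1), class = "invalid_data")
})

test_that("percent hemolysis is scale-invariant in both absorbances jointly", {
  set.seed(9)
  for (i in 1:20) {
    a <- runif(1, 0, 1); tot <- runif(1, 0.5, 2); k <- runif(1, 0.1, 10)
    expect_equal(as.numeric(percent_hemolysis(k * a, k * tot)),
                 as.numeric(percent_hemolysis(a, tot)))
  }
})

test_that("fragility_curve validates its domain and clamps assay noise", {
  d <- data.frame(nacl_percent = c(0.5, 0.9), replicate = 1,
                  hemolysis_percent = c(101, -1))
  cv <- fragility_curve(d)
  expect_true(cv$clamped)
  expect_equal(range(cv$data$hemolysis_percent), c(0, 100))
  expect_error(fragility_curve(
    data.frame(nacl_percent = 2.5, replicate = 1, hemolysis_percent = 50)),
    class = "invalid_data")
  expect_error(fragility_curve(
    data.frame(nacl_percent = 0.7, replicate = 1, hemolysis_percent = 110)),
    class = "invalid_data")
})

test_that("C50 is recovered from a noiseless logistic and shifts with translation", {
  cv <- simulate_fragility(c50 = 0.65, steepness = 0.03, noise_sd = 0)
  fit <- fit_c50(cv)
  expect_equal(unname(coef(fit)["c50"]), 0.65, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["s"]), 0.03, tolerance = 1e-4)

  # translation equivariance: curve shifted left by 0.05% NaCl
  cv_l <- simulate_fragility(c50 = 0.60, steepness = 0.03, noise_sd = 0)
  expect_equal(unname(coef(fit_c50(cv_l))["c50"]),
               unname(coef(fit)["c50"]) - 0.05, tolerance = 1e-6)

  # predictions at the midpoint and the plateaus
  expect_equal(predict(fit, 0.65), 50, tolerance = 1e-4)
  expect_lt(predict(fit, 0.9), 1)
  expect_gt(predict(fit, 0.45), 99)
})

test_that("non-identifiable fragility curves are rejected", {
  all_high <- fragility_curve(
    data.frame(nacl_percent = rep(seq(0.5, 0.8, 0.1), 2),
               replicate = rep(1:2, each = 4),
               hemolysis_percent = 100))
  expect_error(fit_c50(all_high), class = "non_identifiable")
  few <- fragility_curve(
    data.frame(nacl_percent = c(0.5, 0.9), replicate = 1,
               hemolysis_percent = c(99, 1)))
  expect_error(fit_c50(few), class = "insufficient_data")
})

test_that("resistance comparison classifies shifts and is antisymmetric", {
  ctrl <- simulate_fragility(c50 = 0.65, noise_sd = 1.0, seed = 101,
                             treatment = "control")
  same <- simulate_fragility(c50 = 0.65, noise_sd = 1.0, seed = 202,
                             treatment = "same")
  left <- simulate_fragility(c50 = 0.58, noise_sd = 1.0, seed = 303,
                             treatment = "left")   # ~>5 pooled SDs at mid-curve
  right <- simulate_fragility(c50 = 0.72, noise_sd = 1.0, seed = 404,
                              treatment = "right")

  expect_identical(compare_resistance(ctrl, ctrl)$classification, "unchanged")
  expect_identical(compare_resistance(same, ctrl)$classification, "unchanged")
  expect_identical(compare_resistance(left, ctrl)$classification, "increased")
  expect_identical(compare_resistance(right, ctrl)$classification, "decreased")

  # antisymmetry under exchanging treated and control
  expect_identical(compare_resistance(ctrl, left)$classification, "decreased")
  expect_identical(compare_resistance(ctrl, right)$classification, "increased")

  other_grid <- simulate_fragility(nacl_grid = seq(1.0, 1.4, 0.05),
                                   c50 = 1.2, noise_sd = 0)
  expect_error(compare_resistance(other_grid, ctrl),
               class = "comparison_error")
})

test_that("fragility CSV dialect round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  ctrl <- simulate_fragility(seed = 1, treatment = "control")
  trt <- simulate_fragility(c50 = 0.6, seed = 2, treatment = "MFA",
                            concentration_uM = 50)
  write_fragility_csv(ctrl, path)
  write_fragility_csv(trt, path, append = TRUE)
  back <- read_fragility_csv(path)
  expect_setequal(names(back), c("control", "MFA"))
  expect_equal(back$MFA$data$hemolysis_percent, trt$data$hemolysis_percent)
  expect_equal(back$MFA$concentration_uM, 50)
})
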