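test_that("linear fit recovers exact lines and validates input", {
  f <- fit_linear(c(1, 2, 3), c(3, 5, 7))
  expect_equal(unname(f$coefficients["slope"]), 2)
  expect_equal(unname(f$coefficients["intercept"]), 1)
  expect_equal(f$r_squared, 1)
  expect_error(fit_linear(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_linear(c(2, 2, 2), c(1, 2, 3)),
               class = "fus_degenerate_x")
})

test_that("linear fit recovers the published thickness trend from its own line", {
  x <- seq(2, 22, by = 4)
  y <- -14.2 * x + 353.6
  f <- fit_linear(x, y)
  expect_equal(unname(f$coefficients), c(-14.2, 353.6), tolerance = 1e-10)
  # 20 log10(353.6/339.4) = 0.3560, the printed 0.357 at display precision
  expect_equal(unit_attenuation(f, 1), 0.357, tolerance = 0.005)
})

test_that("noisy linear fit recovers the slope within two standard errors", {
  set.seed(42)
  x <- seq(2, 22, by = 2)
  y <- -14.2 * x + 353.6 + rnorm(length(x), sd = 6)
  f <- fit_linear(x, y)
  se <- summary(f$lm)$coefficients["x", "Std. Error"]
  expect_lt(abs(unname(f$coefficients["slope"]) + 14.2), 2 * se)
})

test_that("power fit recovers the published absorption trend within 1 %", {
  x <- seq(200, 5000, by = 480)
  y <- 2993 * x^-0.218 - 418.2
  f <- fit_power(x, y)
  expect_equal(unname(f$coefficients["a"]), 2993, tolerance = 0.01)
  expect_equal(unname(f$coefficients["b"]), -0.218, tolerance = 0.01)
  expect_equal(unname(f$coefficients["c"]), -418.2, tolerance = 0.01)
  expect_gt(f$r_squared, 0.999)
})

test_that("power fit on linear data reduces to the linear fit", {
  x <- 1:8
  y <- 3 * x + 2
  fp <- fit_power(x, y)
  fl <- fit_linear(x, y)
  expect_equal(predict(fp, x), predict(fl, x), tolerance = 1e-4)
})

test_that("noisy power-law fit keeps a high R^2", {
  set.seed(7)
  x <- seq(200, 5000, by = 480)
  y <- 2993 * x^-0.218 - 418.2 + rnorm(length(x), sd = 5)
  f <- fit_power(x, y)
  expect_gt(f$r_squared, 0.95)
})

test_that("unit attenuation uses the intercept-referenced dB convention", {
  f1 <- fit_linear(1:5, -14.2 * (1:5) + 353.6)
  expect_equal(unit_attenuation(f1), 0.35603, tolerance = 1e-4)
  expect_error(unit_attenuation(fit_linear(1:5, 300 - 300.5 * (1:5))),
               "domain error")
  f3 <- fit_linear(11:20, -1.521 * (11:20) + 267.8)
  expect_equal(unit_attenuation(f3), 0.0495, tolerance = 1e-3)
  expect_error(unit_attenuation(fit_power(1:6, 2 * (1:6)^0.5 + 1)),
               "linear")
})

test_that("flat trends give zero unit attenuation", {
  f <- fit_linear(1:5, rep(10, 5) + (1:5) * 1e-15)
  expect_equal(unit_attenuation(f), 0, tolerance = 1e-10)
})

test_that("fitted-curve agreement statistic", {
  x <- seq(2, 22, by = 4)
  fa <- fit_linear(x, -14.2 * x + 353.6)
  expect_equal(pearson_fit_agreement(fa, fa, x), 1)
  fb <- fit_linear(x, 3 * (-14.2 * x + 353.6) + 40)  # affine transform
  expect_equal(pearson_fit_agreement(fa, fb, x), 1, tolerance = 1e-12)
  # published companion-arm formula: near-perfect curve agreement
  fexp <- reference_fit("thickness", "experiment")
  expect_gt(pearson_fit_agreement(fa, fexp, x), 0.999)
  fconst <- fit_linear(x, rep(5, length(x)))
  expect_error(pearson_fit_agreement(fa, fconst, x),
               class = "fus_undefined_r")
})

test_that("tidy and glance methods expose coefficients and fit quality", {
  f <- fit_linear(c(1, 2, 3, 4), c(2.1, 3.9, 6.2, 7.8))
  td <- tidy(f)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("slope", "intercept"))
  gl <- glance(f)
  expect_true(all(c("r.squared", "model_form", "nobs") %in% names(gl)))
  expect_equal(gl$nobs, 4)
})
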