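test_that("substitution rate counts differing ungapped columns", {
  s <- paste(rep("ACGT", 25), collapse = "")
  expect_equal(substitution_rate(s, s)$S, 0)

  # 10 differences over 100 ungapped columns -> 10%
  s2 <- paste0(strrep("C", 10), substring(s, 11))  # ACGTACGTAC -> CCCCCCCCCC
  mism <- sum(strsplit(s, "")[[1]] != strsplit(s2, "")[[1]])
  expect_equal(mism, 7L)  # the C positions already matched
  s3 <- paste0(strrep("T", 10), substring(s, 11))
  expect_equal(substitution_rate(s, s3)$S,
               100 * sum(strsplit(s, "")[[1]][1:10] != "T") / 100)

  # 5 gap columns, 19 differences among the 95 compared -> 20%
  a <- strrep("A", 100)
  b <- paste0(strrep("-", 5), strrep("C", 19), strrep("A", 76))
  r <- substitution_rate(a, b)
  expect_equal(r$compared_sites, 95L)
  expect_equal(r$substituted_sites, 19L)
  expect_equal(r$S, 20.0)
})

test_that("substitution rate is symmetric, treats U as T, skips ambiguity", {
  a <- "ACGUUNRAC-G"
  b <- "ACGTTGCACAG"
  r1 <- substitution_rate(a, b)
  r2 <- substitution_rate(b, a)
  expect_equal(r1$S, r2$S)
  expect_equal(r1$compared_sites, r2$compared_sites)
  # U==T at positions 4-5; N and R columns excluded; gap column excluded
  expect_equal(r1$compared_sites, 8L)
  expect_equal(r1$substituted_sites, 0L)

  expect_error(substitution_rate("---", "AAA"), "no comparable")
  expect_error(substitution_rate("AC", "ACG"), "equal length")
})

test_that("noiseless calibration pairs are refit to machine precision", {
  pairs <- gen_calibration_pairs(50, const1 = 5.0112, const2 = 2.2223,
                                 noise_fraction = 0, seed = 4)
  fit <- fit_calibration(pairs$tan_theta, pairs$S)
  expect_equal(fit$const1, 5.0112, tolerance = 1e-6)
  expect_equal(fit$const2, 2.2223, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("the default calibration form passes through the origin", {
  pairs <- gen_calibration_pairs(40, noise_fraction = 0.05, seed = 8)
  pairs <- rbind(pairs, data.frame(tan_theta = 0, S = 0))
  fit <- fit_calibration(pairs$tan_theta, pairs$S, form = "exp_minus_one")
  expect_identical(predict(fit, 0), 0)
})

test_that("R-squared approaches 1 as noise vanishes", {
  r2 <- vapply(c(0.2, 0.05, 0.005), function(nf) {
    p <- gen_calibration_pairs(400, noise_fraction = nf, seed = 13)
    fit_calibration(p$tan_theta, p$S)$r_squared
  }, 0)
  expect_true(all(diff(r2) > 0))
  expect_gt(r2[3], 0.999)
})

test_that("degenerate or insufficient calibration data is refused", {
  expect_error(fit_calibration(c(0.1, 0.2), c(1, 2)), "at least 3")
  expect_error(fit_calibration(rep(0.5, 10), stats::runif(10)),
               "degenerate")
  expect_error(fit_calibration(c(0.1, 0.5, 1.5), c(1, 2, 3)),
               "\\[0, 1\\]")
})

test_that("prediction is monotone and matches the closed form at 1", {
  fit <- calibration_preset()
  tt <- seq(0, 1, by = 0.01)
  expect_true(all(diff(predict(fit, tt)) > 0))
  expect_equal(predict(fit, 1), 5.0112 * (exp(2.2223) - 1))
  expect_identical(predict(fit, 0), 0)
  expect_error(predict(fit, 0.5, convention = "complement"), "mismatch")
})

test_that("the inverse calibration round-trips", {
  model <- calibration_preset()
  tt <- seq(0, 1, by = 0.05)
  expect_equal(S_to_tantheta(model, predict(model, tt)), tt,
               tolerance = 1e-12)
  expect_error(S_to_tantheta(model, 1000), "range")
})

test_that("calibration models serialize and reload losslessly", {
  pairs <- gen_calibration_pairs(30, noise_fraction = 0.02, seed = 21)
  fit <- fit_calibration(pairs$tan_theta, pairs$S,
                         convention = "complement")
  f <- tempfile()
  write_calibration(fit, f)
  back <- read_calibration(f)
  expect_equal(back$const1, fit$const1)
  expect_equal(back$const2, fit$const2)
  expect_identical(back$form, fit$form)
  expect_identical(back$convention, "complement")
})

test_that("model methods expose coefficients and residuals", {
  pairs <- gen_calibration_pairs(30, noise_fraction = 0.02, seed = 22)
  fit <- fit_calibration(pairs$tan_theta, pairs$S)
  expect_named(coef(fit), c("const1", "const2"))
  expect_length(residuals(fit), 30L)
  expect_output(print(fit), "const1")
  expect_output(print(summary(fit)), "RMSE")
  expect_error(residuals(calibration_preset()), "no fitting data")
})
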