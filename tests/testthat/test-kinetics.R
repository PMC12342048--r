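test_that("progress_fraction evaluates the depletion model exactly", {
  expect_equal(progress_fraction(1e-9, 0, 2.4e5), 0)
  # E*t*k = ln 2 gives half-conversion
  expect_equal(progress_fraction(1e-9, log(2) / (1e-9 * 2.4e5), 2.4e5), 0.5)
  expect_equal(round(progress_fraction(1e-9, 1200, 2.4e5), 4), 0.2502)
  expect_error(progress_fraction(-1e-9, 10, 1), "non-negative")
  # increasing in E, t and k
  expect_true(all(diff(progress_fraction(1e-9, seq(0, 2000, 100), 2.4e5)) > 0))
  expect_true(all(diff(progress_fraction(seq(1, 9) * 1e-9, 600, 2.4e5)) > 0))
  expect_true(all(diff(progress_fraction(1e-9, 600, seq(1, 9) * 1e5)) > 0))
})

test_that("fit_progress_kcat_km is exact on noiseless data and errors on flat", {
  for (k_true in c(3.1e4, 2.4e5, 8e6)) {
    curves <- simulate_progress_curves(kcat_km = k_true, noise_sd = 0, seed = 1)
    fit <- fit_progress_kcat_km(curves)
    expect_equal(fit$estimate, k_true, tolerance = 1e-7)
  }
  flat <- tibble::tibble(enzyme_conc = 1e-9, time_s = c(0, 600, 1200),
                         fraction = 0)
  expect_error(fit_progress_kcat_km(flat), "identifiable")
  expect_error(fit_progress_kcat_km(flat[, 1:2]), "columns")
})

test_that("morrison_velocity matches closed forms and is monotone", {
  expect_equal(morrison_velocity(0.2e-9, 0, 0.045e-9), 1)
  expect_equal(morrison_velocity(0.2e-9, 0.2e-9, 0.045e-9), 0.375,
               tolerance = 1e-12)
  expect_error(morrison_velocity(0, 1e-9, 1e-9), "Et")
  expect_error(morrison_velocity(1e-9, -1, 1e-9), ">= 0")

  Ig <- seq(0, 5e-9, length.out = 60)
  v <- morrison_velocity(0.2e-9, Ig, 0.045e-9)
  expect_true(all(diff(v) < 0))           # strictly decreasing in I
  expect_true(all(v >= 0 & v <= 1))
  v_ki <- vapply(c(1, 2, 5, 10) * 1e-11,
                 function(ki) morrison_velocity(0.2e-9, 0.3e-9, ki), 1)
  expect_true(all(diff(v_ki) > 0))        # increasing in Ki
  # titration limit: at very large I the velocity vanishes
  expect_lt(morrison_velocity(0.2e-9, 1e-5, 0.045e-9), 1e-3)
})

test_that("Morrison reduces to the classical isotherm as Et -> 0", {
  Ki <- 0.045e-9
  Et <- Ki * 1e-4
  for (I in c(0.25, 0.5, 1, 2, 4) * Ki) {
    classical <- 1 / (1 + I / Ki)
    expect_equal(morrison_velocity(Et, I, Ki), classical,
                 tolerance = 1e-3)
  }
})

test_that("fit_morrison_ki recovers exactly without noise and handles edge cases", {
  for (ki_true in c(20e-12, 45e-12, 500e-12)) {
    series <- simulate_inhibition_series(ki = ki_true, noise_sd = 0, seed = 1)
    fit <- fit_morrison_ki(series)
    expect_equal(fit$estimate, ki_true, tolerance = 1e-6)
  }

  # non-identifiable: essentially no inhibition observed
  none <- tibble::tibble(inhibitor_conc = c(0, 1, 2, 4) * 1e-9,
                         vi_over_v0 = c(1, 0.99, 1.0, 0.98))
  expect_error(fit_morrison_ki(none, Et = 0.2e-9), "identifiable")

  # stress: Et >> Ki behaves like an active-site titration but still converges
  tight <- simulate_inhibition_series(ki = 1e-13, Et = 5e-9,
                                      inhibitor_concs = seq(0, 10e-9, 1e-9),
                                      noise_sd = 0, seed = 2)
  fit_tight <- fit_morrison_ki(tight)
  expect_true(is.finite(fit_tight$estimate))
  # titration endpoint: vi/v0 at I = Et is close to the tight-binding value
  expect_equal(morrison_velocity(5e-9, 5e-9, 1e-13),
               1 - (1 - sqrt(1e-13 / 5e-9)), tolerance = 0.01)

  # the v0-scale variant also recovers the truth on clean normalized data
  series <- simulate_inhibition_series(ki = 45e-12, noise_sd = 0, seed = 3)
  fit_v0 <- fit_morrison_ki(series, fit_v0 = TRUE)
  expect_equal(fit_v0$estimate, 45e-12, tolerance = 1e-3)
  expect_equal(unname(coef(fit_v0$fit)["v0"]), 1, tolerance = 1e-3)
})

test_that("fits are deterministic for a fixed simulation seed", {
  f1 <- fit_progress_kcat_km(simulate_progress_curves(seed = 42))
  f2 <- fit_progress_kcat_km(simulate_progress_curves(seed = 42))
  expect_identical(f1$estimate, f2$estimate)
  m1 <- fit_morrison_ki(simulate_inhibition_series(seed = 42))
  m2 <- fit_morrison_ki(simulate_inhibition_series(seed = 42))
  expect_identical(m1$estimate, m2$estimate)
})

test_that("standard-curve interpolation is linear and range-aware", {
  curve <- tibble::tibble(concentration = c(0, 0.39, 0.78, 1.56),
                          signal = c(0.05, 0.40, 0.75, 1.45))
  exact <- interpolate_standard_curve(curve, 0.40)
  expect_equal(exact$concentration, 0.39)
  expect_false(exact$out_of_range)

  mid <- interpolate_standard_curve(curve, (0.40 + 0.75) / 2)
  expect_equal(mid$concentration, (0.39 + 0.78) / 2)

  high <- interpolate_standard_curve(curve, 2.0)
  expect_true(high$out_of_range)
  expect_true(is.na(high$concentration))
  # explicit extrapolation extends the terminal segment linearly
  ex <- interpolate_standard_curve(curve, 2.0, extrapolate = TRUE)
  expect_equal(ex$concentration, 1.56 + (2.0 - 1.45) * (1.56 - 0.78) / (1.45 - 0.75))

  bad <- tibble::tibble(concentration = c(0, 1, 2), signal = c(0.1, 0.5, 0.3))
  expect_error(interpolate_standard_curve(bad, 0.2), "monotone")
})

test_that("tidy and glance summarize kinetic fits", {
  fit <- fit_progress_kcat_km(simulate_progress_curves(seed = 5))
  td <- tidy(fit)
  expect_equal(td$term, "kcat_km")
  expect_true(td$std.error > 0)
  gl <- glance(fit)
  expect_equal(gl$nobs, 21)

  mfit <- fit_morrison_ki(simulate_inhibition_series(seed = 5))
  expect_equal(tidy(mfit)$term, "Ki")
  expect_s3_class(autoplot(mfit), "ggplot")
  expect_s3_class(autoplot(fit), "ggplot")
})
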