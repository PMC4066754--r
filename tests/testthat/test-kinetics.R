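test_that("monoexponential fits recover rates exactly without noise", {
  t <- c(0.25, 0.5, 1, 2, 4, 8)
  tc <- time_course(t, 1 - exp(-0.16 * t))
  f <- fit_timecourse(tc)
  expect_equal(f$k_eff, 0.16, tolerance = 1e-9)
  expect_equal(f$plateau, 1)
  # free plateau recovers both
  tc2 <- time_course(t, 0.8 * (1 - exp(-0.5 * t)))
  f2 <- fit_timecourse(tc2, plateau_mode = "free")
  expect_equal(f2$k_eff, 0.5, tolerance = 1e-7)
  expect_equal(f2$plateau, 0.8, tolerance = 1e-7)
  expect_error(time_course(c(0, 1), c(0, 1)), class = "primext_input_error")
  expect_error(fit_timecourse(time_course(1:3, c(0, 0, 0))),
               class = "primext_input_error")
})

test_that("early-time fit of the hydrolysis-coupled curve gives the RNA rate", {
  # full yield model, monoexponential fit to the first four points only:
  # the apparent rate approaches alpha * k_cov = 0.159 and the reported
  # value is 0.16 h^-1
  s <- rna_scenario()
  t4 <- c(0.25, 0.5, 0.75, 1)
  tc <- time_course(t4, yield_closed_form(s, t4))
  k <- fit_timecourse(tc)$k_eff
  expect_lt(abs(k - 0.16) / 0.16, 0.10)
})

test_that("effective rate follows the competitive-inhibition law", {
  expect_equal(predict_keff(0.3, 0, 100), 0.3)
  # Kd 2 mM: a 2-min half-life stretches 19-fold to 38 min
  k <- halflife_to_rate(2)
  expect_equal(halflife(predict_keff(k, 0.5, 36)), 38)
  # Kd 5 mM: 7 min stretches to 57.4 min (reported as ~60)
  expect_equal(halflife(predict_keff(log(2) / 7, 0.2, 36)), 57.4)
  # monotone decreasing in inhibitor; reciprocal exactly affine
  inh <- seq(0, 72, by = 4)
  ke <- predict_keff(0.3, 0.2, inh)
  expect_true(all(diff(ke) < 0))
  recip <- 1 / ke
  expect_equal(recip, 1 / 0.3 + (0.2 / 0.3) * inh, tolerance = 1e-12)
})

test_that("reciprocal-rate linearization extracts k and K_inh", {
  inh <- c(0, 3.6, 18, 36)
  ke <- predict_keff(0.3, 0.2, inh)
  f <- fit_inhibition_linear(inh, ke)
  expect_equal(f$k, 0.3, tolerance = 1e-12)
  expect_equal(f$k_inh, 0.2, tolerance = 1e-12)
  expect_equal(f$kd, 5, tolerance = 1e-10)
  # two points suffice in fixed-intercept mode
  f2 <- fit_inhibition_linear(c(0, 18), predict_keff(0.2, 0.5, c(0, 18)),
                              intercept_mode = "fixed_at_zero_inh")
  expect_equal(f2$k, 0.2, tolerance = 1e-12)
  expect_equal(f2$k_inh, 0.5, tolerance = 1e-12)
  expect_error(fit_inhibition_linear(c(0, 18), c(0.2, 0.1)),
               class = "primext_input_error")
  # distorted reciprocal line with a negative extrapolated intercept
  expect_error(
    fit_inhibition_linear(c(10, 20, 40), 1 / c(1, 30, 70)),
    class = "primext_fit_error")
})

test_that("noisy two-stage analysis recovers K_inh within the envelope", {
  # envelope (20%) validated by the Monte-Carlo calibration test
  tcs <- gen_inhibitor_series(0.3, 0.2, times_h = c(0.5, 1, 2, 4, 8, 16),
                              noise_sd = 0.02, seed = 23)
  ke <- vapply(tcs, function(x) fit_timecourse(x)$k_eff, numeric(1))
  inh <- vapply(tcs, function(x) x$conditions$inhibitor_mM, numeric(1))
  f <- fit_inhibition_linear(inh, ke)
  expect_lt(abs(f$k_inh - 0.2) / 0.2, 0.20)
})

test_that("global fit matches two-stage exactly on noiseless data", {
  tcs <- gen_inhibitor_series(0.3, 0.2, times_h = c(0.5, 1, 2, 4, 8, 16),
                              noise_sd = 0)
  g <- fit_inhibition_global(tcs)
  expect_equal(g$k, 0.3, tolerance = 1e-9)
  expect_equal(g$k_inh, 0.2, tolerance = 1e-9)
  # unidentifiable from a single zero-inhibitor curve
  expect_error(fit_inhibition_global(tcs[1]),
               class = "primext_input_error")
  # inconsistent conditions rejected
  tcs2 <- tcs
  tcs2[[2]]$conditions$monomer_mM <- 7.2
  expect_error(fit_inhibition_global(tcs2), class = "primext_input_error")
})

test_that("full noiseless pipeline round-trips random kinetic parameters", {
  set.seed(301)
  for (i in 1:50) {
    k <- runif(1, 0.05, 5)
    k_inh <- runif(1, 0.02, 1)
    times <- seq(0.2, 6, length.out = 6) / k
    tcs <- gen_inhibitor_series(k, k_inh, times_h = times, noise_sd = 0)
    ke <- vapply(tcs, function(x) fit_timecourse(x)$k_eff, numeric(1))
    inh <- vapply(tcs, function(x) x$conditions$inhibitor_mM, numeric(1))
    f <- fit_inhibition_linear(inh, ke)
    expect_equal(f$k, k, tolerance = 1e-6)
    expect_equal(f$k_inh, k_inh, tolerance = 1e-6)
  }
})

test_that("hydrolysis decay fitting recovers k_h and its half-life", {
  dc <- gen_decay(0.147, noise_sd = 0)
  f <- fit_decay(dc)
  expect_equal(f$k_h, 0.147, tolerance = 1e-9)
  expect_equal(f$halflife_h, log(2) / 0.147, tolerance = 1e-9)
  expect_equal(round(f$halflife_h, 2), 4.72)
  # constant intact signal: no hydrolysis
  f0 <- fit_decay(time_course(c(0, 2, 4, 8), rep(1, 4)))
  expect_equal(f0$k_h, 0, tolerance = 1e-9)
  rising <- suppressWarnings(time_course(c(0, 1, 2), c(1, 1.01, 1.04)))
  expect_error(fit_decay(rising), class = "primext_input_error")
  # decay and growth fits agree on the same rate
  t <- c(0.5, 1, 2, 4, 8)
  rate <- 0.3
  f_dec <- fit_decay(time_course(c(0, t), exp(-rate * c(0, t))))
  f_gro <- fit_timecourse(time_course(t, 1 - exp(-rate * t)))
  expect_equal(f_dec$k_h, f_gro$k_eff, tolerance = 1e-8)
})

test_that("half-life conversions are exact reciprocal pairs", {
  expect_equal(halflife(log(2) / 2), 2)
  expect_equal(halflife(0.16), log(2) / 0.16)
  expect_equal(round(halflife(0.16), 2), 4.33)
  for (k in c(0.01, 0.16, 2, 40)) {
    expect_equal(halflife_to_rate(halflife(k)), k, tolerance = 1e-15)
  }
  expect_equal(minutes_to_hours(60), 1)
  expect_equal(kd_from_inhibition(0.5), 2)
})
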