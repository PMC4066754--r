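test_that("closed-form yield evaluates the hydrolysis-coupled expression", {
  s <- rna_scenario()
  expect_equal(yield_closed_form(s, 0), 0)
  # t -> infinity plateau of the reference RNA scenario
  expect_equal(yield_closed_form(s, 1e6),
               1 - exp(-0.27 * 20 / (0.147 * 34)), tolerance = 1e-12)
  expect_equal(plateau_yield(s), 0.6605, tolerance = 1e-4)
  # no-hydrolysis limit: simple exponential approach to completion
  s0 <- rna_scenario(k_h = 0)
  tgrid <- seq(0, 48, by = 2)
  expect_equal(yield_closed_form(s0, tgrid),
               1 - exp(-0.27 * 20 * tgrid / 34), tolerance = 1e-12)
  # k_h -> 0 continuity of the two branches
  s_eps <- rna_scenario(k_h = 1e-8)
  expect_equal(yield_closed_form(s_eps, tgrid),
               yield_closed_form(s0, tgrid), tolerance = 1e-6)
  # unequal affinities are refused by the closed form
  expect_error(yield_closed_form(rna_scenario(kd_i = 14 / 3), 1),
               class = "primext_domain_error")
})

test_that("ODE and closed form agree under the constant-denominator convention", {
  s <- rna_scenario()
  curve <- yield_ode(s)
  expect_equal(curve$provenance, "ode_constant")
  expect_lt(max(abs(curve$yields - yield_closed_form(s))), 1e-6)
  # zero covalent rate: no product ever
  s_null <- rna_scenario()
  s_null$k_cov <- 0
  expect_true(all(yield_ode(s_null)$yields == 0))
  # tighter-binding inhibitor (helper-strand case): yields ordered
  # inversely to added inhibitor at every time point
  curves <- lapply(c(0, 5, 20), function(i0)
    yield_ode(rna_scenario(inh0 = i0, kd_i = 14 / 3)))
  expect_equal(curves[[1]]$provenance, "ode_track")
  y0 <- curves[[1]]$yields; y5 <- curves[[2]]$yields; y20 <- curves[[3]]$yields
  keep <- curves[[1]]$times > 0
  expect_true(all(y0[keep] > y5[keep]))
  expect_true(all(y5[keep] > y20[keep]))
})

test_that("k_cov extraction inverts the occupancy-scaled rate", {
  expect_equal(round(kcov_from_rate(0.16, occupancy(14, 20)), 2), 0.27)
  expect_equal(kcov_from_rate(0.4, 1), 0.4)
  # inverse consistency with the amino-terminal DNA system
  alpha <- occupancy(6.9, 3.6)
  expect_equal(kcov_from_rate(8.3 * alpha, alpha), 8.3, tolerance = 1e-12)
  expect_error(kcov_from_rate(0.1, 0), class = "primext_domain_error")
})

test_that("yield curves are monotone and respond correctly to parameters", {
  set.seed(401)
  tgrid <- seq(0, 48, length.out = 25)
  for (i in 1:1000) {
    s <- yield_scenario(kd_m = runif(1, 1, 300), m0 = runif(1, 0.05, 50),
                        k_cov = runif(1, 0.01, 15), k_h = runif(1, 0, 1),
                        inh0 = runif(1, 0, 50), times = tgrid)
    y <- yield_closed_form(s)
    expect_true(all(diff(y) >= -1e-12))
    # mathematically y < 1 always; saturating draws round to 1.0 in doubles
    expect_true(y[1] == 0 && all(y >= 0 & y <= 1))
  }
  # pointwise parameter sensitivities on a fixed grid
  base <- list(kd_m = 14, m0 = 20, k_cov = 0.27, k_h = 0.147, inh0 = 5)
  yb <- yield_closed_form(do.call(yield_scenario, c(base, list(times = tgrid))))
  bump <- function(par, value) {
    b <- base; b[[par]] <- value
    yield_closed_form(do.call(yield_scenario, c(b, list(times = tgrid))))
  }
  keep <- tgrid > 0
  expect_true(all(bump("kd_m", 28)[keep] < yb[keep]))
  expect_true(all(bump("inh0", 20)[keep] < yb[keep]))
  expect_true(all(bump("k_h", 0.3)[keep] < yb[keep]))
  expect_true(all(bump("k_cov", 0.54)[keep] > yb[keep]))
  expect_true(all(bump("m0", 40)[keep] > yb[keep]))
})

test_that("plateau yield behaves at its limits", {
  s_fast <- rna_scenario()
  s_fast$k_cov <- 1e6
  expect_equal(as.numeric(plateau_yield(s_fast)), 1, tolerance = 1e-12)
  p0 <- plateau_yield(rna_scenario(k_h = 0))
  expect_equal(as.numeric(p0), 1)
  expect_true(attr(p0, "no_hydrolysis"))
  expect_lt(plateau_yield(rna_scenario(inh0 = 20)),
            plateau_yield(rna_scenario(inh0 = 0)))
})

test_that("sweep simulation reproduces the dilution-series phenomenology", {
  tgrid <- seq(0, 10, length.out = 41)
  # amino-terminal DNA, A monomer: dilution sweep lowers the plateau
  base_a <- yield_scenario(kd_m = 6.9, m0 = 3.6, k_cov = 8.3, k_h = 0.109,
                           times = tgrid)
  ser <- simulate_series(base_a, list(m0 = c(3.6, 0.36, 0.18, 0.036)))
  expect_length(ser, 4)
  finals <- vapply(ser, function(cv) cv$yields[length(cv$yields)],
                   numeric(1))
  expect_true(all(diff(finals) < 0))
  expect_equal(vapply(ser, `[[`, numeric(1), "sweep_value"),
               c(3.6, 0.36, 0.18, 0.036))
  # G monomer: halving the effective concentration of the most dilute
  # level lowers that curve only
  base_g <- yield_scenario(kd_m = 6.8, m0 = 0.036, k_cov = 12.2,
                           k_h = 0.093, times = tgrid)
  y_full <- yield_closed_form(base_g)
  base_g_half <- yield_scenario(kd_m = 6.8, m0 = 0.036, k_cov = 12.2,
                                k_h = 0.093, conc_scale = 0.5,
                                times = tgrid)
  y_half <- yield_closed_form(base_g_half)
  expect_true(all(y_half[tgrid > 0] < y_full[tgrid > 0]))
  expect_error(simulate_series(base_a, list(m0 = numeric(0))),
               class = "primext_input_error")
  expect_error(simulate_series(base_a, list(k_h = c(0.1, 0.2))),
               class = "primext_config_error")
  # closed form is used when permissible, ODE when forced
  expect_equal(ser[[1]]$provenance, "closed_form")
  ser_ode <- simulate_series(base_a, list(m0 = 3.6), mode = "ode")
  expect_equal(ser_ode[[1]]$provenance, "ode_constant")
  expect_lt(max(abs(ser_ode[[1]]$yields - ser[[1]]$yields)), 1e-6)
})
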