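# Synthetic-data generators: titrations, extension time courses,
# inhibitor series, yield courses and hydrolysis decays with the
# statistical structure the fitters assume (additive iid Gaussian noise
# on the observed quantity). All generators are deterministic under a
# given seed and leave the caller's RNG state untouched.

#' Default titration design: log-spaced ligand levels up to a maximum
#'
#' Zero plus `n - 1` two-fold-spaced levels ending at `max_mM`, echoing
#' a shift titration driven to high nucleotide excess.
#'
#' @param max_mM top ligand concentration, mM (default 774).
#' @param n number of levels including zero (default 8).
#' @return Numeric vector of ligand concentrations, mM.
#' @export
titration_design <- function(max_mM = 774, n = 8) {
  check_positive(max_mM, "max_mM")
  c(0, max_mM / 2^((n - 2):0))
}

#' Generate a synthetic NMR titration
#'
#' Forward model is [predict_shift]; Gaussian noise of standard
#' deviation `noise_sd` ppm is added to the shifts.
#'
#' @param kd true dissociation constant, mM.
#' @param delta0 shift at zero ligand, ppm.
#' @param delta_max limiting shift displacement, ppm (sign free).
#' @param host_mM host concentration, mM (default 0.5).
#' @param ligand_mM design concentrations, mM (default
#'   [titration_design]).
#' @param noise_sd noise standard deviation, ppm (default 0.002).
#' @param seed integer seed; `NULL` leaves the RNG stream alone.
#' @param model forward binding model, `"quadratic"` or `"excess"`.
#' @return A [titration_series].
#' @export
gen_titration <- function(kd, delta0, delta_max, host_mM = 0.5,
                          ligand_mM = titration_design(),
                          noise_sd = 0.002, seed = NULL,
                          model = c("quadratic", "excess")) {
  model <- match.arg(model)
  check_nonnegative(noise_sd, "noise_sd")
  if (any(ligand_mM < 0)) px_input("design concentrations must be nonnegative")
  mu <- predict_shift(list(kd = kd, delta0 = delta0, delta_max = delta_max),
                      host_mM, ligand_mM, model = model)
  y <- with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  titration_series(ligand_mM, y, host_mM)
}

#' Default inhibitor levels from a monomer concentration
#'
#' Equivalence multipliers times the monomer concentration; the default
#' 0/1/5/10 equivalents of 3.6 mM monomer give 0, 3.6, 18, 36 mM.
#'
#' @param monomer_mM monomer concentration, mM (default 3.6).
#' @param eq equivalence multipliers (default `c(0, 1, 5, 10)`).
#' @return Inhibitor concentrations in mM.
#' @export
inhibitor_levels <- function(monomer_mM = 3.6, eq = c(0, 1, 5, 10)) {
  check_positive(monomer_mM, "monomer_mM")
  monomer_mM * eq
}

# clip noisy fractions into the tolerated band
.clip_fraction <- function(x) pmin(pmax(x, 0), 1.05)

#' Generate extension time courses across inhibitor levels
#'
#' Forward model fraction(t) = 1 - exp(-t k / (1 + k_inh inh)) per
#' level; Gaussian noise on the fractions, clipped to [0, 1.05].
#'
#' @param k zero-inhibitor pseudo-first-order rate, h^-1.
#' @param k_inh inhibitor association constant, mM^-1.
#' @param inh_mM inhibitor levels, mM (default [inhibitor_levels]).
#' @param times_h shared sampling times, hours.
#' @param noise_sd noise standard deviation on fractions (default 0.02).
#' @param seed integer seed.
#' @param monomer_mM,monomer condition annotations.
#' @return List of [time_course] objects, one per inhibitor level.
#' @export
gen_inhibitor_series <- function(k, k_inh, inh_mM = inhibitor_levels(),
                                 times_h = c(2, 5, 10, 20, 40, 60, 90, 120) / 60,
                                 noise_sd = 0.02, seed = NULL,
                                 monomer_mM = 3.6, monomer = "") {
  check_nonnegative(k, "k")
  check_nonnegative(k_inh, "k_inh")
  check_nonnegative(noise_sd, "noise_sd")
  if (length(inh_mM) == 0) px_input("inh_mM must be nonempty")
  with_seed(seed, lapply(inh_mM, function(inh) {
    mu <- 1 - exp(-times_h * predict_keff(k, k_inh, inh))
    y <- .clip_fraction(mu + stats::rnorm(length(mu), 0, noise_sd))
    suppressWarnings(time_course(times_h, y, monomer = monomer,
                                 monomer_mM = monomer_mM,
                                 inhibitor_mM = inh))
  }))
}

#' Generate a yield time course from a scenario
#'
#' Forward model is [yield_ode]; Gaussian noise on the yield fractions,
#' clipped to [0, 1.05].
#'
#' @param s a [yield_scenario].
#' @param times_h sampling times, hours; defaults to the scenario grid.
#' @param noise_sd noise standard deviation (default 0.02).
#' @param seed integer seed.
#' @return A [time_course] of extended-primer fraction.
#' @export
gen_yield_course <- function(s, times_h = s$times, noise_sd = 0.02,
                             seed = NULL) {
  check_nonnegative(noise_sd, "noise_sd")
  mu <- yield_ode(s, times = times_h)$yields
  y <- with_seed(seed,
                 .clip_fraction(mu + stats::rnorm(length(mu), 0, noise_sd)))
  suppressWarnings(time_course(sort(unique(times_h)), y,
                               monomer_mM = s$m0,
                               inhibitor_mM = s$inh0))
}

#' Generate a monomer-hydrolysis decay
#'
#' Forward model exp(-k_h t); Gaussian noise clipped to [0, 1.05].
#'
#' @param k_h hydrolysis rate, h^-1.
#' @param times_h sampling times, hours.
#' @param noise_sd noise standard deviation (default 0.02).
#' @param seed integer seed.
#' @return A [time_course] of intact-monomer fraction.
#' @export
gen_decay <- function(k_h, times_h = seq(0, 24, by = 2), noise_sd = 0.02,
                      seed = NULL) {
  check_nonnegative(k_h, "k_h")
  check_nonnegative(noise_sd, "noise_sd")
  mu <- exp(-k_h * times_h)
  y <- with_seed(seed,
                 .clip_fraction(mu + stats::rnorm(length(mu), 0, noise_sd)))
  suppressWarnings(time_course(times_h, y))
}
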