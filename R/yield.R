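# Time-dependent yield of primer extension under concurrent monomer
# hydrolysis: closed-form expression and its ODE generalization.
#
# The model: activated monomer M binds the primer-template complex with
# dissociation constant kd_m and reacts covalently at rate k_cov from
# the bound state; M hydrolyses at rate k_h into a free nucleotide that
# binds the same site (kd_i) without reacting. [Inh] denotes inhibitor
# added at t = 0; hydrolysis-produced inhibitor is accounted for by the
# hydrolysis term itself.

#' Define a yield-prediction scenario
#'
#' @param kd_m monomer dissociation constant, mM (> 0).
#' @param m0 initial activated-monomer concentration, mM (> 0).
#' @param k_cov covalent extension rate from the bound state, h^-1 (>= 0).
#' @param k_h monomer hydrolysis rate, h^-1 (>= 0).
#' @param kd_i inhibitor dissociation constant, mM (> 0); defaults to
#'   `kd_m`. A downstream-binding helper strand typically warrants
#'   `kd_m / helper_kd_factor` for the unactivated nucleotide.
#' @param inh0 inhibitor concentration added at t = 0, mM (>= 0).
#' @param conc_scale multiplier in (0, 1] on the nominal `m0`, modelling
#'   loss of reactive monomer (default 1).
#' @param times default output time grid in hours.
#' @return An object of class `yield_scenario`.
#' @export
yield_scenario <- function(kd_m, m0, k_cov, k_h, kd_i = kd_m, inh0 = 0,
                           conc_scale = 1,
                           times = seq(0, 48, length.out = 97)) {
  check_positive(kd_m, "kd_m")
  check_positive(kd_i, "kd_i")
  check_positive(m0, "m0")
  check_nonnegative(k_cov, "k_cov")
  check_nonnegative(k_h, "k_h")
  check_nonnegative(inh0, "inh0")
  if (conc_scale <= 0 || conc_scale > 1) {
    px_domain("conc_scale must lie in (0, 1]")
  }
  check_nonnegative(times, "times")
  structure(
    list(kd_m = kd_m, kd_i = kd_i, m0 = m0, inh0 = inh0, k_cov = k_cov,
         k_h = k_h, conc_scale = conc_scale, times = sort(times)),
    class = "yield_scenario")
}

#' @export
print.yield_scenario <- function(x, ...) {
  cat(sprintf(
    "<yield_scenario> Kd %.3g mM (inhibitor %.3g), [M]0 %.3g mM x %.3g, [Inh]0 %.3g mM, k_cov %.3g h^-1, k_h %.3g h^-1\n",
    x$kd_m, x$kd_i, x$m0, x$conc_scale, x$inh0, x$k_cov, x$k_h))
  invisible(x)
}

#' Closed-form extension yield under monomer hydrolysis
#'
#' Y(t) = 1 - exp[ k_cov M0 (exp(-k_h t) - 1) / (k_h (Kd + M0 + Inh0)) ]
#' with M0 the (scaled) initial monomer concentration. Valid for equal
#' monomer and inhibitor affinities; the denominator Kd + M0 + Inh0 is
#' constant because total nucleotide is conserved. Below a hydrolysis
#' rate of 1e-9 h^-1 the analytic no-hydrolysis limit
#' 1 - exp(-k_cov M0 t / (Kd + M0 + Inh0)) is used.
#'
#' @param s a [yield_scenario] with `kd_i == kd_m`.
#' @param t time(s) in hours.
#' @return Yield fraction(s) in [0, 1).
#' @export
yield_closed_form <- function(s, t = s$times) {
  if (!inherits(s, "yield_scenario")) px_input("`s` must be a yield_scenario")
  if (s$kd_i != s$kd_m) {
    px_domain(paste("closed form requires equal monomer and inhibitor",
                    "affinities (kd_i == kd_m); use yield_ode()"))
  }
  check_nonnegative(t, "t")
  m <- s$conc_scale * s$m0
  denom <- s$kd_m + m + s$inh0
  if (s$k_h < 1e-9) {
    1 - exp(-s$k_cov * m * t / denom)
  } else {
    1 - exp(s$k_cov * m * (exp(-s$k_h * t) - 1) / (s$k_h * denom))
  }
}

#' Ultimate (t -> infinity) extension yield
#'
#' The plateau of the closed-form yield: hydrolysis eventually destroys
#' all monomer, capping the yield below 1. With `k_h = 0` the reaction
#' runs to completion and the plateau is 1 (flagged via the
#' `"no_hydrolysis"` attribute).
#'
#' @param s a [yield_scenario].
#' @return Plateau yield fraction.
#' @export
plateau_yield <- function(s) {
  if (!inherits(s, "yield_scenario")) px_input("`s` must be a yield_scenario")
  m <- s$conc_scale * s$m0
  if (s$k_h == 0) {
    return(structure(1, no_hydrolysis = TRUE))
  }
  1 - exp(-s$k_cov * m / (s$k_h * (s$kd_m + m + s$inh0)))
}

#' Numerical (ODE) extension yield
#'
#' Integrates dP1/dt = -k_cov alpha(t) P1 with adaptive step control
#' (relative tolerance 1e-8, absolute 1e-12). Two conventions for the
#' site occupancy alpha(t):
#' \describe{
#'   \item{constant}{alpha(t) = M(t) / (Kd + M0 + Inh0), the constant
#'     total-nucleotide denominator of the closed form; requires equal
#'     affinities and matches [yield_closed_form] to solver tolerance.}
#'   \item{track}{alpha(t) = (M/kd_m) / (1 + M/kd_m + I/kd_i) with
#'     M(t) = M0 exp(-k_h t) and I(t) = Inh0 + M0 (1 - exp(-k_h t))
#'     tracked explicitly; required when kd_i != kd_m.}
#' }
#' The default `"auto"` picks `"constant"` for equal affinities and
#' `"track"` otherwise.
#'
#' @param s a [yield_scenario].
#' @param denominator `"auto"` (default), `"constant"` or `"track"`.
#' @param times output grid in hours; defaults to the scenario grid.
#' @return An object of class `yield_curve`: `times`, `yields`,
#'   `provenance` (`"ode_constant"` or `"ode_track"`).
#' @export
yield_ode <- function(s, denominator = c("auto", "constant", "track"),
                      times = s$times) {
  if (!inherits(s, "yield_scenario")) px_input("`s` must be a yield_scenario")
  denominator <- match.arg(denominator)
  if (denominator == "auto") {
    denominator <- if (s$kd_i == s$kd_m) "constant" else "track"
  }
  if (denominator == "constant" && s$kd_i != s$kd_m) {
    px_domain("constant-denominator convention requires kd_i == kd_m")
  }
  check_nonnegative(times, "times")
  times <- sort(unique(times))
  m0 <- s$conc_scale * s$m0
  alpha_fun <- if (denominator == "constant") {
    denom <- s$kd_m + m0 + s$inh0
    function(t) m0 * exp(-s$k_h * t) / denom
  } else {
    function(t) {
      M <- m0 * exp(-s$k_h * t)
      I <- s$inh0 + (m0 - M)
      (M / s$kd_m) / (1 + M / s$kd_m + I / s$kd_i)
    }
  }
  rhs <- function(t, y, parms) list(-s$k_cov * alpha_fun(t) * y)
  grid <- if (times[1] > 0) c(0, times) else times
  sol <- tryCatch(
    deSolve::lsoda(c(P1 = 1), grid, rhs, parms = NULL,
                   rtol = 1e-8, atol = 1e-12),
    error = function(e)
      px_fit_failure(sprintf(
        "ODE integration failed (%s) for scenario kd_m=%g kd_i=%g m0=%g inh0=%g k_cov=%g k_h=%g",
        conditionMessage(e), s$kd_m, s$kd_i, s$m0, s$inh0, s$k_cov, s$k_h)))
  p1 <- sol[match(times, sol[, "time"]), "P1"]
  structure(
    list(times = times, yields = pmin(pmax(1 - p1, 0), 1),
         provenance = paste0("ode_", denominator)),
    class = "yield_curve")
}

#' @export
print.yield_curve <- function(x, ...) {
  cat(sprintf(
    "<yield_curve> %d points to %.3g h, final yield %.4f (%s)\n",
    length(x$times), max(x$times), x$yields[length(x$yields)],
    x$provenance))
  invisible(x)
}

#' @export
as.data.frame.yield_curve <- function(x, ...) {
  data.frame(time_h = x$times, yield = x$yields,
             provenance = x$provenance)
}

#' Covalent rate constant from an observed early rate and occupancy
#'
#' At early times, before hydrolysis matters, the observed
#' pseudo-first-order rate is k = alpha k_cov, so k_cov = k / alpha.
#'
#' @param k observed early-time rate, h^-1 (>= 0).
#' @param alpha extension-site occupancy in (0, 1].
#' @return k_cov in h^-1.
#' @examples
#' kcov_from_rate(0.16, occupancy(14, 20))  # ~0.27 h^-1
#' @export
kcov_from_rate <- function(k, alpha) {
  check_nonnegative(k, "k")
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha > 1)) {
    px_domain("`alpha` must lie in (0, 1]")
  }
  k / alpha
}

#' Simulate a family of yield curves over a parameter sweep
#'
#' Produces one yield curve per sweep value, on a shared time grid.
#' Supported sweep parameters: `inh0` (added inhibitor) and `m0`
#' (monomer dilution series). The closed form is used when permissible
#' (equal affinities) unless `mode = "ode"` forces integration.
#'
#' @param base a [yield_scenario] providing all non-swept parameters.
#' @param sweep named list of length 1, e.g. `list(inh0 = c(0, 5, 20))`
#'   or `list(m0 = c(3.6, 0.36, 0.18, 0.036))`.
#' @param mode `"auto"` (default), `"closed"` or `"ode"`.
#' @param times shared time grid in hours; defaults to the base grid.
#' @return A `yield_series`: list of `yield_curve`s, each carrying
#'   `sweep_name`/`sweep_value`; has an `as.data.frame` method.
#' @export
simulate_series <- function(base, sweep, mode = c("auto", "closed", "ode"),
                            times = base$times) {
  mode <- match.arg(mode)
  if (!inherits(base, "yield_scenario")) {
    px_input("`base` must be a yield_scenario")
  }
  if (!is.list(sweep) || length(sweep) != 1 || is.null(names(sweep)) ||
      length(sweep[[1]]) == 0) {
    px_input("`sweep` must be a named list of one nonempty vector")
  }
  name <- names(sweep)
  if (!name %in% c("inh0", "m0")) {
    px_config(sprintf("unsupported sweep parameter '%s' (use inh0 or m0)",
                      name))
  }
  curves <- lapply(sweep[[1]], function(v) {
    s <- base
    s[[name]] <- v
    s$times <- times
    s <- do.call(yield_scenario, unclass(s))
    cv <- if (mode == "ode" || (mode == "auto" && s$kd_i != s$kd_m)) {
      yield_ode(s, times = times)
    } else if (mode == "closed" || s$kd_i == s$kd_m) {
      structure(list(times = times,
                     yields = yield_closed_form(s, times),
                     provenance = "closed_form"),
                class = "yield_curve")
    } else {
      yield_ode(s, times = times)
    }
    cv$sweep_name <- name
    cv$sweep_value <- v
    cv
  })
  structure(curves, class = "yield_series")
}

#' @export
as.data.frame.yield_series <- function(x, ...) {
  do.call(rbind, lapply(x, function(cv)
    data.frame(time_h = cv$times, sweep_value = cv$sweep_value,
               yield = cv$yields, provenance = cv$provenance)))
}

#' @export
print.yield_series <- function(x, ...) {
  cat(sprintf("<yield_series> %d curves over %s = %s\n",
              length(x), x[[1]]$sweep_name,
              paste(vapply(x, `[[`, numeric(1), "sweep_value"),
                    collapse = ", ")))
  invisible(x)
}
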