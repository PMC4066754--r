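# Competitive-inhibition kinetics: pseudo-first-order fits of extension
# time courses, reciprocal-rate linearization and global fits across
# inhibitor levels, and first-order monomer-hydrolysis decay.
#
# Internal units: time in hours, rates in h^-1, concentrations in mM.

#' Construct a kinetic time course
#'
#' Holds (time, fraction) pairs for either the extended-primer fraction
#' of an extension assay or the intact-monomer fraction of a hydrolysis
#' assay, together with the assay conditions.
#'
#' @param time observation times, nonnegative and strictly increasing.
#' @param fraction observed fractions in [0, 1.05] (a small calibration
#'   overshoot above 1 is tolerated but flagged with a warning).
#' @param time_unit `"hours"` (default) or `"minutes"`; minutes are
#'   converted to hours on construction.
#' @param monomer monomer identity label.
#' @param monomer_mM activated-monomer concentration, mM.
#' @param inhibitor_mM unactivated-nucleotide (inhibitor) concentration, mM.
#' @param helper_present logical, downstream-binding strand present.
#' @param temperature_c temperature, degrees Celsius.
#' @param motif sequence-context label (e.g. "TCT").
#' @return An object of class `time_course`.
#' @export
time_course <- function(time, fraction, time_unit = c("hours", "minutes"),
                        monomer = "", monomer_mM = NA_real_,
                        inhibitor_mM = 0, helper_present = FALSE,
                        temperature_c = 20, motif = "") {
  time_unit <- match.arg(time_unit)
  if (length(time) != length(fraction)) {
    px_input("time and fraction must have equal length")
  }
  if (length(time) < 3) px_input("a time course needs at least 3 points")
  check_nonnegative(time, "time")
  if (any(diff(time) <= 0)) px_input("times must be strictly increasing")
  if (any(!is.finite(fraction)) || any(fraction < 0) ||
      any(fraction > 1.05)) {
    px_input("fractions must lie in [0, 1.05]")
  }
  if (any(fraction > 1)) {
    warning("fractions above 1 present (calibration overshoot)",
            call. = FALSE)
  }
  if (time_unit == "minutes") time <- minutes_to_hours(time)
  structure(
    list(time_h = as.numeric(time), fraction = as.numeric(fraction),
         conditions = list(monomer = monomer, monomer_mM = monomer_mM,
                           inhibitor_mM = inhibitor_mM,
                           helper_present = helper_present,
                           temperature_c = temperature_c, motif = motif)),
    class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf(
    "<time_course> %d points over %.3g h (inhibitor %.3g mM)\n",
    length(x$time_h), max(x$time_h), x$conditions$inhibitor_mM))
  invisible(x)
}

#' Monoexponential fit of an extension time course
#'
#' Least-squares fit of fraction(t) = plateau * (1 - exp(-k_eff t)).
#' The plateau is fixed at 1 by default (complete conversion of free
#' primer-template complex, the assumption behind Kd extraction) or left
#' free in (0, 1.05].
#'
#' @param tc a [time_course].
#' @param plateau_mode `"fixed1"` (default) or `"free"`.
#' @return An object of class `kinetic_fit`: `k_eff` (h^-1), `plateau`,
#'   `residual_rms`, `plateau_mode`, `residuals`.
#' @export
fit_timecourse <- function(tc, plateau_mode = c("fixed1", "free")) {
  plateau_mode <- match.arg(plateau_mode)
  if (!inherits(tc, "time_course")) px_input("`tc` must be a time_course")
  t <- tc$time_h
  y <- tc$fraction
  if (all(y == 0)) px_input("all-zero signal: nothing to fit")
  k0 <- .rate_start(t, y)
  fit <- NULL
  for (mult in c(1, 0.3, 3, 0.1, 10)) {
    fit <- tryCatch(
      if (plateau_mode == "fixed1") {
        minpack.lm::nlsLM(
          y ~ 1 - exp(-k_eff * t),
          start = list(k_eff = k0 * mult), lower = c(k_eff = 0),
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                               ptol = 1e-15))
      } else {
        minpack.lm::nlsLM(
          y ~ plateau * (1 - exp(-k_eff * t)),
          start = list(k_eff = k0 * mult, plateau = min(max(y), 1)),
          lower = c(k_eff = 0, plateau = 1e-6),
          upper = c(k_eff = Inf, plateau = 1.05),
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                               ptol = 1e-15))
      },
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    px_fit_failure(sprintf(
      "time-course fit did not converge (k0=%.3g, mode=%s)",
      k0, plateau_mode))
  }
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  structure(
    list(k_eff = unname(cf["k_eff"]),
         plateau = if (plateau_mode == "fixed1") 1 else unname(cf["plateau"]),
         residual_rms = sqrt(mean(res^2)),
         plateau_mode = plateau_mode,
         residuals = as.numeric(res),
         conditions = tc$conditions),
    class = "kinetic_fit")
}

# crude rate start: time to half-signal, else scale from the last point
.rate_start <- function(t, y) {
  ymax <- max(y)
  i <- which(y >= ymax / 2)[1]
  k0 <- if (!is.na(i) && t[i] > 0) log(2) / t[i] else NA_real_
  if (!is.finite(k0) || k0 <= 0) {
    yl <- min(max(y[length(y)], 1e-3), 0.999)
    k0 <- -log(1 - yl) / t[length(t)]
  }
  k0
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> k_eff %.4g h^-1 (t1/2 %.3g h), plateau %.3g [%s], rms %.2e\n",
    x$k_eff, log(2) / x$k_eff, x$plateau, x$plateau_mode, x$residual_rms))
  invisible(x)
}

#' Effective rate constant under competitive inhibition
#'
#' k_eff = k / (1 + k_inh * inh): the zero-inhibitor pseudo-first-order
#' rate k = k'[M], slowed by the equilibrium sequestration of the
#' primer-template complex by the inhibitor.
#'
#' @param k pseudo-first-order rate at zero inhibitor, h^-1 (>= 0).
#' @param k_inh inhibitor association constant, mM^-1 (>= 0).
#' @param inh inhibitor concentration, mM (>= 0).
#' @return Effective rate in h^-1.
#' @export
predict_keff <- function(k, k_inh, inh) {
  check_nonnegative(k, "k")
  k / inhibition_factor(k_inh, inh)
}

#' Reciprocal-rate linearization across inhibitor concentrations
#'
#' Plots 1/k_eff against inhibitor concentration: a straight line with
#' slope K_inh/k and intercept 1/k, so slope/intercept = K_inh. With few
#' points and strong inhibition the free intercept can carry a large
#' relative error; `intercept_mode = "fixed_at_zero_inh"` pins it to the
#' measured zero-inhibitor rate instead.
#'
#' @param inh inhibitor concentrations, mM.
#' @param k_eff effective rates at each concentration, h^-1 (> 0).
#' @param intercept_mode `"free"` (ordinary least squares, needs >= 3
#'   distinct levels) or `"fixed_at_zero_inh"` (needs a measured
#'   inh = 0 run; >= 2 distinct levels).
#' @return An object of class `inhibition_fit`: `k_inh` (mM^-1), `k`
#'   (h^-1), `kd` (mM), `intercept_mode`, `slope`, `intercept`.
#' @export
fit_inhibition_linear <- function(inh, k_eff,
                                  intercept_mode = c("free",
                                                     "fixed_at_zero_inh")) {
  intercept_mode <- match.arg(intercept_mode)
  if (length(inh) != length(k_eff)) px_input("inh and k_eff lengths differ")
  check_nonnegative(inh, "inh")
  check_positive(k_eff, "k_eff")
  nlev <- length(unique(inh))
  if (nlev < 2) px_input("need >= 2 distinct inhibitor concentrations")
  y <- 1 / k_eff
  if (intercept_mode == "free") {
    if (nlev < 3) {
      px_input("free-intercept mode needs >= 3 distinct inhibitor levels")
    }
    lf <- stats::lm(y ~ inh)
    icpt <- unname(stats::coef(lf)[1])
    slope <- unname(stats::coef(lf)[2])
    if (icpt <= 0) {
      px_fit_failure(paste(
        "fitted intercept is nonpositive; with few points and strong",
        "inhibition use intercept_mode = 'fixed_at_zero_inh'"))
    }
  } else {
    if (!any(inh == 0)) {
      px_input("fixed-intercept mode needs a measured inh = 0 run")
    }
    icpt <- mean(y[inh == 0])
    pos <- inh > 0
    slope <- sum(inh[pos] * (y[pos] - icpt)) / sum(inh[pos]^2)
  }
  k_inh <- slope / icpt
  structure(
    list(k_inh = k_inh, k = 1 / icpt, kd = 1 / k_inh,
         intercept_mode = intercept_mode, slope = slope, intercept = icpt),
    class = "inhibition_fit")
}

#' Global fit of extension time courses across inhibitor levels
#'
#' Fits one shared (k, k_inh) pair simultaneously to every curve under
#' fraction(t) = 1 - exp(-t k / (1 + k_inh inh)). Coincides exactly with
#' the two-stage (per-curve rate, then linearization) estimate on
#' noiseless data.
#'
#' @param tcs list of [time_course] objects spanning >= 2 inhibitor
#'   concentrations with otherwise shared conditions.
#' @return An `inhibition_fit` with an extra `per_curve` data frame of
#'   residual RMS per inhibitor level.
#' @export
fit_inhibition_global <- function(tcs) {
  if (!is.list(tcs) || !all(vapply(tcs, inherits, logical(1), "time_course"))) {
    px_input("`tcs` must be a list of time_course objects")
  }
  inh_lev <- vapply(tcs, function(x) x$conditions$inhibitor_mM, numeric(1))
  if (length(unique(inh_lev)) < 2) {
    px_input("k_inh is unidentifiable: need >= 2 distinct inhibitor levels")
  }
  shared <- lapply(tcs, function(x)
    x$conditions[c("monomer", "monomer_mM", "temperature_c", "motif",
                   "helper_present")])
  if (length(unique(shared)) > 1) {
    px_input("time courses have inconsistent conditions (only inhibitor_mM may vary)")
  }
  t_all <- unlist(lapply(tcs, `[[`, "time_h"))
  y_all <- unlist(lapply(tcs, `[[`, "fraction"))
  inh_all <- rep(inh_lev, vapply(tcs, function(x) length(x$time_h), integer(1)))

  # two-stage start: per-curve rates, then linearization
  ke <- vapply(tcs, function(x) fit_timecourse(x)$k_eff, numeric(1))
  start <- tryCatch({
    f2 <- if (length(unique(inh_lev)) >= 3) {
      fit_inhibition_linear(inh_lev, ke)
    } else {
      fit_inhibition_linear(inh_lev, ke, "fixed_at_zero_inh")
    }
    list(k = f2$k, k_inh = max(f2$k_inh, 1e-6))
  }, error = function(e) list(k = max(ke), k_inh = 0.1))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y_all ~ 1 - exp(-t_all * k / (1 + k_inh * inh_all)),
      start = start, lower = c(k = 0, k_inh = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e)
      px_fit_failure(paste("global inhibition fit failed:",
                           conditionMessage(e))))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  per_curve <- data.frame(
    inhibitor_mM = inh_lev,
    residual_rms = vapply(split(res, inh_all)[as.character(inh_lev)],
                          function(r) sqrt(mean(r^2)), numeric(1)),
    row.names = NULL)
  out <- list(k_inh = unname(cf["k_inh"]), k = unname(cf["k"]),
              kd = 1 / unname(cf["k_inh"]),
              intercept_mode = "global", slope = NA_real_,
              intercept = NA_real_, per_curve = per_curve)
  class(out) <- "inhibition_fit"
  out
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat(sprintf(
    "<inhibition_fit> k %.4g h^-1, K_inh %.4g mM^-1 -> Kd %.4g mM (%s)\n",
    x$k, x$k_inh, x$kd, x$intercept_mode))
  invisible(x)
}

#' Dissociation constant from an inhibition constant
#'
#' @param k_inh association constant, mM^-1 (> 0).
#' @return Kd = 1/k_inh in mM.
#' @export
kd_from_inhibition <- function(k_inh) kinh_to_kd(k_inh)

#' First-order decay fit of intact activated monomer
#'
#' Fits fraction(t) = exp(-k_h t) to a hydrolysis time course; the
#' signal must start near 1 and must not trend upward.
#'
#' @param tc a [time_course] of intact-monomer fraction.
#' @return An object of class `decay_fit`: `k_h` (h^-1),
#'   `halflife_h`, `residual_rms`.
#' @export
fit_decay <- function(tc) {
  if (!inherits(tc, "time_course")) px_input("`tc` must be a time_course")
  t <- tc$time_h
  y <- tc$fraction
  if (y[1] < 0.8) px_input("intact-monomer signal must start near 1")
  if (stats::coef(stats::lm(y ~ t))[2] > 1e-8) {
    px_input("signal increases with time: not a decay")
  }
  # log-linear start where the signal is positive
  pos <- y > 0
  k0 <- if (sum(pos) >= 2) {
    max(-unname(stats::coef(stats::lm(log(y[pos]) ~ t[pos]))[2]), 0)
  } else 1
  if (k0 == 0 && all(abs(y - 1) < 1e-12)) {
    out <- list(k_h = 0, halflife_h = Inf, residual_rms = 0)
    class(out) <- "decay_fit"
    return(out)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ exp(-k_h * t), start = list(k_h = max(k0, 1e-8)),
      lower = c(k_h = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e)
      px_fit_failure(paste("decay fit failed:", conditionMessage(e))))
  kh <- unname(stats::coef(fit)["k_h"])
  res <- stats::resid(fit)
  structure(
    list(k_h = kh, halflife_h = if (kh > 0) log(2) / kh else Inf,
         residual_rms = sqrt(mean(res^2))),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> k_h %.4g h^-1 (t1/2 %.3g h), rms %.2e\n",
              x$k_h, x$halflife_h, x$residual_rms))
  invisible(x)
}
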