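.check_model <- function(model) {
  if (identical(model, c("quadratic", "excess"))) return("quadratic")
  if (length(model) != 1 || !model %in% c("quadratic", "excess")) {
    px_config(sprintf("unknown binding model '%s'",
                      paste(model, collapse = ",")))
  }
  model
}

# NMR shift-titration fitting: single-site binding model for the
# chemical-shift displacement of a reporter proton as nucleotide is
# titrated into a hairpin (primer-template mimic) solution.

#' Construct an NMR titration series
#'
#' @param ligand_mM total ligand (nucleotide) concentrations, mM,
#'   nonnegative and strictly increasing.
#' @param shift_ppm observed chemical shift of the reporter proton, ppm.
#' @param host_mM total host (hairpin) concentration, mM.
#' @param reporter free-text label of the reporter proton.
#' @param temperature_c temperature in degrees Celsius.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(ligand_mM, shift_ppm, host_mM,
                             reporter = "", temperature_c = 20) {
  if (length(ligand_mM) != length(shift_ppm)) {
    px_input("ligand_mM and shift_ppm must have equal length")
  }
  check_nonnegative(ligand_mM, "ligand_mM")
  if (any(diff(ligand_mM) <= 0)) {
    px_input("ligand_mM must be strictly increasing")
  }
  if (any(!is.finite(shift_ppm))) px_input("shifts must be finite")
  check_positive(host_mM, "host_mM")
  structure(
    list(ligand_mM = as.numeric(ligand_mM),
         shift_ppm = as.numeric(shift_ppm),
         host_mM = host_mM, reporter = reporter,
         temperature_c = temperature_c),
    class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series> %d points, host %.3g mM, ligand %.3g-%.4g mM%s\n",
    length(x$ligand_mM), x$host_mM, min(x$ligand_mM), max(x$ligand_mM),
    if (nzchar(x$reporter)) paste0(", reporter ", x$reporter) else ""))
  invisible(x)
}

#' Predicted chemical shift under the single-site binding model
#'
#' shift = delta0 + delta_max * f_bound, with f_bound the occupancy of
#' the host: the ligand-excess isotherm (`"excess"`) or the exact 1:1
#' quadratic solution (`"quadratic"`).
#'
#' @param fit a `titration_fit`, or any list with elements `kd` (mM),
#'   `delta0` (ppm) and `delta_max` (ppm).
#' @param host_total host concentration, mM.
#' @param ligand_total ligand concentration(s), mM.
#' @param model `"quadratic"` (default) or `"excess"`.
#' @return Predicted shift(s) in ppm.
#' @export
predict_shift <- function(fit, host_total, ligand_total,
                          model = c("quadratic", "excess")) {
  if (!all(c("kd", "delta0", "delta_max") %in% names(fit))) {
    px_input("`fit` needs elements kd, delta0, delta_max")
  }
  model <- .check_model(model)
  f <- if (model == "excess") {
    occupancy(fit$kd, ligand_total)
  } else {
    vapply(ligand_total, function(l)
      exact_bound_fraction(fit$kd, host_total, l), numeric(1))
  }
  fit$delta0 + fit$delta_max * f
}

#' Fit the single-site binding model to a shift titration
#'
#' Nonlinear least squares over (kd, delta_max, delta0) on the observed
#' shifts, solved by variable projection: for any kd the shift model is
#' linear in (delta0, delta_max), so those are profiled out exactly and
#' the sum of squares is minimised over kd alone (coarse log-spaced
#' bracket followed by golden-section refinement). This makes the fit
#' exactly invariant to adding a constant to all shifts and to flipping
#' the displacement direction. If the maximal observed displacement is
#' below `saturation_threshold` of the fitted plateau the series is
#' flagged unsaturated, and if in addition the kd standard error is
#' unusable the kd is reported as a lower bound at the largest tested
#' ligand concentration (the "no saturation observed" case).
#'
#' @param series a [titration_series].
#' @param model `"quadratic"` (exact 1:1, default) or `"excess"`.
#' @param saturation_threshold fraction of the fitted plateau the data
#'   must reach to count as saturated (default 0.5).
#' @return An object of class `titration_fit`: `kd` (mM), `delta_max`,
#'   `delta0` (ppm), `residual_rms` (ppm), `saturation_reached`,
#'   `kd_is_lower_bound`, `model`, `residuals`.
#' @export
fit_titration <- function(series, model = c("quadratic", "excess"),
                          saturation_threshold = 0.5) {
  if (!inherits(series, "titration_series")) {
    px_input("`series` must be a titration_series")
  }
  model <- .check_model(model)
  L <- series$ligand_mM
  y <- series$shift_ppm
  if (length(L) < 4) px_input("need at least 4 titration points to fit")
  disp <- y - y[1]
  if (max(abs(disp)) == 0) px_input("shift displacement range is zero")

  H <- series$host_mM
  fb <- function(kd) {
    if (model == "excess") L / (kd + L)
    else vapply(L, function(l) exact_bound_fraction(kd, H, l), numeric(1))
  }
  dfb <- function(kd) {
    if (model == "excess") -L / (kd + L)^2
    else {
      b <- H + L + kd
      sq <- sqrt(b^2 - 4 * H * L)
      ((1 - b / sq) / 2) / H
    }
  }
  # profiled sum of squares: (delta0, delta_max) solved by linear LS
  linfit <- function(kd) stats::lm.fit(cbind(1, fb(kd)), y)
  ss <- function(lkd) sum(linfit(exp(lkd))$residuals^2)
  # envelope theorem: d(profiled SS)/d(kd) at the inner LS optimum
  grad <- function(kd) {
    lf <- linfit(kd)
    -2 * sum(lf$residuals * lf$coefficients[2] * dfb(kd))
  }

  # coarse log bracket around the sampled concentration range
  lmax <- log(max(L))
  grid <- seq(lmax - 16, lmax + 16, length.out = 81)
  ssg <- vapply(grid, ss, numeric(1))
  i <- which.min(ssg)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(ss, c(lo, hi), tol = 1e-10)
  kd_hat <- exp(opt$minimum)
  # polish to gradient-root precision (value-only search stalls at
  # sqrt(machine eps) relative)
  g0 <- grad(kd_hat)
  if (is.finite(g0) && g0 != 0) {
    step <- 1e-6 * kd_hat
    k_lo <- kd_hat; k_hi <- kd_hat
    for (j in 1:60) {
      if (g0 > 0) k_lo <- k_lo - step else k_hi <- k_hi + step
      step <- step * 2
      if (k_lo <= 0) { k_lo <- kd_hat * 1e-8; break }
      if (g0 > 0 && grad(k_lo) < 0) break
      if (g0 < 0 && grad(k_hi) > 0) break
    }
    if (k_lo > 0 && grad(k_lo) < 0 && grad(k_hi) > 0) {
      kd_hat <- stats::uniroot(grad, c(k_lo, k_hi),
                               tol = 1e-14 * kd_hat)$root
    }
  }

  lf <- linfit(kd_hat)
  delta0 <- unname(lf$coefficients[1])
  delta_max <- unname(lf$coefficients[2])
  res <- lf$residuals

  # curvature-based standard error for the lower-bound criterion
  n <- length(y)
  sigma2 <- sum(res^2) / max(n - 3, 1)
  h <- 1e-4
  lkd <- log(kd_hat)
  d2 <- (ss(lkd + h) - 2 * ss(lkd) + ss(lkd - h)) / h^2
  se_kd <- if (is.finite(d2) && d2 > 0) {
    sqrt(2 * sigma2 / d2) * kd_hat  # delta-method back from log scale
  } else NA_real_

  sat <- max(abs(disp)) >= saturation_threshold * abs(delta_max)
  lower_bound <- FALSE
  if (!sat && (!is.finite(se_kd) || se_kd / kd_hat > 1)) {
    lower_bound <- TRUE
    kd_hat <- max(L)
  }
  structure(
    list(kd = kd_hat,
         delta_max = delta_max,
         delta0 = delta0,
         residual_rms = sqrt(mean(res^2)),
         saturation_reached = sat,
         kd_is_lower_bound = lower_bound,
         model = model,
         residuals = as.numeric(res),
         series = series),
    class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf(
    "<titration_fit> Kd %s%.4g mM, delta_max %.4g ppm, delta0 %.4g ppm (%s model)\n",
    if (x$kd_is_lower_bound) ">= " else "", x$kd, x$delta_max, x$delta0,
    x$model))
  cat(sprintf("  residual rms %.2e ppm; saturation %sreached\n",
              x$residual_rms, if (x$saturation_reached) "" else "NOT "))
  invisible(x)
}
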