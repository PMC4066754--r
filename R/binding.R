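# Binding algebra: occupancy isotherms, competitive-site occupancy,
# constant conversions and summary averaging over tabulated constants.
#
# All concentrations are in mM. A dissociation constant Kd describes the
# 1:1 equilibrium between a nucleoside monophosphate and the extension
# site of a primer-template complex (or its hairpin mimic); its reciprocal
# is the association ("inhibition") constant K_inh in mM^-1.

#' Fractional occupancy of the extension site by a ligand in excess
#'
#' Single-site binding isotherm alpha = m / (kd + m), valid when the
#' ligand (nucleotide) is in large excess over the host so that its free
#' concentration equals its total concentration.
#'
#' @param kd dissociation constant, mM (> 0).
#' @param m total ligand concentration, mM (>= 0).
#' @return Occupancy in [0, 1).
#' @examples
#' occupancy(14, 20)   # ~0.59: GMP on an RNA hairpin at 20 mM monomer
#' @export
occupancy <- function(kd, m) {
  check_positive(kd, "kd")
  check_nonnegative(m, "m")
  m / (kd + m)
}

#' Rate-reduction factor caused by a competitive inhibitor
#'
#' The free fraction of primer-template complex in the presence of a
#' non-reactive nucleotide is 1 / (1 + k_inh * inh); this returns the
#' reciprocal slowdown factor 1 + k_inh * inh (>= 1).
#'
#' @param k_inh association constant of the inhibitor, mM^-1 (>= 0).
#' @param inh inhibitor concentration, mM (>= 0).
#' @return Dimensionless factor >= 1 by which the effective rate drops.
#' @examples
#' inhibition_factor(1 / 2, 36)  # Kd = 2 mM, 36 mM inhibitor -> 19
#' @export
inhibition_factor <- function(k_inh, inh) {
  check_nonnegative(k_inh, "k_inh")
  check_nonnegative(inh, "inh")
  1 + k_inh * inh
}

#' Occupancy of a site contested by monomer and inhibitor
#'
#' Equilibrium partition of the extension site between activated monomer
#' (dissociation constant `kd_m`), unactivated inhibitor (`kd_i`) and the
#' free state, both ligands in excess.
#'
#' @param kd_m monomer dissociation constant, mM (> 0).
#' @param kd_i inhibitor dissociation constant, mM (> 0); defaults to
#'   `kd_m` (same affinity for activated and spent monomer).
#' @param m monomer concentration, mM (>= 0).
#' @param inh inhibitor concentration, mM (>= 0).
#' @return An object of class `occupancy_result`: list with `alpha`
#'   (monomer-bound), `fraction_free` and `fraction_inhibitor_bound`,
#'   each in [0, 1] and summing to 1.
#' @examples
#' competitive_occupancy(14, m = 20, inh = 0)$alpha  # reduces to occupancy()
#' @export
competitive_occupancy <- function(kd_m, m, inh, kd_i = kd_m) {
  check_positive(kd_m, "kd_m")
  check_positive(kd_i, "kd_i")
  check_nonnegative(m, "m")
  check_nonnegative(inh, "inh")
  denom <- 1 + m / kd_m + inh / kd_i
  out <- list(
    alpha = (m / kd_m) / denom,
    fraction_free = 1 / denom,
    fraction_inhibitor_bound = (inh / kd_i) / denom
  )
  class(out) <- "occupancy_result"
  out
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf(
    "Extension-site occupancy: monomer %.4f, inhibitor %.4f, free %.4f\n",
    x$alpha, x$fraction_inhibitor_bound, x$fraction_free))
  invisible(x)
}

#' Exact bound fraction of the host from the 1:1 mass-balance quadratic
#'
#' Solves H + L <-> HL without the ligand-excess approximation: the
#' fraction f of host bound satisfies
#' (1 - f) (L - f H) = Kd f. Converges to `occupancy(kd, ligand_total)`
#' as `host_total -> 0`.
#'
#' @param kd dissociation constant, mM (> 0).
#' @param host_total total host (hairpin/duplex) concentration, mM (> 0).
#' @param ligand_total total ligand concentration, mM (>= 0).
#' @return Fraction of host bound, in [0, 1].
#' @export
exact_bound_fraction <- function(kd, host_total, ligand_total) {
  check_positive(kd, "kd")
  check_positive(host_total, "host_total")
  check_nonnegative(ligand_total, "ligand_total")
  b <- host_total + ligand_total + kd
  disc <- b^2 - 4 * host_total * ligand_total
  stopifnot(disc >= 0)  # always true for positive parameters
  hl <- (b - sqrt(disc)) / 2
  f <- hl / host_total
  stopifnot(f >= -1e-12, f <= 1 + 1e-12)
  pmin(pmax(f, 0), 1)
}

#' Convert between dissociation and association constants
#'
#' The association (inhibition) constant is the reciprocal of the
#' dissociation constant; round trips are exact.
#'
#' @param kd dissociation constant, mM (> 0).
#' @param k_inh association constant, mM^-1 (> 0).
#' @return The reciprocal constant.
#' @examples
#' kd_to_kinh(2)    # 0.5 mM^-1
#' kinh_to_kd(0.5)  # 2 mM
#' @export
kd_to_kinh <- function(kd) {
  check_positive(kd, "kd")
  1 / kd
}

#' @rdname kd_to_kinh
#' @export
kinh_to_kd <- function(k_inh) {
  check_positive(k_inh, "k_inh")
  1 / k_inh
}

#' Typical Kd reduction afforded by a downstream-binding helper strand
#'
#' A helper oligonucleotide hybridised immediately downstream of the
#' extension site stacks on the incoming nucleotide and typically
#' tightens binding about 3-fold.
#' @export
helper_kd_factor <- 3

#' Apply or remove the helper-strand correction to a Kd
#'
#' @param kd dissociation constant, mM (> 0).
#' @param direction `"add_helper"` divides by [helper_kd_factor] (binding
#'   tightens), `"remove_helper"` multiplies.
#' @param quiet suppress the informational message.
#' @return Corrected Kd in mM.
#' @export
helper_correct_kd <- function(kd, direction = c("add_helper", "remove_helper"),
                              quiet = FALSE) {
  check_positive(kd, "kd")
  direction <- match.arg(direction)
  out <- if (direction == "add_helper") kd / helper_kd_factor
         else kd * helper_kd_factor
  if (!quiet) {
    message(sprintf("helper-strand correction (%s): Kd %.4g -> %.4g mM (factor %d)",
                    direction, kd, out, helper_kd_factor))
  }
  out
}

#' Packaged dissociation-constant tables
#'
#' Dissociation constants for nucleotides binding to hairpin termini
#' (NMR titrations) and to the extension site of template:primer
#' duplexes (competitive-inhibition kinetics), transcribed from the
#' source study. Censored entries (no saturation observed) carry the
#' largest tested concentration as a lower bound and `censored = TRUE`.
#'
#' @param which `"both"` (default), `"hairpin"` (NMR table) or
#'   `"duplex"` (inhibition table).
#' @return A `binding_records` data frame with columns `nucleotide`,
#'   `templating_base`, `motif`, `helper_present`, `temperature_c`,
#'   `kd_mM`, `censored`, `pairing`, `method`.
#' @export
binding_constants <- function(which = c("both", "hairpin", "duplex")) {
  which <- match.arg(which)
  read_one <- function(f) {
    utils::read.csv(system.file("extdata", f, package = "primext",
                                mustWork = TRUE),
                    stringsAsFactors = FALSE)
  }
  df <- switch(which,
    hairpin = read_one("table1_kd.csv"),
    duplex  = read_one("table2_kd.csv"),
    both    = rbind(read_one("table1_kd.csv"), read_one("table2_kd.csv"))
  )
  class(df) <- c("binding_records", "data.frame")
  df
}

#' Mean dissociation constant over a selection of records
#'
#' Arithmetic mean of Kd for one nucleotide over complementary-pairing,
#' uncensored records at a given temperature — the averaging used to
#' rank global binding strength of the four deoxynucleotides. An
#' alternative mode averages association constants (1/Kd) instead and
#' reports the reciprocal of that mean.
#'
#' @param records a `binding_records` data frame (see
#'   [binding_constants]).
#' @param nucleotide nucleotide identity to select (exact match, so
#'   `"G"` does not include the ribonucleotide `"rG"`).
#' @param temperature_c temperature filter in degrees Celsius.
#' @param pairing pairing classes retained (default complementary only).
#' @param scale `"kd"` (default) averages Kd; `"association"` averages
#'   1/Kd and returns 1/mean.
#' @return Mean Kd in mM.
#' @export
average_kd <- function(records, nucleotide, temperature_c = 20,
                       pairing = "complementary",
                       scale = c("kd", "association")) {
  scale <- match.arg(scale)
  sel <- records$nucleotide == nucleotide &
    records$temperature_c == temperature_c &
    records$pairing %in% pairing &
    !records$censored
  if (!any(sel)) {
    px_input(sprintf(
      "no uncensored records match nucleotide=%s, temperature_c=%s, pairing=%s",
      nucleotide, temperature_c, paste(pairing, collapse = "/")))
  }
  kd <- records$kd_mM[sel]
  if (scale == "kd") mean(kd) else 1 / mean(1 / kd)
}

#' @export
print.binding_records <- function(x, ...) {
  cat(sprintf("<binding_records> %d dissociation constants (%d censored)\n",
              nrow(x), sum(x$censored)))
  NextMethod()
}
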