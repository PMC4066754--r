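# Independent oracles used across tests.

# Brute-force bisection solve of the 1:1 mass balance
# (1 - f) (L - f H) = Kd f for the bound host fraction f in [0, 1].
bisect_bound_fraction <- function(kd, host, ligand, tol = 1e-12) {
  g <- function(f) (1 - f) * (ligand - f * host) - kd * f
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# The reference RNA extension scenario: GMP-OAt on an RNA primer-template
# (Kd 14 mM, 20 mM monomer, k_cov 0.27 h^-1, k_h 0.147 h^-1).
rna_scenario <- function(inh0 = 0, kd_i = 14, k_h = 0.147,
                         times = seq(0, 48, by = 0.5)) {
  yield_scenario(kd_m = 14, m0 = 20, k_cov = 0.27, k_h = k_h,
                 kd_i = kd_i, inh0 = inh0, times = times)
}

# Dissociation constants used as ground truths for recovery tests
# (hairpin NMR table values plus the RNA system).
truth_kds <- c(260, 280, 240, 10, 16, 100, 40, 38, 14)
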