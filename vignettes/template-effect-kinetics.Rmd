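---
title: "Binding, inhibition and yield in enzyme-free primer extension"
author: "primext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding, inhibition and yield in enzyme-free primer extension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primext)
```

## The system and the model

Enzyme-free primer extension couples three elementary processes. An
activated nucleoside monophosphate (the monomer M, typically an
oxyazabenzotriazolide ester) binds reversibly to the templating base of
a primer–template complex P1 with dissociation constant $K_d$; from the
bound state it reacts covalently at rate $k_\mathrm{cov}$ to give the
extended primer P2; and in solution it hydrolyses at rate $k_h$ into an
unactivated nucleotide that still binds the extension site — with the
same or similar affinity — but cannot react. The hydrolysis product is
therefore a competitive inhibitor that the reaction generates against
itself.

All concentrations in this package are millimolar, times are hours and
rates h$^{-1}$; readers accept minutes and convert on input, because
half-lives of the fast amino-terminal assays are naturally quoted in
minutes while hydrolysis and RNA extension run over hours.

### Occupancy

With the monomer in large excess over the primer–template complex
(micromolar complex vs millimolar monomer, the regime of all assays
emulated here), the extension-site occupancy is the single-site
isotherm

$$\alpha = \frac{[\mathrm{M}]_0}{K_d + [\mathrm{M}]_0},$$

implemented in `occupancy()`. When an inhibitor competes for the same
site the three-state partition is

$$\alpha = \frac{[\mathrm{M}]/K_d^{(M)}}
{1 + [\mathrm{M}]/K_d^{(M)} + [\mathrm{Inh}]/K_d^{(I)}},$$

implemented in `competitive_occupancy()`, whose components (monomer
bound, inhibitor bound, free) always sum to one. For NMR titrations,
where up to 1 M nucleotide faces only 0.5 mM hairpin, the ligand-excess
assumption is nearly exact, but `exact_bound_fraction()` provides the
exact 1:1 mass-balance quadratic for completeness and is the default
forward model of the titration fitter.

### Competitive-inhibition kinetics

Extension with monomer in excess is pseudo-first-order,
$k = k'[\mathrm{M}]$. A fast pre-equilibrium with an inhibitor at
association constant $K_\mathrm{Inh} = 1/K_d$ reduces the free complex
by $1/(1 + K_\mathrm{Inh}[\mathrm{Inh}])$, giving

$$k_\mathrm{eff} = \frac{k}{1 + K_\mathrm{Inh}[\mathrm{Inh}]}, \qquad
\frac{1}{k_\mathrm{eff}} = \frac{1}{k} +
\frac{K_\mathrm{Inh}}{k}[\mathrm{Inh}].$$

`fit_inhibition_linear()` implements the reciprocal-rate line
(slope/intercept $= K_\mathrm{Inh}$); `fit_inhibition_global()` fits
one shared $(k, K_\mathrm{Inh})$ pair to all time courses at once. The
two coincide exactly on noiseless data, and in simulation the global
estimator has the smaller variance, which is why it is the
recommendation for real data. This kinetic model deliberately ignores
monomer hydrolysis during the assay — valid for the fast
amino-terminal chemistry whose extension outruns hydrolysis by an
order of magnitude; the coupled treatment lives in the yield model.

### Yield under hydrolysis

Because total nucleotide (activated plus hydrolysed) is conserved at
$[\mathrm{M}]_0 + [\mathrm{Inh}]$ and both species share one $K_d$, the
occupancy denominator is constant in time and the survival of
unreacted primer integrates in closed form:

$$Y_{P2}(t) = 1 - \exp\!\left[
\frac{k_\mathrm{cov}[\mathrm{M}]_0(e^{-k_h t}-1)}
{k_h\,(K_d + [\mathrm{M}]_0 + [\mathrm{Inh}])}\right].$$

Here $[\mathrm{Inh}]$ means inhibitor *added at $t=0$*; the inhibitor
produced by hydrolysis is already accounted for by the
$(e^{-k_h t}-1)$ term. This is the easiest misreading of the formula
and is worth stating twice: do **not** add the hydrolysed monomer to
`inh0`.

`yield_ode()` integrates $\dot P_1 = -k_\mathrm{cov}\,\alpha(t)\,P_1$
with `deSolve::lsoda` (rtol 1e-8, atol 1e-12) under two conventions
for $\alpha(t)$: the *constant-denominator* convention above, which
reproduces the closed form to solver tolerance and is the default when
monomer and inhibitor bind equally; and a *track-species* mode that
uses the time-resolved $M(t) = [\mathrm{M}]_0 e^{-k_h t}$ and
$I(t) = [\mathrm{Inh}]_0 + [\mathrm{M}]_0(1 - e^{-k_h t})$ in the
denominator, which is required when the inhibitor binds with a
different $K_d$. That unequal-affinity case is physically real: a
downstream-binding helper oligonucleotide stacks on the *unactivated*
nucleotide about 3-fold more effectively (`helper_kd_factor`), so
simulations of helper-containing systems use
`kd_i = kd_m / helper_kd_factor`. The dispatch is automatic
(`denominator = "auto"`) and recorded in the curve's provenance field.

The plateau $t \to \infty$,
$1 - \exp[-k_\mathrm{cov}[\mathrm{M}]_0 / (k_h(K_d + [\mathrm{M}]_0 +
[\mathrm{Inh}]))]$, is exposed as `plateau_yield()`. With $k_h = 0$
completion is eventual and the plateau is reported as 1 with a flag.
Below $k_h = 10^{-9}\,\mathrm{h}^{-1}$ the closed form switches to the
analytic no-hydrolysis limit to avoid 0/0 cancellation; the two
branches agree to 1e-6 at the switch point.

```{r}
s <- yield_scenario(kd_m = 14, m0 = 20, k_cov = 0.27, k_h = 0.147)
plateau_yield(s)
max(abs(yield_ode(s)$yields - yield_closed_form(s)))
```

The `conc_scale` parameter multiplies the nominal monomer
concentration by a factor in (0, 1], modelling loss of reactive
species (e.g. to side reactions with trace impurities at very low
monomer concentration); it scales $[\mathrm{M}]_0$ everywhere it
appears, including the conserved denominator.

## Fitting choices

**Titration fits.** The shift model
$\delta = \delta_0 + \Delta\delta_\mathrm{max} f_\mathrm{bound}(K_d)$
is linear in $(\delta_0, \Delta\delta_\mathrm{max})$, so
`fit_titration()` uses variable projection: the linear pair is solved
exactly for each candidate $K_d$ and the profiled sum of squares is
minimised over $K_d$ alone — an 81-point log-spaced bracket spanning
$e^{\pm 16}$ times the top ligand concentration, golden-section
refinement, then a root polish on the analytic profile gradient. This
outperforms a joint 3-parameter Levenberg–Marquardt fit in two ways
that matter here: recovery on noiseless data is exact to ~1e-13
relative rather than ~1e-7 (a numeric-gradient floor), and the fit is
invariant under shift offset and displacement-sign flips to machine
precision, as it should be since those transformations leave the
profile objective unchanged. Ordinary (unweighted) least squares is
used, matching conventional shift-titration practice.

The default forward model is the exact quadratic, which is never
worse; the `"excess"` mode reproduces the conventional analysis. The
two disagree on $K_d$ by at most roughly the bound-host concentration
(≤ 0.5 mM at the 0.5 mM hairpin concentration of the emulated assays)
— negligible for weak binders but about 2% at $K_d = 10$ mM, which is
why the quadratic is the default rather than a refinement.

A titration is flagged unsaturated when the largest observed
displacement is below half the fitted plateau (threshold
configurable); if additionally the curvature-based standard error on
$K_d$ exceeds the estimate itself, $K_d$ is reported as a lower bound
at the largest tested concentration — the behaviour of a mismatched
nucleotide that shows no saturation at 1 M.

**Kinetic fits.** `fit_timecourse()` defaults to a plateau fixed at 1,
because the $K_d$-extraction model assumes complete conversion of free
complex; a free-plateau mode (bounded by 1.05 to tolerate calibration
overshoot in quantitative MALDI data) exists for visibly incomplete
curves and the mode is recorded in the output. Rates are started from
the time-to-half-signal and refined by bounded Levenberg–Marquardt.
The linearization is unweighted on the $1/k_\mathrm{eff}$ scale; when
the extrapolated intercept comes out nonpositive (few points, strong
inhibition) the error message directs the user to the fixed-intercept
mode, which pins the intercept to the measured zero-inhibitor rate.

## The synthetic-data generators

Every fitter has a paired generator (`gen_titration`,
`gen_inhibitor_series`, `gen_yield_course`, `gen_decay`) whose forward
model is the package's own prediction function, so
generator/fitter round trips are exact at zero noise. The emulated
designs follow the assays: titrations run 0–774 mM ligand in two-fold
steps at 0.5 mM host; inhibitor series use 0/1/5/10 equivalents of a
3.6 mM monomer (0, 3.6, 18, 36 mM); hydrolysis decays span a day.

The noise model is additive iid Gaussian on the observed quantity
(shift or fraction), with defaults of 0.002 ppm and 0.02 fraction.
These magnitudes are declared, not derived from data — the assays
publish no error model — and were chosen as what a 500 MHz titration
and quantitative MALDI calibration typically deliver. Fractions are
clipped to [0, 1.05]. What the generators deliberately do *not*
emulate: heteroscedasticity, baseline drift, exchange broadening at
high ligand, biphasic kinetics of amino-terminal primers at low
monomer, or correlated errors within a titration. Passing recovery
tests therefore demonstrate estimator correctness and precision under
the stated error model, not robustness to these real-data pathologies.

Recovery envelopes under noise were calibrated by simulation (200
replicates at fixed seeds): titration $K_d$ lands within 15% of truth
in ≥ 90% of replicates at 0.002 ppm noise, and the two-stage
$K_\mathrm{Inh}$ within 20% in ≥ 90% at 0.02 fraction noise, with the
global estimator tighter still. The test suite re-runs these
calibrations; they complete in seconds because each replicate is a
few small least-squares problems.

## Averaging and the constant tables

`binding_constants()` loads the transcribed dissociation-constant
tables; `average_kd()` reproduces the global per-nucleotide binding
strengths as the arithmetic mean of $K_d$ over uncensored,
complementary-pairing records at one temperature. Two choices were
genuinely open and are resolved as follows. First, averaging is done
on the $K_d$ scale, not the association-constant scale: the $K_d$-mean
yields a T:G strength ratio of ≈ 18-fold, consistent with the reported
summary, while association-constant averaging gives ≈ 20; the
alternative remains available via `scale = "association"`. Second,
wobble and mismatch entries are excluded from means even where a
caption's entry count might suggest otherwise, because the summary is
defined for complementary pairs; censored bounds ("no saturation up to
1 M") are stored as bounds and never averaged. The ribonucleotide
entry is likewise excluded from the deoxynucleotide means by exact
nucleotide matching (`"G"` ≠ `"rG"`).

## Numerical and interface conventions

* Degenerate inputs fail fast with classed conditions
  (`primext_domain_error`, `primext_input_error`,
  `primext_config_error`, `primext_fit_error`); the CLI maps them to
  exit codes 2 and 3.
* CSV dialect: comma-separated, header mandatory, units in column
  names (`time_h`/`time_min`, `shift_ppm`, `*_mM`). Sidecar metadata
  travels in a YAML file next to the CSV. Writers round-trip
  losslessly.
* Generators are deterministic under a seed and restore the caller's
  RNG state.
* Problem sizes in the shipped tests: 1000-draw property sweeps for
  the algebraic invariants, 50-draw pipeline round trips, 200-replicate
  Monte-Carlo calibrations, yield grids of ~100 points — sizes at
  which every property is measured comfortably and the whole suite
  runs in well under a minute.

## Known limitations

* The kinetic model assumes monoexponential extension; biphasic
  kinetics of amino-terminal primers at very low monomer concentration
  are out of scope, as is any fidelity/mismatch-stalling model beyond
  the tabulated wobble and mismatch constants.
* The yield model treats the primer as stably bound to its template;
  strand separation and full replication cycles are not modelled.
* The track-species ODE mode is a model generalization for the
  unequal-affinity case, not a reproduction of any more elaborate
  published treatment; for equal affinities it is validated against
  the closed form, for unequal affinities only qualitative orderings
  (inhibitor always lowers yield, tighter inhibitor lowers it more)
  are asserted.
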