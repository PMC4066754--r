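# primext

Quantitative modelling of enzyme-free, template-directed primer
extension — the copying chemistry in which an activated nucleoside
monophosphate binds the templating base of a primer–template complex by
Watson–Crick pairing alone and is ligated to the primer without a
polymerase.

The package is for chemists and origin-of-life researchers who measure
or model this reaction. It answers three linked questions:

1. **How strongly does a nucleotide bind the extension site?**
   Dissociation constants `Kd` are extracted from NMR chemical-shift
   titrations (single-site isotherm, exact 1:1 quadratic or
   ligand-excess forms) and from the inhibitory effect of unactivated
   nucleotides on extension kinetics.
2. **How occupied is the site at a given monomer concentration?**
   Occupancy isotherms `alpha = [M]0 / (Kd + [M]0)`, including
   three-state competition between activated monomer and inhibitor.
3. **What yield will an extension reach before hydrolysis destroys the
   monomer?** The closed-form yield under concurrent first-order
   monomer hydrolysis,

   ```
   Y(t) = 1 - exp[ k_cov [M]0 (exp(-k_h t) - 1) / (k_h (Kd + [M]0 + [Inh])) ]
   ```

   plus an adaptive-ODE generalization that allows the inhibitor a
   different affinity than the monomer (the helper-strand case).

The competitive-inhibition analysis follows the pseudo-first-order
model: extension at rate `k = k'[M]` is slowed to
`k_eff = k / (1 + K_Inh [Inh])`, so `1/k_eff` is linear in `[Inh]` with
slope/intercept `= K_Inh = 1/Kd`. Both the two-stage (per-curve rate,
then linearization) and global estimators are provided, together with
synthetic-data generators that close the loop on every fitter.

Transcribed dissociation-constant tables for nucleotides binding
hairpin termini and template:primer duplexes ship in
`inst/extdata/` and load via `binding_constants()`.

## Worked example: the RNA extension system

GMP-OAt extending an RNA primer (Kd = 14 mM, 20 mM monomer,
k_cov = 0.27 h⁻¹, hydrolysis k_h = 0.147 h⁻¹):

```r
library(primext)

alpha <- occupancy(kd = 14, m = 20)
round(alpha, 2)
#> [1] 0.59

kcov_from_rate(k = 0.16, alpha = alpha)   # early-time rate -> covalent rate
#> [1] 0.272

s <- yield_scenario(kd_m = 14, m0 = 20, k_cov = 0.27, k_h = 0.147)
plateau_yield(s)
#> [1] 0.6605512
```

59% of extension sites are occupied, the covalent step runs at
0.27 h⁻¹ from the bound state, and — because hydrolysis converts
monomer into a competing inhibitor at a comparable rate — the reaction
plateaus at 66% yield rather than running to completion. Added
unactivated nucleotide lowers this further:

```r
plateau_yield(yield_scenario(kd_m = 14, m0 = 20, k_cov = 0.27,
                             k_h = 0.147, inh0 = 20))
#> [1] 0.4935208
```

A command-line surface (`exec/primext`) exposes the same operations as
`fit-titration`, `fit-inhibition`, `fit-decay`, `simulate-yield`,
`generate` and `report` subcommands, e.g.

```sh
Rscript exec/primext simulate-yield --kd 14 --m0 20 --kcov 0.27 \
    --kh 0.147 --sweep "inh0=0,5,20" --out curves.csv
```

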