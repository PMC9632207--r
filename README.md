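# solvbind

Binding thermodynamics and inhibition kinetics for enzyme–ligand
systems, built around the extended solvation model of isothermal
titration calorimetry (ITC) heats. The motivating system is the
inhibition of jack bean urease (E.C. 3.5.1.5) by the flavonol
kaempferol, but every estimator is generic.

## What it computes

**Extended solvation model.** Per-injection ITC heats are modelled
through the cooperative bound fraction
`xB' = p·xB/(xA + p·xB)` (cooperativity parameter `p`; `p > 1` means
positive cooperativity) as

```
q = q_max·xB' − (δA·xA' + δB·xB')·(xA'·LA + xB'·LB)
```

with saturation heat `q_max`, solvation indices `δA`, `δB`, and
relative partial molar dilution enthalpies `LA`, `LB` obtained from a
dilution series by the tangent construction. `fit_solvation()`
estimates `(p, q_max, δA, δB)` by profiled least squares (the model is
linear given `p`) with multi-start 1-D optimisation.

**Two-region Hill analysis.** `split_regions()` + `fit_hill()` fit
`q = q_max·Lⁿ/(Kdⁿ + Lⁿ)` in the low- and high-concentration regions,
reporting the Hill coefficient `n`, `Ka = 1/Kd`, and the derived
thermodynamics `ΔG = −RT·ln(Ka)`, `TΔS = ΔH − ΔG`
(R = 8.314 J·mol⁻¹·K⁻¹, T = 300 K for ITC quantities).

**Inhibition kinetics.** `lineweaver_burk()` diagnostics,
`classify_mechanism()` (competitive / noncompetitive / uncompetitive /
mixed, or `indeterminate`), `fit_inhibition()` — global nonlinear least
squares on untransformed velocities with a secondary-plot Ki
cross-check — plus `estimate_ic50()` (two-parameter logistic) and
`reversibility_check()`.

**Energy bookkeeping.** `ki_from_energy()`/`energy_from_ki()`
(docking convention, `Ki = exp(ΔG/RT)` at 298.15 K),
`sum_components()` for MM-PBSA decompositions with the residual
against a reported total surfaced explicitly, and `compare_methods()`
to place ITC, docking and MM-PBSA ΔG values on one kJ/mol scale.

**Synthetic data.** `simulate_titration()`, `simulate_dilution()`,
`simulate_hill_series()`, `simulate_kinetics()` and
`simulate_dose_response()` generate every input class with known
ground truth, seeded noise, and truth sidecars — the basis of the
package's parameter-recovery tests.

## Worked example

```r
library(solvbind)

design <- titration_design()           # 8000 µmol/L into 5 µmol/L, 30 inj., 300 K
truth  <- solvation_parameters(p = 1.2, q_max = 50,
                               delta_A = -0.23, delta_B = -0.17)
series <- simulate_titration(design, truth, dilution_coef = c(-20, 40, -30))
fit    <- fit_solvation(series)
coef(fit)
#>       p   q_max delta_A delta_B
#>    1.20   50.00   -0.23   -0.17

thermodynamics(Ka = 253009, dH = 5.16, temperature = 300)
#> Binding thermodynamics at 300 K
#>   Ka  = 253009 L/mol
#>   dH  =    5.160 kJ/mol
#>   dG  =  -31.031 kJ/mol
#>   TdS =   36.191 kJ/mol   (TdS = dH - dG)

kin <- simulate_kinetics(kinetics_design(), "noncompetitive",
                         Vmax = 1, Km = 3, Ki = 6.06)
fit_inhibition(kin, mechanism = "auto")
#> Reversible inhibition fit
#>   mechanism: noncompetitive
#>   Vmax = 1,  Km = 3 mM
#>   Ki   = 6.06 uM (global fit)
#>   Ki   = 6.06 uM (secondary plot)
#>   residual norm: 3.249e-16; converged: TRUE
```

The refit recovers the generating parameters exactly on noise-free
data: the cooperativity parameter `p = 1.2` classifies the binding as
positively cooperative, the negative solvation indices indicate minor
structural rearrangement, ΔG < 0 with TΔS > 0 marks spontaneous,
entropy-driven (hydrophobic) binding, and the kinetic fit classifies a
noncompetitive mechanism (Km unchanged, Vmax reduced) with
Ki = 6.06 µM.

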