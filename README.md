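# perfusim

Simulation and design of 3D stem-cell expansion cultures in perfusion
bioreactors.

Mesenchymal stromal cells expanded on porous scaffolds under perfusion
secrete extracellular matrix (ECM) as they proliferate; the matrix
protects their potency but makes harvest hard, and growth factors that
favor proliferation over matrix deposition are the costliest medium
component. `perfusim` is for bioprocess engineers and computational
biologists who want to ask, before running a month-long culture: *which
medium refreshment schedule and growth-factor dose give the most cells
for the least money?*

## The model

A homogenized (space-independent) six-variable ODE system: oxygen,
glucose and lactate concentrations C₀, C_g, C_la, ECM and cell volume
fractions V_ECM, V_Cell of the available pore space V_T, and
growth-factor concentration gf. Growth of both tissue fractions is gated
by a shared modulator product

    P = f_s(τ) · f_c(κ) · h₁(C_o) · h₂(C_g) · h₃(pH)

(piecewise shear response, linear curvature response, Michaelis–Menten
nutrient saturations, piecewise pH penalty with pH = 7.4 − 0.0406·C_la),
and the tissue balances are

    dV_ECM/dt  = A₁ P V_Cell (V_T − V_Cell − V_ECM) · α₁/(1 + gf)
    dV_Cell/dt = A₂ P V_Cell V_ECM (V_T − V_Cell − V_ECM) · α₂ gf/(α₃ + gf)
    dgf/dt     = −λ gf                     (half-life 1.5 h)

so cell growth requires ECM (a lag phase), both stop at the carrying
capacity, and the growth factor boosts proliferation while suppressing
matrix deposition. Medium refreshment is an instantaneous event every
period p: glucose, lactate and growth factor jump to the weighted average
(1−a)·current + a·fresh; dissolved oxygen is untouched. On top of the
simulator sit a genetic-algorithm calibrator (with a synthetic-observation
generator for parameter-recovery testing), an anchor-based normalization
of the lumped rate scales, an experiment cost model

    C = (M + gf₀·P_g)(1 + (24d/p)·a) + L(1 + 24d/p),

an external-archive multi-objective particle swarm optimizer over
(period, fraction, dose), and knee-point selection on the Pareto front.
The methods vignette (`vignettes/perfusion-culture-model.Rmd`) documents
every equation, default and design choice.

## A worked example

```r
library(perfusim)

ref <- reference_configuration()          # anchored parameter set
traj <- simulate_culture(ref$params,
                         regime = refreshment_regime(12, 0.65, 28),
                         medium = medium_spec(gf0 = 7))
tail(traj, 1)[, c("time_h", "V_cell", "cells", "Cg", "pH")]
#>     time_h    V_cell   cells      Cg  pH
#> 728    672 0.7875511 5665835 24.9997 7.4
experiment_cost(12, 0.65, 7)
#> [1] 492.1367
```

Refreshing 65% of the medium every 12 h at a 7 ng/ml growth-factor dose
fills 78.8% of the scaffold pore space with cells (about 5.7 million
cells) after 28 days, at a total cost of 492 € — against 9.6% fill
(6.9×10⁵ cells) for the baseline schedule of a full exchange every 48 h
at the 1 ng/ml baseline dose. The fill plateau just below 79% is the
flow-induced shear ceiling of the default geometry closures.

`optimize_regimen()` maps the whole yield-versus-cost trade-off and
`knee_point()` marks the sweet spot; `scenario_preset()` bundles the
published validation scenarios (static 120 h/50% culture, 55 h/100%
perfusion, and the six dose-by-schedule prediction runs). A thin CLI over
the same functions lives at `inst/cli/perfusim.R`
(`simulate | calibrate | optimize | cost | presets`).

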