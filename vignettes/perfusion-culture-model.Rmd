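---
title: "Modelling cell expansion and matrix production in a perfused scaffold"
author: "perfusim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cell expansion and matrix production in a perfused scaffold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfusim)
```

## The problem

Expanding mesenchymal stromal cells on 3D porous scaffolds in a perfusion
bioreactor preserves their potency better than flask culture, but the cells
secrete extracellular matrix (ECM) as they grow, and a matrix-entombed
population is hard to harvest. Medium composition — in particular growth
factors that push proliferation over matrix deposition — and the medium
refreshment schedule are the main levers an experimenter has. `perfusim`
implements a homogenized (space-independent) model of this culture system,
plus the machinery to calibrate it against observed time courses and to
optimize the refreshment regimen against experiment cost.

## The model

Six quantities evolve in time: oxygen, glucose and lactate concentrations
$C_o$, $C_g$, $C_{la}$ (mol/m$^3$), the ECM and cell volume fractions
$V_{ECM}$, $V_{Cell}$ (of the available pore space, normalized to
$V_T = 1$), and the growth-factor concentration $gf$ (ng/ml). pH is
derived from lactate: $\mathrm{pH} = 7.4 - 0.0406\,C_{la}$.

Growth of both tissue fractions is gated by a shared modulator product

$$P = f_s(\tau)\; f_c(\kappa)\; h_1(C_o)\; h_2(C_g)\; h_3(\mathrm{pH})$$

with a piecewise-linear shear response $f_s$ (half-speed at zero shear, an
optimal plateau on $[a_1, a_2)$, linear decline to zero at the detrimental
threshold $a_3$), a linear curvature response $f_c(\kappa) = \max(\kappa, 0)$,
Michaelis–Menten nutrient saturations $h_1, h_2$, and a piecewise pH
penalty $h_3$ (1 above pH 7.1, 0 at or below pH 6.375, the ramp
$\tfrac{4}{3}\mathrm{pH} - 8.5$ in between). The balances are

$$\frac{dV_{ECM}}{dt} = A_1 P\, V_{Cell} (V_T - V_{Cell} - V_{ECM})
  \frac{\alpha_1}{1 + gf},$$
$$\frac{dV_{Cell}}{dt} = A_2 P\, V_{Cell} V_{ECM} (V_T - V_{Cell} - V_{ECM})
  \frac{\alpha_2\, gf}{\alpha_3 + gf},$$

so cell growth needs ECM (the observed lag phase), both stall when the
scaffold is full, and the growth factor differentially boosts
proliferation (saturating gain, ceiling $\alpha_2$, half-saturation
$\alpha_3$) while attenuating matrix deposition ($\alpha_1/(1+gf)$). The
species balances consume oxygen and glucose and produce two lactate per
glucose, all proportional to the filled fraction
$V_{fill} = V_{Cell} + V_{ECM}$; the growth factor decays first-order with
a 1.5 h half-life ($\lambda = \ln 2 / 5400\ \mathrm{s}^{-1}$).

Medium refreshment is an instantaneous event: every period $p$ a fraction
$a$ of the reservoir is replaced, so glucose, lactate and growth factor
jump to the weighted average $(1-a)\,x + a\,x_{\mathrm{fresh}}$. Dissolved
oxygen is left untouched (the physical set-up exchanges oxygen with the
environment continuously, so a medium swap does not move it), and an
exchange that would fall at the final instant of culture is skipped — it
could not influence any outcome.

## Geometry closures

The spatially resolved ancestor of this model evaluates curvature and wall
shear on the actual neotissue interface. The homogenized model needs
closures in the filled fraction, and the published account does not print
them, so `perfusim` supplies defaults modelled on a shrinking cylindrical
pore and declares them injectable (`environment_model()`):

* $\kappa(V_{fill}) = \sqrt{(1 - V_0)/(1 - V_{fill})}$, normalized to 1 at
  the seeded fraction $V_0 = 0.0139$;
* $\tau(V_{fill}, Q) = \tau_0 \,(Q/Q_{ref})\,((1 - V_0)/(1 - V_{fill}))^{1.5}$
  with $\tau_0 = 0.005$ Pa and $Q_{ref} = 0.04$ ml/min — Poiseuille
  wall-shear scaling that starts in the sub-optimal branch of $f_s$ at the
  reference low flow rate and rises as the pores fill.

A consequence worth knowing: at $Q = 0.04$ ml/min the shear response
reaches the detrimental threshold at a filled fraction of about 0.79, so
the model never fills the scaffold completely; predicted fills in the
high-growth regimens cluster just below 79%. Static culture ($Q = 0$)
pins $\tau = 0$ and hence $f_s = 0.5$ throughout.

## Units and the anchored rate scale

The published constants mix genuinely per-second quantities (cell-specific
uptake rates $V_o$, $V_g$; the decay rate $\lambda$) with lumped scales
($A_1$, $A_2$, $\beta_1$, $\beta_2$) whose implied time base is not
dimensionally consistent under seconds. Rather than silently reinterpret
them, the package keeps all published values as written and adds one
dimensionless multiplier, `rate_scale`, applied to the four lumped scales
and to the stoichiometrically coupled lactate production term. Applying it
to the lactate term as well keeps the printed identity
$dC_{la}/dt = -(2/\beta_2)\, dC_g/dt$ true for any rescale, with $\beta_2$
the published value.

The multiplier is pinned by a one-dimensional root find
(`normalize_reference_configuration()`): under the baseline regimen (full
exchange every 48 h, $gf_0 = 1$ ng/ml, 28 days) the day-28 cell count must
equal the observed $6.9\times10^5$ cells within 0.1%. Cell count and
volume fraction are interconvertible through the seeding condition
($1.39\% \leftrightarrow 10^5$ cells; one cell is a 20 µm sphere,
$4.2\times10^3$ µm$^3$). The anchored value, about $6.84\times10^{-12}$,
ships as a versioned fixture (`inst/extdata/reference_config.yaml`) and is
re-derived from scratch by the acceptance script and tests. At that scale
the species balances are slow compared to the refreshment period, so the
regimen acts on growth mainly through growth-factor resupply and the
geometry closures — the nutrient, lactate and pH terms are retained for
structural fidelity and become active only at much larger rate scales.

## Numerical choices

Integration uses `deSolve::ode` (lsoda, stiff-capable), relative tolerance
$10^{-8}$, absolute $10^{-10}$, all configurable. Each refreshment is a
hard restart of the integrator; the pre- and post-event states are both
recorded at the event timestamp. Output is sampled hourly by default, plus
all event times. Round-off excursions below zero are clamped only within
integrator working precision (below $100 \times$ the absolute tolerance);
anything worse aborts the run. The integrator's inlined right-hand side is
pinned to the exported reference implementation (`state_derivative()`) by
tests, and the adaptive solution is cross-checked against an independent
fixed-step classical Runge–Kutta oracle at 1 s steps.

## Calibration

`residual_objective()` measures the distance between a candidate parameter
set and observed cell/ECM time courses as a sum of squared residuals,
each channel normalized by its maximum observation so the small ECM
fractions are not drowned out by the cell channel; missing observations
contribute nothing; a failed simulation returns a large finite penalty so
population-based search can continue.

The optimizer is a real-coded genetic algorithm (`ga_calibrate()`):
tournament selection (size 3), blend crossover (rate 0.9, expansion 0.5),
Gaussian mutation (rate 0.1, scale 10% of bound width), elitism 1,
population 50 over 100 generations by default — unremarkable, deliberately
standard settings, all exposed in `ga_config()` and reproducible from one
seed.

One structural fact shapes how recovery experiments must be read: the
fitted constants enter the dynamics only through the products
$A_1 \alpha_1$ and $A_2 \alpha_2$ (plus $\alpha_3$ through the shape of
the dose response), so the five parameters are not individually
identifiable from a single trajectory — the likelihood is flat along a
two-dimensional ridge. Parameter-recovery tests therefore run with tight
bounds (±10% around the generating values) and additionally assert the
identifiable combinations; with zero noise the products are recovered to
a few percent, and recovery error grows with observation noise. The
synthetic-observation generator (`synthesize_observations()`) samples the
simulator at requested times and adds independent Gaussian noise
truncated at zero; it emulates sampling variability only — not systematic
assay bias, attachment losses at seeding, or donor-to-donor variation —
so passing recovery tests demonstrate the estimation machinery, not field
performance on real assays.

Recovery fixtures use a deliberately brisk synthetic truth
(`rate_scale` $= 3\times10^{-11}$, 4-day cultures refreshed daily at a
5 ng/ml dose) so that a short simulated experiment carries a clear growth
signal; test problem sizes (populations of 10–24 over 6–30 generations,
eight to twelve observation times) were chosen as the smallest designs
that exercise the machinery convincingly.

## Cost model and regimen optimization

The cost of a culture is
$C = (M + gf_0 P_g)(1 + \tfrac{24 d}{p} a) + L (1 + \tfrac{24 d}{p})$
with $M = 0.2611$ € of medium per full exchange, $L = 6.8$ € of labor per
refreshment, and $P_g$ the growth-factor price per ng/ml dose per 10 ml
reservoir. Consumables scale with the exchanged fraction, labor does not,
and the `+1` terms are the initial fill and set-up. $P_g$ is not a
published number; the default 0.362 € is back-solved from the two
published (regimen, cost) pairs — 492 € at (12 h, 65%, dose 7) and
1411 € at (7 h, 40%, dose 50) — which one consistent price reproduces to
within 2.5%.

`optimize_regimen()` searches (period 4–96 h, fraction 0.05–1, dose
1–100 ng/ml) with an external-archive multi-objective particle swarm
(inertia 0.7, cognitive/social 1.5/1.5, velocity clamp 20% of bound
width, reflection at bounds, crowding-distance leader selection and
archive truncation; 100 particles, 50 iterations by default). The final
cell volume fraction is maximized against total cost minimized. On the
resulting front, `knee_point()` selects the sweet spot: after min–max
normalization of both objectives, the point farthest from the segment
joining the front extremes; collinear fronts are flagged degenerate, and
fronts shorter than three points fall back to the cheapest member with a
warning. Whether the published study's swarm used an archive or repeated
scalarizations is not stated; the archive variant was chosen as the
standard citable formulation.

## Design choices where the source was ambiguous

* The declining branch of the shear response is implemented as
  $(a_3 - \tau)/(a_3 - a_2)$ — the printed form has an inverted sign; this
  one is 1 at $a_2$, 0 at $a_3$, and matches the stated biology.
* The pH ramp's printed domain is garbled; it is read as
  $6.375 \le \mathrm{pH} < 7.1$, with outputs clipped to $[0,1]$ to guard
  the 0.967-to-1 jump at 7.1 under floating point.
* The species balances are driven by the total filled fraction
  $V_{fill} = V_{Cell} + V_{ECM}$ (cells within neotissue consume
  regardless of compartment); driving them by $V_{Cell}$ alone is a
  one-line change in `state_derivative()`.
* $A_1$ and $A_2$ may be zero (growth switched off, a useful degenerate
  test case) even though every other constant must be strictly positive.
* Refreshment events falling exactly at the end of culture are skipped;
  the event count over $d$ days at period $p$ is otherwise
  $\lfloor 24 d / p \rfloor$.

## Known limitations

The model is space-independent: curvature and shear enter through scalar
closures, not through the actual evolving pore geometry, and the two
predictive regimen checks inherit the closure reconstruction — they are
verified to the published values within 15 percentage points, not to
curve-shape fidelity. Oxygen has no resupply term (as in the source
system, which leaks oxygen continuously, the exchange events do not touch
it); do not use the oxygen trace quantitatively. The growth-factor
equations are calibrated against a single historic data set and are
structurally non-identifiable at the individual-parameter level, as
discussed above. Costs ignore tubing dead volume and multi-scaffold
parallelism.

## A worked example

```{r example, eval = FALSE}
library(perfusim)

ref <- reference_configuration()
traj <- simulate_culture(ref$params, regime = refreshment_regime(12, 0.65, 28),
                         medium = medium_spec(gf0 = 7))
tail(traj, 1)[, c("time_h", "V_cell", "cells", "Cg", "pH")]
experiment_cost(12, 0.65, 7)
```
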