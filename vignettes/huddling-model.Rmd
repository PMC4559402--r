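---
title: "A self-organising model of thermoregulatory huddling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A self-organising model of thermoregulatory huddling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huddlesim)
```

## The model

Newborn rodents huddle: below a critical ambient temperature a litter
collapses into a dense aggregate, and within the aggregate individuals
continually exchange places between the warm centre and the cool periphery
("pup flow"). `huddlesim` implements an agent-based model in which both
behaviours emerge from strictly local interactions, together with the
group-level metrics used to quantify them and a closed-form "super-organism"
description of the litter.

Each pup is a circle of radius $r$ (the unit of length) moving in a circular
arena of radius $10r$. Its state is a position $\mathbf{x}_i$, a heading
$\theta_i$ and a body temperature $T_{b_i}$. The body surface carries $n$
evenly spaced thermometers at angular offsets $(k - \tfrac12)\,2\pi/n$ from
the heading, the first $n/2$ on the left side. A thermometer registers
contact with littermate $j$ when the bodies overlap ($d_{ij} \le 2r$) and
the thermometer's angle lies within $\cos^{-1}(d_{ij}/2r)$ of the bearing of
$j$; for equal radii this is exactly the point-in-disc test, which the test
suite verifies on randomised configurations. Exposure flags
$\epsilon_{ik} = \prod_j (1 - \alpha_{ijk})$ give the exposed fraction
$\eta_i$, and a contacted thermometer registers the body temperature of the
nearest contacting littermate, $\chi_{ik}$.

Five steps are applied synchronously to all pups on each timestep:

1. **Sensing.** $\tau_{ik} = T_a\,\epsilon_{ik} + s\,\chi_{ik}$ (plus
   optional Gaussian sensor noise), averaged over each half of the body to
   give $T_{L_i}$, $T_{R_i}$.
2. **Motor drives.** Contralateral wiring normalised to a unit sum:
   $M_{L_i} = F(T_{R_i}) / (F(T_{L_i}) + F(T_{R_i}))$ and symmetrically for
   $M_R$.
3. **Orientation.** $\Delta\theta_i = \mathrm{d}t \cdot
   \arctan\!\big(v_1 (M_{R_i} - M_{L_i})\big)$, so a pup whose right side is
   warmer ($M_L > M_R$) turns clockwise, toward the warmth. The increment is
   bounded by $\mathrm{d}t\,\pi/2$.
4. **Translation.** Constant speed $v_2$ along the heading, an inward
   boundary force $\beta_i \mathbf{x}_i / |\mathbf{x}_i|$ with $\beta_i =
   r_{\text{arena}} - |\mathbf{x}_i| - r \le 0$ at the wall, and a collision
   spring $(r - d_{ij}/2)$ pushing directly apart from every overlapping
   littermate. Transient overlaps are permitted; there is no iterative
   constraint solver.
5. **Thermodynamics.** Forward Euler on
   $\dot T_{b_i} = -k_1 \eta_i (T_{b_i} - T_a)
   - k_2 (1 - \eta_i)(T_{b_i} - T_{c_i}) + G$,
   where $T_{c_i}$ is the mean of $\chi$ over contacted thermometers.

Three variants differ only in steps 2 and 5. The **endothermic** variant
clamps $T_b = 37$°C and uses the identity transfer $F(T) = T$: pups turn
toward heat when the contact temperature exceeds ambient and away above it,
producing a sharp dispersal transition at 37°C. The **ectothermic** variant
evolves $T_b$ by the heat balance with the identity transfer; because
thermogenesis keeps every body at least as warm as the environment, these
litters huddle at all ambient temperatures. The **homeothermotaxic**
variant gates the drives through
$F(T) = \big(1 + e^{-(T_p - T_b)\,T/\sigma}\big)^{-1}$: a pup below its
preferred temperature $T_p$ seeks heat, above it avoids heat, and at
$T_b = T_p$ the drives are exactly $\tfrac12$. This restores the phase
transition while sustaining a single macro-huddle, and produces pup flow.

## Parameters, units and conventions

Defaults (all exposed in `sim_config()`): 12 pups, $n = 1000$ thermometers,
$v_1 = 200$, $v_2 = 0.3$, $G = 6.32$°C/time, $T_p = 37$°C, $\sigma = 100$,
$\mathrm{d}t = 0.05$, 8000 recorded steps after a 100-step settle, initial
$T_b = 30$°C, initial positions uniform in the central disc of radius $r$
(a pre-formed macro-huddle — the model studies huddle maintenance, not
formation across a large arena), headings uniform.

Two conventions deserve explanation:

* **Thermal rates.** `k1` and `k2` are stored as per-time rate constants
  for a fully exposed / fully contacted pup, defaults 1 and 2.5. They equal
  the circumference $2\pi r$ times per-unit-arc conductances
  $1/2\pi r$ and $2.5/2\pi r$; only this scaling is consistent with the
  model's own group-level behaviour: the isolated steady state
  $T_a + G/k_1$, a thermoregulatory plateau spanning roughly 19--31°C at
  defaults and centred near 25°C, and a thermogenesis sweep pivoting at
  $T_a = 25.26$°C all require $k_1 = 1$ per unit time.
* **Turning sign.** With contralateral wiring, the heading increment uses
  $M_R - M_L$ so that the warmer side attracts. Writing it with the
  opposite sign would make every variant heat-avoiding and abolish
  huddling altogether; the choice here reproduces the described
  single-pup behaviour (orienting toward a warm contact below 37°C) and the
  litter-level transition.

Degenerate cases are defined explicitly: coincident centres (bearing
undefined) draw one uniform bearing per pair from the seeded RNG stream and
the collision spring separates the pair immediately; a zero drive sum sets
both motors to $\tfrac12$; a fully exposed pup reports $T_c = T_b$ so its
exchange term is exactly zero; ties in the nearest-littermate assignment go
to the lowest pup index for deterministic replay.

## Metrics

* **Huddling** $= 1 - \eta$ averaged over pups and recorded (post-settle)
  steps. Settle records are excluded from all metric averages.
* **Pup flow** $=$ the time-averaged $|\mathrm{d}\eta/\mathrm{d}t|$ per
  pup, estimated as $\frac{1}{n_t - 1}\sum_t |\eta(t) - \eta(t-1)|$ divided
  by $\mathrm{d}t$, averaged over pups. The per-time normalisation matters:
  a huddling litter at $T_a = 5$°C holds a baseline near 0.013 per unit
  time (0.00065 per step at $\mathrm{d}t = 0.05$). `pup_flow(scale =
  "step")` gives the raw per-step difference.
* **Subgroups**: connected components of the contact graph with an edge
  where $d_{ij} \le 2r$ — the same gate as the contact field; touching
  counts as connected. `largest_aggregate()` reports the largest component,
  time-averaged or maximal.
* **Mean body temperature** over pups and recorded steps.

## The super-organism model

Treating the litter as one body with exposed-area fraction $A$ and settled
heat balance $0 = k_1 A (T_a - T_p) + G$ gives the optimal area
$A = G / (k_1 (T_p - T_a))$, clipped to measured bounds
$[A_{\min}, A_{\max}]$ (defaults 0.36 and 1.0; `estimate_area_bounds()`
recomputes them from any sweep, which is the normative path when comparing
against simulations). The body temperature is $T_a + G/(k_1 A_{\min})$
below the plateau, $T_p$ on it, $T_a + G/(k_1 A_{\max})$ above. The plateau
spans $\Delta T_a = (G/k_1)(1/A_{\min} - 1/A_{\max})$: the model's central
testable prediction is that increasing thermogenesis, or insulating pups
(reducing $k_1$), widens the range of ambient temperatures over which body
temperature is regulated by huddling. With the bounds held fixed both
breakpoints also shift downward as $G/k_1$ grows — the regulated range
widens toward colder environments; a claim that the critical temperature
itself rises with $G$ does not follow from the piecewise formulae.

With $G = 0$ the formulae degenerate to a sharp step at $T_p$, predicting
strong huddling up to the preferred temperature; simulated litters instead
disperse at every ambient temperature (without thermogenesis there is no
heterogeneity to steer by), so `exposed_area()` warns in this regime.

## Numerical choices

Forward Euler at $\mathrm{d}t = 0.05$ throughout; the isolated-pup
relaxation matches the closed-form exponential within 1% of the initial
amplitude over ten time constants (tested). The contact field is computed
once per step from the start-of-step state and reused by both the motion
and the temperature update; heading and position increments are evaluated
simultaneously at the start-of-step state. Headings are stored unwrapped
(they enter only through cosines and sines). A non-finite state aborts with
a diagnostic naming the step and pup, signalling a misconfigured timestep.

The production path is a compiled (Rcpp) loop; a pure-R step
(`sim_step()`, `engine = "r"`) defines the reference semantics and the two
are cross-checked to 1e-10 on every variant in the tests. All randomness
(initial placement, sensor noise, degenerate tie-breaks) flows through R's
seeded RNG; with noise off a seed reproduces trajectories bitwise. Sweeps
give each (value, replicate) its own seed derived from the master seed.

## What the simulations do and do not show

The default generator *is* the study design: pre-formed litters of twelve,
a fixed arena, constant ambient temperature per run. Simulated metric
means at desk scale (4000 recorded steps, 3 replicates, used by the test
suite) sit within a few percent of the full 8000-step protocol; the
thermometer count is kept at 1000 even at desk scale because the pup-flow
metric differences consecutive $\eta$ values and becomes
quantisation-limited below a few hundred sensors (an $\eta$ convergence
check at $n = 200$ vs $n = 1000$ passes at 0.01, but flow inflates
roughly fourfold).

Several published group-level quantities are reproduced closely by this
implementation: the sharp endothermic transition just below 37°C, the
ectothermic macro-huddle (huddling ≈ 0.6, aggregates of 10+ pups versus
much smaller endothermic ones), the pup-flow baseline ≈ 0.013 at cold
ambient temperatures with a peak near 16°C, and complete dispersal at high
temperatures. Two families of quantities are *not* reproduced from the
equations as written, and are reported as such rather than patched: the
dispersed endothermic litter retains ≈ 20% surface contact in the original
study but approaches zero here (pups end in a contact-free ring at the
arena wall; exploratory experiments suggest the original analysis counted
thermometer arcs pressed beyond the arena boundary as covered, a mechanism
the written model excludes), and on the transition slope our huddles are
looser than the analytic optimum (mean body temperature ≈ 30--34°C rather
than $T_p$), because per-pup coverage equilibrates where the collision
spring balances the constant forward drive. Real litters, of course,
deform their bodies, conserve heat through bedding and differ in many ways
from rigid discs; passing tests validate the model's internal logic, not
its fidelity to animals.

## A worked sweep

```{r sweep, eval = FALSE}
cfg <- sim_config("homeothermotaxic")
sw <- run_sweep(cfg, "t_a", seq(5, 50, length.out = 20), replicates = 10,
                seed = 1)
summarise_sweep(sw)
bounds <- estimate_area_bounds(sw)
autoplot(sw, superorg = superorganism_params(a_min = bounds$a_min,
                                             a_max = bounds$a_max))
```
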