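---
title: "Multiple flow equilibria in microvascular networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple flow equilibria in microvascular networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemonet)
```

## The model

`hemonet` models steady blood flow with haematocrit transport in small
vascular networks. Each vessel is a rigid cylinder carrying Poiseuille flow,

$$Q_{(x,y)} = \frac{P_x - P_y}{R_{(x,y)}}, \qquad
  R_{(x,y)} = \frac{128\, L_{(x,y)}\, \mu(H_{(x,y)}, D_{(x,y)})}{\pi D_{(x,y)}^4},$$

where the apparent viscosity $\mu(H, D)$ follows the empirical in-vivo law of
Pries and co-workers, capturing the Fåhræus–Lindqvist effect: $\mu$ depends
nonlinearly on the tube haematocrit $H$ and on the diameter $D$ (in µm)
through the relative viscosity at 45% haematocrit, $\mu_{45}(D)$, and the
shape coefficient $C(D)$ (`mu_45()`, `coeff_C()`, `apparent_viscosity()`).
For $D \gg 10$ µm, $C \to -0.8$ and $\mu_{45} \to 3.2$, so the law loses its
diameter dependence; the package exploits this in its diameter sweeps.

At every interior junction blood and red blood cells (RBCs) are conserved.
Junctions have exactly three vessels (the phase-separation law below is only
defined for three-vessel junctions, so networks are restricted to interior
degree 3). A junction with two inflows is a *convergence*: RBC conservation
determines the outflow haematocrit. A junction with two outflows is a
*bifurcation*: conservation is insufficient and a *splitting rule*
$\psi(r)$ prescribes the fraction of the parent RBC flux entering a daughter
with fractional blood flow $r = Q_\text{daughter}/Q_\text{parent}$. The
default rule is the Pries 1990 logit form with a threshold $X_0 = 0.4/D$:
daughters taking less than a fraction $X_0$ of the parent flow receive no
red cells at all. The rule satisfies a partition of unity between the two
daughters, which makes nodal RBC conservation automatic. Alternative rules
plug in through `register_splitting_rule()`; a degenerate `"proportional"`
rule ($\psi = r$, no phase separation) is included for testing.

### The steady-state system

Pressures are prescribed at inlets and outlets, haematocrit at inlets. The
unknowns are the interior nodal pressures and the haematocrit of every
non-inlet vessel; flows are eliminated through Poiseuille's law. Each
interior node contributes a flow-conservation equation, and each non-inlet
vessel contributes the haematocrit equation of its upstream junction --
conservation at a convergence, the splitting rule at a bifurcation. Which
form applies depends on the *current flow directions*, so the residual is
re-assembled (junctions re-typed) at every evaluation; this is what lets the
solver track solutions whose flow pattern changes with the parameters.

All flows are normalised by the total inflow $Q_{in}$, making the system
dimensionless: equilibria are invariant under rescaling of the plasma
viscosity $\mu_p$, the reference vessel length $L$, and the
boundary-pressure span. The package's tests assert all three invariances.
Because of them, $\mu_p$ defaults to 1 and lengths are stored as multiples
of $L = 1$.

### Redundant vessels

A feasible flow orientation directs every vessel so that inlets feed the
network, outlets drain it, interior nodes have in- and out-flow, and no
directed cycle exists (a flow loop would contradict pressure-driven flow).
`enumerate_feasible_orientations()` enumerates these exhaustively (the
target networks have at most a handful of free vessels; the search is
guarded at 25 vessels). A vessel whose direction differs between feasible
orientations is *redundant* (`find_redundant_vessels()`). Coexisting
equilibria are labelled per redundant vessel as having negative,
intermediate, or positive flow, so a network with $r$ redundant vessels
admits at most $3^r$ equilibria (`equilibrium_upper_bound()`).

The two benchmark networks are built by `build_triangle()` (one redundant
vessel, bound 3) and `build_extended_triangle()` (two, bound 9). Length
ratios $\alpha$ (redundant vessels) and $\beta$ (vessel (4,6), the asymmetry
control) and a common diameter $D$ parameterise both; defaults are
$P_1 = P_2 = 0.5$, $P_3 = 0$, $D = 10$, $\alpha = 0.1$, $\beta = 1$,
$\bar H_{in} = 0.45$.

## Numerical methods

**Newton solves.** `newton_solve()` uses damped Newton iteration with a
backtracking line search and a central finite-difference Jacobian with
steps scaled to each unknown. Finite differences were chosen over analytic
derivatives because the splitting rule is piecewise and junction types
switch with flow signs; hand-coded derivatives would be brittle exactly
where the interesting dynamics are. Haematocrit iterates are clipped to
$[0, 0.999]$ during iteration only; acceptance requires the unclipped
residual below $10^{-11}$.

**Homotopy start.** `homotopy_initial_solve()` finds a first equilibrium by
deforming a starting system $G$ with a known unique solution into the full
equations $F$ along $h = (1-\lambda)F + \lambda G$. $G$ freezes the
viscosity at $\mu(\bar H_{in}, D)$ and pins every haematocrit to
$\bar H_{in}$, making it linear in the pressures with a closed-form
solution. Any starting system with a known unique root works for a convex
homotopy; this one stays close to the physical solution manifold.

**Pseudo-arclength continuation.** `continue_branch()` traces equilibrium
branches in any sweep parameter ($\beta$, $\alpha$, $\bar H_{in}$, $D$, an
inlet pressure) with a secant-tangent predictor and a Newton corrector
orthogonal to the tangent. Unlike naive parameter stepping, arclength
continuation passes through folds, where the branch turns back in the
parameter. The parameter is internally scaled to $[0,1]$; steps adapt
between $10^{-9}$ and `ds_max` (default 0.03 of the scaled range; the sweep
drivers use 0.01-0.02). Every recorded point is verified to residual
$10^{-10}$.

**Fold detection and refinement.** Folds are flagged by a sign change of
the parameter increment along the branch, then located precisely in two
stages: a Brent search for the parameter extremum along the local chord
(each trial point is projected back onto the branch by a Newton corrector),
followed by a Newton polish of the bordered Moore system
$[F;\, F_x v;\, \|v\|^2 - 1] = 0$, whose solution has a singular
state-space Jacobian. The polish is accepted only if it agrees with the
Brent location to $10^{-5}$; this two-stage scheme makes fold locations
reproducible to machine precision across branches, so folds found from
different starting equilibria merge cleanly (tolerance $2\times10^{-5}$ —
well below the closest genuinely distinct fold pair we observe, which is
separated by about $4\times10^{-4}$ in $\beta$).

**Border-collision folds.** When the first critical haematocrit is
approached at moderate diameters, the fold can sit exactly on the splitting
rule threshold $r = X_0$, where the residual is only piecewise smooth.
There the corrector cannot turn the corner and the trace stalls with a
vanishing step. A stalled trace whose endpoint lies within $10^{-3}$ of a
$\psi$ kink is therefore recorded as a fold at the stall point. This
matters for the diameter sweep of the critical curves; the smooth-fold
machinery alone would silently miss these points.

**Enumerating all equilibria.** `enumerate_equilibria()` combines four seed
families: the homotopy solution; Newton from the frozen-viscosity and
zero-haematocrit base states; one structured seed per flow-state pattern in
$\{-,0,+\}^r$ (pressures biased to drive the target directions,
haematocrit zeroed in "intermediate" vessels); and a Latin-hypercube
multistart in which a random *haematocrit field* is drawn first and the
matching pressures are obtained from the linear Kirchhoff system frozen at
that field. Haematocrit-first sampling places every start on the
pressure-consistent manifold and is dramatically more effective than
sampling pressures blindly. For networks carrying a mirror annotation the
set is closed under the reflection map (`mirror_state()`), which at
$\beta = 1$ is an exact symmetry. Accepted states must have positive total
inflow, inlet vessels feeding the network, normalised flows bounded by 1
and non-negative haematocrits; duplicates merge below a state distance of
$10^{-6}$.

**Zero-flow canonicalisation.** At exactly zero flow in a redundant vessel
the splitting-rule equation for that vessel is vacuous ($\psi = 0$ and
$Q H = 0$ for any $H$), so the haematocrit there is unidentifiable -- a
genuine degeneracy of the model, not a solver artifact. The canonical
representative carries $H = 0$ in any vessel with $|\hat Q| < 10^{-8}$,
consistent with the threshold behaviour of the rule and with the
interpretation that a vessel without flow transports no red cells.

**Numerical floors.** Flows below $10^{-14}$ (normalised) are treated as
zero when junctions are typed. The inflow normalisation falls back to the
largest flow magnitude whenever $Q_{in}$ is smaller than $10^{-8}$ of it,
so near-degenerate iterates cannot amplify round-off.

## Sweep drivers and problem sizes

The drivers `beta_sweep()`, `alpha_sweep()`, `haematocrit_sweep()`,
`region_map_alpha_beta()`, `region_map_D_H()` and `inlet_pressure_sweep()`
reproduce the package's bifurcation studies: fold locations in $\beta$, the
stepwise loss of equilibria as $\alpha$ grows, critical inlet haematocrits
$\bar H_{in}^{(k)}(D)$, equilibrium-count maps of the $(\alpha, \beta)$
plane, and pressure sweeps under any registered rule. Region maps count
equilibria at cell centres with warm-started enumeration; areas are cell
counts times cell area. The critical-haematocrit curve over diameter uses a
20-point log-spaced grid on $[10, 200]$ µm with the anchor haematocrit 0.6
(safely above the critical values) and a parabolic refinement (in $\log D$)
around the gridded maximum. The test suite runs these at reduced grids
(e.g. $7\times7$ region maps, 5-point $\alpha$ grids) chosen so the whole
suite completes in minutes on a single core; the qualitative assertions do
not depend on the grid resolution.

## What the random generator emulates

`random_network()` produces small degree-3 networks for property tests:
a feasible topology (Y, double-Y tree, triangle, extended triangle) with
randomised lengths ($0.05$–$3\,L$), diameters (5–50 µm), boundary pressures
(inlets above outlets) and inlet haematocrit (0–0.6), under random node
relabelling. It emulates the parameter heterogeneity of real microvascular
beds, not their topology statistics: real networks are far larger, have
degree-4+ junctions, compliant walls, and unsteady flow. Tests passing on
these fixtures validate the solver contracts and conservation laws; they do
not by themselves establish behaviour of full-scale vascular trees.

## Known limitations

* Interior junctions are restricted to degree 3, as required by the
  splitting rule; generalising $\psi$ to higher-degree junctions is not
  specified by the underlying rheological literature.
* Stability of the equilibria (and oscillatory solutions) is out of scope:
  the package classifies and counts steady states but does not integrate
  the time-dependent problem.
* Only the Pries 1990 splitting rule ships with coefficients; other rules
  from the literature must be registered by the user through the rule
  interface.
* Boundary nodes keep their declared role; inlet/outlet switching under
  extreme pressure sweeps is not modelled.
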