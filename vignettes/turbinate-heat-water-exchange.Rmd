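---
title: "Modeling heat and water-vapor exchange in seal nasal turbinates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling heat and water-vapor exchange in seal nasal turbinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turbsim)
```

## The physical problem

When a seal inhales cold, relatively dry air, the maxilloturbinates (MT) —
scrolled, mucosa-covered bony structures filling the anterior nasal cavity —
warm and humidify that air before it reaches the lungs. On exhalation the
process partially reverses: the warm, saturated air from the lungs recools
against the mucosal surfaces that were chilled during inhalation, returning
part of the heat and condensing part of the water. The efficiency of this
regenerative exchange decides how much heat and water the animal
irreversibly loses to the environment with every breath, and therefore how
expensive breathing is in a cold climate.

`turbsim` simulates this exchange in a quasi-1D, time-dependent model of
the MT region and quantifies its imperfection by the second-law measure of
the process: the total entropy production per breathing cycle,
$\Sigma_{irr}$, and the corresponding lost work
$W_{lost} = T_{amb}\,\Sigma_{irr}$.

## Model structure

### Geometry

The MT air space is abstracted to a tube of varying cross-sectional airflow
area $A_a(z^*)$ and air–tissue perimeter $\gamma_a(z^*)$ along the scaled
axial position $z^* = z/L$. Real profiles, measured from CT slices, are
single-humped; the built-in generator (`synth_geometry()`) emulates them
with a raised-cosine bell between a support range $[z_{lo}, z_{hi}]$,
peaking at the midpoint and falling to `edge_fraction` (default 0.2) times
the peak at the support endpoints. Two named geometries are provided:

```{r species}
species_geometry("Eb")   # Arctic bearded seal morphometry
species_geometry("Mm")   # subtropical monk seal morphometry
```

The peak values ($A_{a,max}$ = 3.55e-3 vs 1.99e-3 m$^2$, $\gamma_{a,max}$ =
11.1 vs 3.82 m), MT lengths (61.0 vs 51.6 mm) and support ranges
(0.14–0.87 vs 0.18–0.82) are the published morphometric values for the two
species. The perimeter-to-area ratio $\delta^* = \gamma_a/A_a$ is exposed
as `complexity()`; although often quoted as a dimensionless complexity
measure, it carries units of 1/m and the package reports it as such without
rescaling. Positions outside the support exchange nothing and are not part
of the computational domain. Whether a soft-tissue lining thickness should
be subtracted from the bone-derived $A_a$ before simulation is not settled;
the package never silently modifies a profile, and the tissue sleeve
thickness is an explicit configuration parameter instead.

### Subsystems and balance equations

Five coupled subsystems exchange heat radially at every axial position:
the air (a), the liquid mucus lining (m, thickness $d_m$ = 10 um), the
interstitial tissue (it), and the arterial and venous blood (art, ven).
The air additionally exchanges water vapor with the mucus. Area-averaged
balance equations (one energy balance per subsystem, plus the air water
vapor mass balance) are discretized in $z$ by the method of lines:

* air: advection by the breathing flow $F_a(t)$ plus interface exchange,
* mucus: interface heat flux, latent heat of the condensing/evaporating
  water flux, conduction to the tissue, and the enthalpy of the
  replenishment water,
* tissue: conduction to mucus and to both blood compartments,
* artery: advection toward the nostril ($-z$) plus tissue contact,
* vein: advection toward the body ($+z$) plus tissue contact.

Blood flows countercurrent to the inhaled air: arterial blood enters warm
at the body end and returns through the vein, with the venous inflow at the
nostril end set to the local arterial temperature. The artery, vein and
tissue cross sections derive from a configured tissue sleeve of thickness
`d_it` (default 200 um, the mucosal thickness of the reference case) on the
perimeter, split by volume fractions (defaults 0.15/0.15 artery/vein).

Breathing is sinusoidal, $F_a = F_{a,max}\sin(2\pi t/t_{br})$ with
$F_{a,max} = \rho_a V_t / t_{br}$ evaluated at the ambient inlet state
(tidal volume 6.3 L, cycle 3.09 s). Integrating this law over the
inhalation half-cycle gives an inhaled mass of $\rho_a V_t/\pi$ rather than
$\rho_a V_t$; the package implements the sinusoidal law literally and
offers `pi_correction` in the pattern block for users who want the nominal
tidal mass per breath restored.

### The air–mucus interface law

The coupled transfer of measurable heat $J_q'$ and water $J_w$ across the
air–mucus interface follows nonequilibrium thermodynamics: fluxes and
conjugate forces are linked by a symmetric positive-definite resistance
matrix,
$$X_q = r_{qq} J_q' + r_{qw} J_w,\qquad X_w = r_{qw} J_q' + r_{ww} J_w,$$
with $X_q = 1/T_m - 1/T_a$ and
$X_w = (R/M_w)\ln\varphi_a + h_{w,a}\,(1/T_m - 1/T_a)$. Chemical
potentials are referenced to saturation at the local temperature (the mucus
surface is saturated liquid water, so $\mu_{w,m} = 0$), and the enthalpy
coefficient is the latent heat at the mean interface temperature — the
Gibbs–Helmholtz companion of that reference choice. Consequently $X_w$
vanishes exactly when the local vapor pressure equals saturation at the
mucus temperature, and both forces vanish at thermal and humidity
equilibrium. Because a single off-diagonal resistivity is stored, Onsager
symmetry holds structurally and the local entropy production
$\sigma = \gamma_a (J_q' X_q + J_w X_w)$ is a positive semi-definite
quadratic form — non-negative for every state, by construction rather than
by tolerance.

The default resistivities are constant interfacial (kinetic-theory-style)
conductances, `h_q_if` = 150 W/(m$^2$K) for heat and `k_w_if` = 0.05 m/s
for water, with a heat-of-transfer coupling `q_star` = -2.4e5 J/kg (about
a tenth of the latent heat, the order suggested by kinetic theory for
evaporating water). Two observations motivated making the interfacial term
the default resistance rather than a laminar-duct film:

* a film coefficient scaled on the hydraulic diameter $D_h = 4A_a/\gamma_a$
  makes the air-side conductance depend on the cross-sectional area, and
  the entropy production then responds almost as strongly to area changes
  as to perimeter changes — contradicting the reported structural
  sensitivity of the system, which is dominated by the perimeter;
* an interfacial resistivity is a material property of the evaporating
  surface, comparable in magnitude to the film value for these narrow
  channels (the parallel-plate film coefficient is about 150 W/(m$^2$K) at
  the Arctic seal's mean gap of ~0.6 mm), which is what "considerable
  interface resistance" means quantitatively here.

The film term remains available (`use_film = TRUE` with parallel-plate
Nu = Sh = 7.54) and then acts in series with the interfacial part. The
mucus–tissue and tissue–blood exchanges are plain linear conductances
(defaults 500 W/(m$^2$K)); the blood-side contacts contribute little to the
entropy budget, so low fidelity is acceptable there. The mucus water
inventory is closed instantaneously, $J_m = -J_w$, consistent with the
constant lining thickness and density.

### Moist-air thermodynamics

The humid-air state is determined by temperature, pressure (fixed at
101325 Pa along the channel; the viscous pressure drop is negligible) and
water fraction. Density comes from the Peng–Robinson cubic equation of
state for the air–water mixture (one-fluid mixing, $k_{ij}=0$); at ambient
conditions the cubic correction to the ideal-gas density is below 1%, but
it is retained for consistency. Saturation pressure uses an Antoine-type
(Buck) correlation over liquid water, extrapolated into the supercooled
range because the mucus lining stays liquid well below 0 degC. The latent
heat is linear in temperature, $\Delta_{vap}H = 2.501\times10^6 - 2361\,
(T - 273.15)$ J/kg.

### Boundary conditions and integration

During inhalation the distal (nostril) air node is pinned to the ambient
temperature and humidity; during exhalation the proximal air node is
pinned to deep-body conditions (36 degC, saturated) — the nasopharynx is
treated as an ideal buffer, so expired air always enters the MT domain at
body state. In both phases the mucus, tissue and artery at the proximal
end are held at body temperature and the venous inflow at the distal end
tracks the local arterial temperature. The constrained nodes are handled
algebraically (their time derivatives are removed from the ODE system),
which is the constrained-system analogue of a mass-matrix formulation;
phases switch exactly at the zeros of $F_a$.

Spatial derivatives use five-point, fourth-order finite-difference
stencils biased into the upwind direction (three upwind points where the
domain allows, one-sided closures at the ends) — with one documented
exception. The row adjacent to the inflow boundary can have at most one
upwind neighbor; its clipped five-point stencil is downwind-heavy and
gives the semi-discrete advection operator a weakly unstable spectrum
(positive real eigenvalues of order 100 s$^{-1}$ at peak flow), which in
practice destroys the integration within a few cycles. That single row
therefore uses a three-point centered closure, which makes the operator
spectrum strictly dissipative at the cost of second-order accuracy at one
node; a unit test checks the spectrum stays in the left half-plane.

The resulting stiff ODE system (6 fields x Ns nodes) is integrated with a
variable-order BDF scheme (`deSolve`'s `vode`), half-cycle by half-cycle,
from an initial state at body conditions. The run stops when the relative
cycle-to-cycle change of two monitors — the flow-weighted expired-air
temperature and the total entropy production — falls below
`convergence_eps` (default 1e-4; the stopping rule is stated without a
value in the source literature, and 1e-4 resolves both monitors well below
every effect studied here). The cyclic steady state is independent of the
initial condition, which a test verifies by also starting from ambient
conditions. With the default coefficients, convergence takes of order
30–80 cycles depending on species and ambient temperature.

Default problem sizes: the production grid is Ns = 24 (doubling to 48
changes the entropy production by well under 1%; `grid_convergence_study()`
reproduces this check), with 25 stored time points per half-cycle during
iteration and 61 for the final densely recorded cycle. The test suite runs
its model-level checks on a reduced configuration (Ns = 12,
`convergence_eps` = 1e-3) so that the whole suite stays fast; the
package-level conclusions are grid-checked separately.

## Entropy accounting and summary statistics

`total_entropy()` integrates the local entropy production over the final
cycle (trapezoids in $z$ and $t$) and reports the per-interface
components: the air–mucus term split into heat and water parts
($\Sigma_{a-m,q}$, $\Sigma_{a-m,w}$), the mucus–tissue term, and the two
blood contacts. Their sum is $\Sigma_{irr}$ and the lost work is
$W_{lost} = T_{amb}\Sigma_{irr}$ — the multiplier is the ambient absolute
temperature (the temperature of the surroundings where the dissipated heat
ends up). `dissipation_rates()` converts a per-cycle lost work into kJ/h
and kJ/day.

`exchange_summary()` references losses to the ambient inlet state: the
heat loss is the cycle-integrated sensible plus latent enthalpy export of
the expired air at the nostril relative to inhaled ambient air, and the
no-recovery baseline re-evaluates that export as if expired air left at
deep-body conditions. Recovery is $100(1 - \mathrm{loss}/\mathrm{baseline})$,
which is 100% when expired air re-equals inhaled air and 0% when it leaves
at body state. Latent heat is evaluated at the expired-air temperature and
sensible heat as $c_{p,a}\Delta T$; both conventions are configurable
because the loss bookkeeping admits several consistent choices.
`expired_t_regression()` fits expired-air temperature against ambient
temperature in degC (slope 0 = perfect exchanger, slope 1 = no exchange).

## What the synthetic generator does and does not emulate

The raised-cosine geometries reproduce the single-humped shape, the peak
values, the support ranges and the MT lengths of the measured profiles,
and therefore the leading-order contrast between the two species: the
Arctic seal has about three times the exchange perimeter of the
subtropical seal at comparable air volume. They do not reproduce the
measured profiles' asymmetry or small-scale roughness, and because both
profiles share one shape function, the complexity ratio $\delta^*$ is
constant along the synthetic nose rather than peaked near mid-span.
Consequently, tests passing on synthetic geometry demonstrate the solver,
the thermodynamics and the structural orderings — not agreement with the
CT-derived profiles, which users can supply as delimited tables via
`load_geometry()`.

Equally, the transport-coefficient defaults are this package's own
physically motivated choices, documented above; published per-cycle loss
and entropy magnitudes depend on a coefficient set that is not in the
public domain, so desk-scale runs should be compared against orderings and
sensitivities rather than absolute table values.

## Numerical choices and degenerate inputs

* Interpolation of geometry onto the solver grid is monotone piecewise
  cubic (Fritsch–Carlson), which cannot undershoot positive data.
* The force–flux system is solved node-wise in closed form; the resistance
  matrix is validated positive definite at construction over the full
  working temperature range, so a singular system is rejected before any
  integration starts.
* Property correlations are clamped to their validity range inside the
  right-hand side, because a stiff integrator's predictor may briefly probe
  states outside any physical bracket; the public property functions keep
  hard range errors.
* Supersaturation: the solver permits transient supersaturation of the air
  (condensation proceeds at a finite rate), but `air_state()` rejects
  relative humidity above 1 on construction, since an equilibrium state
  description does not cover it.
* Equilibrium boundary conditions (ambient = body, saturated) reproduce
  the exact fixed point: all derivatives vanish, the run converges in at
  most two cycles and $\Sigma_{irr} = 0$ to integrator tolerance.
* The budget diagnostics in `cycle_budget()` pair each subsystem's
  cycle-integrated advective transport — evaluated with the same discrete
  differentiation operators the solver uses, over the freely evolving
  nodes — against its interface sources; they close to about a percent
  (cycle-periodicity plus snapshot quadrature). The cruder estimate that
  telescopes advection to the two boundary values differs from the stencil
  integral by O(10%) at these grids because the inflow front of the
  non-conservative advection form is only a few cells wide; the exported
  loss accounting therefore uses the boundary states directly and is
  documented as such, while the budget check tests the scheme's own
  bookkeeping.

## Known limitations

* The model is quasi-1D with radial symmetry per cross section; no
  secondary flows, no conjugate axial conduction in tissue.
* Air outside the MT mass (between turbinate and cavity wall) is not
  modeled; measured expired temperatures of live seals include that bypass
  and thermoregulatory control, so model-experiment offsets are expected.
* The vascular heating of the nose tip observed at very low ambient
  temperatures is deliberately absent; expired-air temperatures at the
  coldest ambients are therefore underestimated.
* Blood flow is constant; no congestion dynamics within a run (congestion
  is represented only as geometry perturbation between runs).
* Water appears as vapor and as saturated lining liquid only; no ice
  phase, no mucociliary transport, no CO2/O2 exchange.
* Because the interfacial water resistivity scales as the reciprocal of
  the saturation concentration at the mucus temperature, condensation
  kinetics freeze out over very cold mucus: at -30 degC ambient the
  expired air leaves supersaturated with respect to its own temperature
  (the familiar fogging of exhaled breath), by up to a factor ~2 at the
  default coefficients. Near-saturation of the exhalate holds at moderate
  ambient temperatures; no aerosol/fog phase is tracked, so that water is
  counted as lost.
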