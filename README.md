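# turbsim

Quasi-1D, time-dependent simulation of coupled heat and water-vapor
transport in the maxilloturbinate (MT) region of a seal's nasal cavity,
with entropy-production (energy-dissipation) accounting.

## What it is for

Arctic seals have strikingly elaborate nasal turbinates. During
inhalation the turbinate mucosa warms and humidifies cold ambient air;
during exhalation the expired air recools against the same surfaces,
returning part of the heat and water. `turbsim` is for quantitative
comparative physiology of that regenerative exchanger: given a turbinate
morphometry — cross-sectional airflow area `Aa(z*)` and air–tissue
perimeter `gamma_a(z*)` along the nose — it simulates full breathing
cycles to a cyclic steady state and reports how much heat and water the
animal loses per breath, what fraction it recovers, and how
thermodynamically imperfect the exchange is.

## The model in brief

Five subsystems — air, liquid mucus lining, interstitial tissue, artery,
vein — exchange heat (and, between air and mucus, water) radially at every
axial position, while air and countercurrent blood advect axially. A
sinusoidal tidal flow `Fa = Fa,max sin(2 pi t / t_br)` drives the cycle.
The air–mucus interface uses the force–flux law of nonequilibrium
thermodynamics,

    X_q = r_qq Jq' + r_qw Jw
    X_w = r_qw Jq' + r_ww Jw

with `X_q = 1/Tm − 1/Ta`, `X_w = (R/Mw) ln(phi_a) + h_w (1/Tm − 1/Ta)`,
and a symmetric positive-definite resistance matrix, so the local entropy
production `sigma = gamma_a (Jq' X_q + Jw X_w) >= 0` holds by
construction. Cycle-integrating sigma over the MT domain gives the total
entropy production `Sigma_irr` (J K^-1 cycle^-1) and the lost work
`W_lost = T_amb * Sigma_irr` — the energy the animal must replace with
food because its nose is not a perfect exchanger.

The balance equations are discretized by the method of lines (fourth-order
upwind-biased differences, 24-node default grid) and integrated with a
stiff BDF scheme, cycle by cycle, until the expired-air temperature and
the entropy production repeat to within 1e-4 per cycle. See the methods
vignette (`vignettes/turbinate-heat-water-exchange.Rmd`) for the full
model description, parameter table and numerical choices.

## Worked example

Compare an Arctic-type and a subtropical-type turbinate under an Arctic
ambient (−30 °C, 90% relative humidity), on the built-in synthetic
geometries that emulate the two species' published morphometry:

```r
library(turbsim)

eb <- run_case(case_spec("Eb", "A0", Tamb_C = -30))  # Arctic bearded seal
mm <- run_case(case_spec("Mm", "A0", Tamb_C = -30))  # Mediterranean monk seal

print(eb$exchange)
#> heat loss  133.9 J/cyc (recovery 70.5%)
#> water loss 19.55 mg/cyc (recovery 81.9%)
#> expired air temperature 272.14 K (-1.01 C)

print(mm$exchange)
#> heat loss  283.1 J/cyc (recovery 37.7%)
#> water loss 60.14 mg/cyc (recovery 44.3%)
#> expired air temperature 289.22 K (16.07 C)

print(eb$entropy)
#> entropy production over one breathing cycle (J/(K cyc)):
#>   air-mucus   0.04353  (heat 0.01959 + water 0.02394)
#>   mucus-tissue 0.01422; tissue-artery 0.008237; tissue-vein 0.00766
#>   total Sigma_irr = 0.07365; W_lost = 17.9 J/cyc at T_amb = 243.15 K
```

Reading: under identical boundary conditions the Arctic-type geometry
(peak perimeter 11.1 m vs 3.82 m) recovers far more heat and water per
breath, expires much cooler air, and dissipates less energy — the
structural advantage of elaborate turbinates in the cold. The air–mucus
interface dominates the entropy budget, with heat and water transfer
contributing comparably; the blood-side contacts are minor.

The sensitivity of the dissipation to geometry is exposed directly:

```r
perturbation_study(case_spec("Eb", "A0", Tamb_C = -30))
```

scales the area (`A1`, ×1.2²), the perimeter (`A2`, ×1.2) or both (`A3`)
and reports the percentage change of `Sigma_irr` against the unmodified
`A0` — enlarging the perimeter cuts the dissipation by several percent
while enlarging the area alone changes it by well under a tenth of that.

A shell driver wraps the same functionality:

```sh
Rscript inst/cli/turbsim.R run --species Eb --case A0 --tamb -30 --out out/
Rscript inst/cli/turbsim.R sweep --species Eb --tamb-list=-30,-10,10
Rscript inst/cli/turbsim.R tables --species Eb --tamb -30
Rscript inst/cli/turbsim.R gridcheck --species Mm --tamb 10 --ns-list 12,24
```

Custom morphometries enter as delimited tables (`z_star,Aa_m2,gamma_m`,
one row per CT slice) via `load_geometry()`; every physical constant,
transport coefficient and solver setting is overridable through the
configuration (`default_config()`, YAML-loadable with `read_config()`).

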