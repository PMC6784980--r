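---
title: "Modelling lake sediment oxygen demand with sediagen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lake sediment oxygen demand with sediagen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sediagen)
```

## The problem

In eutrophic lakes the sediment is the dominant sink for hypolimnetic
oxygen.  Two channels make up the sediment oxygen demand (SOD): the
diffusive sediment oxygen uptake (SOU), i.e. the O2 flux across the
sediment-water interface that is consumed within the top millimetres, and
the efflux of reduced substances (F_red) - CH4, NH4+, S(-II), Mn(II) and
Fe(II) - which act as a negative oxygen flux once they are oxidized in the
water column:

$$F_\mathrm{red} = 2\,J_{CH_4} + 2\,J_{NH_4} + 2\,J_{S(-II)}
  + 0.5\,J_{Mn(II)} + 0.25\,J_{Fe(II)}, \qquad
  \mathrm{SOD} = \mathrm{SOU} + F_\mathrm{red}.$$

`sediagen` implements a transient, one-dimensional early-diagenesis
reaction-transport model of a eutrophic, artificially aerated lake
(the configuration shipped with the package describes Lake Baldegg,
Switzerland): it carries the sediment column through 160 years of
eutrophication, anoxia (1890-1982) and aeration history, and projects four
management scenarios to 2050 - status quo (SQ), mesotrophic (M) and
oligotrophic (O) re-oligotrophication, and a termination of artificial
aeration (NoAa).  The central question is the *sediment memory effect*: how
long reactive organic carbon buried during the anoxic decades keeps feeding
methanogenesis and thus F_red.

## Model structure

### Transport

Concentrations $C_i(x,t)$ of 12 solutes (umol cm^-3 porewater) and 10
solids (umol g^-1 dry sediment) obey

$$\frac{\partial(\varepsilon C_i)}{\partial t} =
  \frac{\partial}{\partial x}\!\left(D_i\,\varepsilon\,
  \frac{\partial C_i}{\partial x}\right)
  - \frac{\partial(\vartheta\,\varepsilon C_i)}{\partial x}
  + \sum \varepsilon\, r_i ,$$

with $\varepsilon = \phi$ (porosity, 0.84) for solutes and $1-\phi$ for
solids, burial velocity $\vartheta(t)$ from the forcing timeline, and
$D_i = D_b(x,t) + D_{sed}$ for solutes (bioturbation mixes both phases)
or $D_i = D_b$ for solids.  The tortuosity correction is
$D_{sed} = D_{mol}/(1-\ln\phi^2)$; the bioturbation profile is a tanh decay
from the interface value $D_{b0}(t)$ with attenuation scale 1.43 cm and a
residual 0.01 cm^2 yr^-1.  Solutes exchange with the bottom water through a
diffusive boundary layer of 0.082 cm,
$F^{upper}_i = D_{mol}(B_i(t) - C_i(0,t))/d_{DBL}$; solids receive the
depositional flux $J_i(t)$; the bottom boundary (50 cm) imposes a zero
diffusive gradient with burial outflow retained.  Molecular diffusivities
are a Boudreau-style infinite-dilution compilation evaluated at a bottom
water temperature of 5 degC (they are not part of the tabulated parameter
set); they can be overridden through `species_registry()`.

The discretization is a conservative finite-volume scheme on a geometric
grid whose spacing grows proportionally to depth plus a surface length
scale.  This law was chosen because it reproduces all three documented
resolutions of the reference configuration simultaneously (0.004-0.013 cm
within the top centimetre, about 0.29 cm at 30 cm and 0.48 cm at 50 cm with
500 cells); a power-law stretch cannot.  Burial advection is first-order
upwind (burial Peclet numbers are small), interface diffusivities are
arithmetic means, and the discrete scheme conserves mass to machine
precision, which the test suite asserts.

### Reaction network

Reactive organic matter (OM1; the refractory pool OM2 is inert) decays by
first-order kinetics partitioned over the classical terminal-electron-
acceptor cascade O2, NO3-, Mn-oxides, Fe-(hydr)oxides, SO4^2- and
methanogenesis.  Pathway $i$ carries a Monod limitation in its own TEA and
multiplicative inhibition by all energetically superior TEAs with the same
half-saturation constants (the Van Cappellen-Wang convention).  The oxide
limitations use the reactive pools (Mo1, Foh1), which are the pools the
pathways consume; the less-reactive pools (Mo2, Foh2) take part only in the
slower secondary oxidations.  Every carbon mineralized liberates N, P and S
in the organic-matter elemental ratio 106 : 8 : 0.5 : 0.5 (as NH4+,
HPO4^2- and S(-II)); methanogenesis splits carbon 1:1 into CH4 and CO2;
denitrification routes nitrogen to N2 (lost to the water column) except for
a configurable DNRA branch that returns NH4+.  The DNRA fraction has no
tabulated rate constant; its default (0.2 of the nitrate-reducing carbon
flow) is calibrated so that DNRA supplies at most about a quarter of the
NH4+ production, the documented bound for this system.

Seventeen secondary redox reactions (aerobic oxidation of NH4+, Mn(II),
Fe(II), S(-II) and CH4; anaerobic oxidations by Mn- and Fe-oxides;
sulfate-driven anaerobic CH4 oxidation; Mn(II) oxidation by nitrate) are
bimolecular.  Mineral phases (FeS, pyrite, vivianite, MnCO3) follow
saturation kinetics: precipitation proportional to $\max(\Omega-1,0)$ and
dissolution to the mineral content times $\max(1-\Omega,0)$, with pyrite
formation and sulfide-driven vivianite dissolution as bimolecular laws.
The carbonate system is fixed-pH: CO3^2- is computed from HCO3- with the
tabulated speciation constant at pH 7.  The equilibrium constants carry no
fixed unit convention; the package evaluates the vivianite ion-activity
product on the mol L^-1 scale (where its solubility product of 3e-20 is
meaningful) and the FeS and carbonate equilibria with the proton activity
expressed on the model's umol cm^-3 concentration scale, which yields FeS
accumulation rates of the observed order (tens of umol g^-1 over the
anoxic decades).

The whole network lives in a single stoichiometry matrix
(`stoichiometry_matrix()`, exportable with `write_stoichiometry()`), and an
element-composition matrix makes conservation auditable: the product of the
two matrices is zero for C, N, P, S, Fe and Mn, which the tests check
exactly.

### Forcing and scenarios

Upper boundary conditions are piecewise-linear timelines anchored at 1860,
1890, 1900, (1950), 1982, 1985 and 2018, shared by all scenarios, with the
scenario columns reached by a linear ramp over 2018-2030 and held to 2050.
The aeration-stop scenario collapses O2 to numerical zero by 2020 (the one
step-annotated entry of the timeline) and raises the reduced-substance
boundaries as the hypolimnion turns anoxic; its CH4 boundary is
0.1 umol cm^-3 (100 umol L^-1).  Optional seasonal
forcing multiplies selected boundaries by cosines with unit annual mean
(O2: 1 + 0.9 cos 2*pi*t, peaking at winter overturn; reduced solutes:
1 - 0.75 cos; depositional fluxes: 1 - 0.5 cos), so seasonal and
non-seasonal runs receive identical annual loads by construction.

Runs start from a 350-year spin-up under constant 1860 boundary conditions
(the pre-eutrophication state; the near-empty initial column is erased by
the spin-up, which the tests verify by doubling its length), continue
through the shared 1850-2018 history, and branch per scenario.

## Numerical design

The method-of-lines system (22 species x 120 cells by default) is stiff:
the fastest reactions (aerobic CH4 oxidation) have timescales of hours
while the simulation spans two centuries.  It is integrated with `lsodes`
(sparse BDF) through `deSolve`, with the right-hand side - including the
boundary-condition interpolation - compiled in C++ and called natively by
the solver.  A pure-R reference implementation of the same kernel ships in
the package and the test suite asserts that both produce identical
tendencies; the R path is also the basis of the user-facing operations
(`net_source_terms()`, `transport_tendency()`, `model_rhs()`).

Three numerical choices matter and are deliberate:

* **Smooth rate laws.**  All rate laws are evaluated on the raw state.
  Every consumption term is mass-action or Monod in each consumed species,
  so rates vanish linearly at zero and continue smoothly (and restoringly)
  through the tiny negative excursions a multistep integrator can produce.
  Clamping states or rates at zero instead introduces derivative
  discontinuities exactly where trace species (O2 during the anoxic era)
  live, and collapses the step-size control - in development this meant
  more than 1e6 steps per model decade.  For the same reason the tabulated
  rate-limitation constant L = 1e-8 is kept in the parameter set but its
  multiplicative guard C/(C+L) is not applied: at geochemically meaningful
  concentrations the factor is 1 within 1e-8, its only effect being the
  harmful switch at the 1e-8 scale.  The non-negativity it is meant to
  enforce is already guaranteed by the rate laws.
* **C1 saturation kinetics.**  The $\max(\cdot,0)$ hinges of the mineral
  saturation laws are blended quadratically over a width of 0.1 in
  saturation index: exactly zero below the threshold, bounded curvature at
  it.
* **Tolerances and resolution.**  Defaults are rtol 1e-5, atol 1e-7 and
  120 grid cells - the smallest grid at which doubling the resolution moves
  the 2015 SOU and F_red by less than 2%, and tightening the tolerances
  tenfold moves them by well under 1% (both asserted in the tests).
  A full scenario chain (spin-up, history, four branches, seasonal leg and
  the sensitivity pair) runs in well under a minute.

For seasonal runs the cosine forcing is switched on in 2005 from the
non-seasonal state rather than carried through the whole history at
sub-monthly resolution: the boundary seasonality equilibrates in the upper
few centimetres within about two years, while the deep CH4-producing
strata evolve on decadal scales set by the (identical) annual-mean loads.
Snapshots are stored every 1/24 yr in the seasonal leg and annually
otherwise.

## Diagnostics

`flux_table()` evaluates the boundary-layer flux of every solute at each
snapshot and assembles SOU, the per-species O2-equivalent effluxes, F_red
and SOD.  F_red counts outward fluxes only: a reduced species diffusing
*into* the sediment (the M scenario keeps a finite CH4 bottom-water
concentration over a fully oxidized surface layer) is oxidized inside and
already charged to SOU.  Further diagnostics: Fick's-law flux estimation
from discrete profiles (`fick_flux_from_profile()`; window configurable,
default the top 2 cm - note that for species consumed in the oxic
surface layer the estimate is strongly window-dependent), the O2
penetration depth (threshold 0.1 umol L^-1), production attribution to
sediment age via the burial-history depth-age mapping
(`production_by_age()`, default bins 0-2, 2-20, >20 yr), element mass
balances over any window (`element_mass_balance()`), and the normalized
+/-1% sensitivity of the areal hypolimnetic mineralization output
(`sensitivity_AHM()`).  AHM itself is operationalized as SOD at the
evaluation year: F_red and SOU are its sediment-side components, and no
more specific definition is available for this configuration.

## Synthetic observations

`synthesize_porewater()` and `synthesize_bulk_toc()` emulate a seasonal
field campaign: four sampling months (March, June, September, November),
depth profiles over 0-30 cm at field-like resolution (0.5 cm slices in the
top 5 cm, 1 cm below), and multiplicative lognormal noise with unit mean
(default CV 0.15 for porewater solutes, 0.05 for bulk TOC, the spread
typical of such measurements).  The generator samples
the model's own seasonal profiles, so it reproduces the seasonal envelope
(largest near the surface) and the TOC structure including the buried
legacy-carbon bump, but none of the features of real data that the model
lacks: analytical biases, lateral heterogeneity among cores, ebullition
artefacts in CH4 sampling, or replicate structure.  Passing the
recovery tests therefore demonstrates identifiability under the model's own
assumptions, not field realism.

`parameter_recovery_experiment()` validates the trial-and-error
calibration logic: synthetic observations generated at a true parameter
value (reactive-TOC fraction, methanogenesis or oxic rate constant) are
scanned against a candidate grid under an identical design, using a
quasi-steady present-day column (boundaries frozen at 2015) to keep each
candidate run cheap.  With noise-free observations the recovery is exact;
at CV 0.15 the reactive fraction (true 2/3) is recovered within its
acceptance band.

## Worked example

```{r example, eval = FALSE}
library(sediagen)
cfg <- solver_config()          # 120 cells, compiled kernel
traj <- run_scenario("SQ", cfg) # spin-up + history + status quo to 2050
ft <- flux_table(traj)
ft[ft$year %in% c(2015, 2050), c("year", "SOU", "J_CH4", "J_NH4",
                                 "F_red", "SOD")]
production_by_age(traj, "CH4", 2015)
plot_fluxes(ft)
plot_profiles(traj, year = 2015)
```

## Known limitations

* The reaction network follows the standard early-diagenesis model family
  for this configuration; full stoichiometries of comparable models are
  rarely documented completely.  Reduced-substance fluxes can be evaluated
  either as post-oxidation boundary-layer effluxes (the package default)
  or as porewater-gradient (Fick) fluxes below the oxidation zone; for CH4
  the two differ by the ~20-30% that is oxidized within the sub-millimetre
  oxic skin, and gradient-based field estimates correspond to the latter.
  Both evaluations are available in the package.
* Porosity and burial velocity are depth-uniform; there is no compaction,
  no non-local irrigation, no ebullition (CH4 bubble transport), and no
  dynamic pH or full carbonate speciation.
* OM2 is strictly inert; anaerobic CH4 oxidation by Fe/Mn oxides or humics
  is not part of the network.
* Diffusivities are fixed at one reference temperature; no activity
  corrections.
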