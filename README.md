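# crocodiel

Diel carbon–nitrogen–oxygen–iron cell-flux simulation of the unicellular
marine diazotroph *Crocosphaera watsonii*.

*Crocosphaera* fixes N₂ with nitrogenase, an enzyme that O₂ destroys, in a
cell that photosynthesises O₂ all day and sits in near-air-saturated
seawater all night. `crocodiel` is a coarse-grained model of how the cell
manages this: daytime photosynthesis fills a carbon store C_S while iron
sits in the photosystems; after dark, iron moves through an intracellular
buffer into nitrogenase, and stored carbon is burned — partly as
*respiratory protection*, respiration whose purpose is to consume the
diffusive O₂ influx and hold the intracellular concentration at zero so
nitrogenase can work. The intracellular O₂ of a spherical cell is the
pseudo-steady diffusion–respiration balance

    [O2_cell] = [O2] − r² γ_net / (3 κ),

with an effective membrane-layer diffusivity κ = D_water(T)/(6.45·10⁴),
Arrhenius temperature factors f_T = exp(A_T (1/T_ref − 1/T)) on the
metabolic rates, and a saturating light response with hinge
photoinhibition, f_I = 1 − exp(−A_I·I) − s·max(0, I − I₀). N₂ fixation is
N2fix = A_N2fix · f_T · Fe_N · f(C_S) · (1 − N_S/NS_max) ·
(1 − [O2_cell]/[O2_cri]).

The package is aimed at people studying diazotroph physiology and its
environmental controls: it reproduces the canonical diel laboratory cycle
at the 20% (186 µM) and 5% (46 µM) O₂ treatments, the O₂-management
sensitivity scenarios (no size change, no respiratory protection,
*Azotobacter*-level membrane diffusivity), temperature and irradiance
scans of daily-integrated rates, and the measurement-side computations
(PSII electron transfer rate from FRR fluorometry, Eilers–Peeters
light-response fitting, acetylene-reduction conversion, parameter
calibration against diel observations).

## Worked example

```r
library(crocodiel)

p   <- croco_params()   # calibrated defaults
f20 <- croco_forcing(ambient_o2 = o2_treatment_concentration(0.20))
f5  <- croco_forcing(ambient_o2 = o2_treatment_concentration(0.05))

r20 <- run_diel(f20, p, dt = 0.02)
r5  <- run_diel(f5,  p, dt = 0.02)
r20
#> <croco_sim> default scenario
#>   6 day(s), periodic steady state (day-over-day change 4.21e-06), dt = 0.02 h
#>   final day: N2fix 4.390e-16 mol N cell-1 d-1, photo 4.206e-14 mol C cell-1 d-1, resp 7.739e-15 mol O2 cell-1 d-1
r5
#> <croco_sim> default scenario
#>   7 day(s), periodic steady state (day-over-day change 9.17e-05), dt = 0.02 h
#>   final day: N2fix 9.020e-16 mol N cell-1 d-1, photo 4.484e-14 mol C cell-1 d-1, resp 3.327e-15 mol O2 cell-1 d-1

first_o2_depletion_hour(r20)   # 16.94
first_o2_depletion_hour(r5)    # 12
```

Lights-on is clock hour 0 and darkness begins at hour 12. At 5% O₂ the
interior is anoxic from dark onset (hour 12) and the cell fixes
9.0·10⁻¹⁶ mol N cell⁻¹ d⁻¹; at 20% O₂ respiratory protection needs almost
5 h (hour 16.9) to eliminate intracellular O₂ — the observed delay in
fixation onset at air saturation — daily fixation is roughly halved, and
daily respiration is more than double that at 5% (7.7 vs
3.3 · 10⁻¹⁵ mol O₂ cell⁻¹ d⁻¹). Photosynthesis is nearly unchanged
between treatments.

Scenarios and scans:

```r
run_scenario("no_respiratory_protection", f20, p)  # fixation collapses
scan_forcing("temperature", 20:35, croco_forcing(), p)   # argmax ~30 degC
scan_forcing("irradiance", seq(0, 1000, 50), croco_forcing(), p)
```

Light-response fitting on the measurement side:

```r
E <- c(0, 20, 50, 100, 150, 200, 300, 450, 600, 800, 1100, 1500)
fit_eilers_peeters(E, eilers_peeters(E, 4e-6, 2.667e-3, 1))
#> <croco_pve_fit> Eilers-Peeters light response
#>   ETR_max = 150, alpha = 1, E_K = 150 (SSE 3.84e-14, n = 12)
```

A thin command-line front end lives in `inst/scripts/cfm_cell_model.R`
(`simulate`, `scan`, `etr-fit`, `fixtures` subcommands; YAML run
configuration, see `inst/extdata/run_canonical_20.yaml`).

## Package layout

* `R/environment.R` — forcing, temperature/light factors, O₂ solubility,
  Walden-rule diffusivity
* `R/oxygen.R` — diffusion–respiration balance and the dark-period solver
* `R/metabolism.R` — C/N fluxes: photosynthesis, fixation kinetics,
  biomass production, respiration components, growth dilution, cell-size
  acclimation
* `R/iron.R` — iron translocation schedule and chlorophyll coupling
* `R/simulator.R` — Euler stepper, periodic-steady-state driver,
  scenarios, scans
* `R/analysis.R`, `R/fixtures.R`, `R/calibrate.R` — ETR, Eilers–Peeters,
  acetylene conversion, synthetic data, calibration

The methods vignette (`vignettes/crocodiel-methods.Rmd`) documents the
model equations, the parameter defaults and their calibration rationale,
and the numerical choices.
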