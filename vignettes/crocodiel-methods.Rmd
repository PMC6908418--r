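---
title: "A diel carbon-nitrogen-oxygen-iron cell-flux model of Crocosphaera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A diel carbon-nitrogen-oxygen-iron cell-flux model of Crocosphaera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crocodiel)
```

## The problem

*Crocosphaera watsonii* is a unicellular marine cyanobacterium that both
photosynthesises and fixes N~2~. The two processes are chemically
incompatible: nitrogenase is inactivated by O~2~, while photosynthesis
produces it. The organism separates them in time — C fixation by day, N~2~
fixation by night — but the surface ocean stays near air saturation
(~200 µM O~2~) around the clock, so even at night the cell faces a steady
diffusive O~2~ influx that must be eliminated before nitrogenase can work.

`crocodiel` implements a coarse-grained cell-flux model of this daily
cycle. A cell is described by a carbon store $C_S$ (glycogen/starch built
by daytime photosynthesis), a nitrogen store $N_S$ (built by nighttime
fixation), three iron pools — photosystems $Fe_P$, an intracellular buffer
$Fe_B$ (ferritin-like storage), and nitrogenase $Fe_N$ — chlorophyll tied
to $Fe_P$, and a population density $X$. Total cellular iron is constant;
what changes over the day is its allocation, and the allocation is what
couples the C, N and O~2~ budgets: photosynthesis is proportional to
chlorophyll (hence $Fe_P$), N~2~ fixation to nitrogenase (hence $Fe_N$).

## State equations

Per-cell pools evolve by forward-Euler integration of

$$\frac{dC_S}{dt} = P - \lambda(1+E) - P_{CO_2}^{N_2fix} - P_{CO_2}^{RP}
  - M - Exc, \qquad
  \frac{dN_S}{dt} = N_2fix - \lambda\,Y^{N:C}_{bio}, \qquad
  \frac{dX}{dt} = X\,\lambda / Q_C,$$

with $P$ gross photosynthesis, $\lambda$ biomass production (its C cost is
$\lambda(1+E)$ with biosynthetic CO~2~ overhead $E$), $P_{CO_2}^{N_2fix}$
the C cost of fixation, $P_{CO_2}^{RP}$ respiratory protection, $M$ basal
maintenance, and $Exc$ overflow excretion. Division is continuous: new
cells carry the quota $Q_C$, and per-cell stores are diluted so that
population-level mass is conserved exactly. Iron moves by first-order
transfers routed through the buffer,

$$\frac{dFe_P}{dt} = F_{BP} - F_{PB},\quad
  \frac{dFe_B}{dt} = -F_{BP} + F_{PB} - F_{BN} + F_{NB},\quad
  \frac{dFe_N}{dt} = F_{BN} - F_{NB},$$

and chlorophyll follows photosystem iron with a fixed yield,
$dChl/dt = (F_{BP}-F_{PB})\,Y^{Chl:Fe}$.

Phase rules: in the light $N_2fix$, $P_{CO_2}^{N_2fix}$, $P_{CO_2}^{RP}$
and $F_{BN}$ are zero; in the dark $P$, $\lambda$, $Exc$ and $F_{BP}$ are
zero. Iron scheduling in the light builds photosystems from the buffer
until a target, returning iron to the buffer once $C_S$ crosses a fraction
of its capacity (there is no benefit to further photosynthesis when the
store is nearly full); in the dark idle photosystems release iron to the
buffer and the buffer feeds nitrogenase until a fixed clock hour
(`t_NB_start`, default 22 h — 2 h before dawn), after which nitrogenase is
torn down. The teardown hour is clock-based because the observed Fe
transfer behaves circadianly (fixation drops at the same hour regardless
of the O~2~ treatment).

## Intracellular oxygen

O~2~ equilibrates much faster than the metabolite pools, so the model
treats it as pseudo-steady: at every step, diffusive influx and metabolic
consumption balance. For a spherical cell of radius $r$ with effective
membrane-layer diffusivity $\kappa$,

$$[O_2^{cell}] = [O_2] - \frac{r^2\,\gamma_{net}}{3\kappa},$$

floored at zero; equivalently the maximal per-cell O~2~ uptake is
$4\pi r \kappa [O_2]$. The effective diffusivity is a fixed fraction of
the diffusivity of O~2~ in water (default $1/(6.45\times10^4)$; the value
inferred for *Azotobacter*, $1/(1.27\times10^3)$, is the
`high_diffusivity` scenario), with the water value scaled in temperature
by Walden's rule $D \propto T/\mu(T)$ using a Vogel-type viscosity
correlation ($\mu = 2.414\times10^{-5} \cdot 10^{247.8/(T-140)}$ Pa s).

N~2~ fixation follows
$N_2fix = A_{N_2fix}\, f_T\, Fe_N \cdot \frac{C_S}{C_S+K_{CS}} \cdot
\max\!\left(0, 1-\frac{N_S}{N_S^{max}}\right) \cdot
\max\!\left(0, 1-\frac{[O_2^{cell}]}{[O_2^{cri}]}\right)$ — linear in
nitrogenase, saturating in the C fuel, product-inhibited by stored N, and
linearly inhibited by intracellular O~2~ up to a critical concentration
$[O_2^{cri}]$ (60 µM by calibration) above which fixation stops.

In the dark these quantities are mutually dependent: fixation is inhibited
by O~2~, the O~2~-consuming part of fixation's respiration lowers O~2~,
and respiratory protection tops O~2~ consumption up toward the influx
ceiling, limited by a capacity
$R_{max} f_T\, C_S/(C_S+K_{CS})$. `solve_dark_o2_state()` finds the
self-consistent state by damped fixed-point iteration from an anoxic
initial guess. Two numerical details matter. First, the balance map's
slope passes through one exactly at the onset of self-sustained anoxia
(where fixation begins to bootstrap its own O~2~ removal), where plain
damping stalls; the solver therefore applies Aitken extrapolation when a
slope estimate is available and safe, and falls back to bisection of the
bracketed residual — which cannot fail on this continuous map — if the
iteration has not converged in 100 steps. Second, when the kinetic O~2~
demand exceeds the diffusive ceiling, the O~2~ books are closed at the
ceiling (the cell is O~2~-limited) while the CO~2~ books retain the full
substrate cost; the energetic shortfall is implicitly non-respiratory.

The split matters at low ambient O~2~: only a fraction
(`resp_o2_frac`, default 0.15) of fixation's C cost $Y^{C:N}_{resp}$
consumes O~2~ as respiratory ATP production; the remainder represents
electron donation to nitrogenase and substrate-level CO~2~ release. Were
the cost fully aerobic, fixation at the 5% O~2~ treatment would be capped
by a diffusive O~2~ influx twenty times smaller than at air saturation,
contradicting the observation that low-O~2~ cultures fix *more*.

Basal maintenance $M = m\,f_T$ is likewise treated as substrate-level
carbon expenditure: its O~2~ demand is negligible beside the protection
fluxes, but its carbon demand is not, and because it scales with the
Arrhenius factor while the diffusive O~2~ ceiling (and hence the
O~2~-limited night respiration) is nearly temperature-flat, maintenance is
what makes the nighttime carbon budget bind as temperature rises. This is
the model's high-temperature brake: above the optimum, storage is
exhausted before dawn, the protection capacity collapses with
$C_S/(C_S+K_{CS})$, intracellular O~2~ rebounds, and fixation loses the
remainder of the night. Without a temperature-scaled carbon sink outside
the O~2~ envelope, daily fixation can be shown to be monotone increasing
in $f_T$ — no parameter choice produces the observed optimum.

## Temperature, light, oxygen management

The Arrhenius factor $f_T = \exp(A_T(1/T_{ref} - 1/T))$ (reference
28 °C) multiplies fixation kinetics, photosynthesis, and the respiratory
terms; a three-way mask (`temp_mask`) switches it per process for the
decomposition scenarios. The light response is
$f_I = \mathrm{clip}(1 - e^{-A_I I} - \Omega(I),\,0,\,1)$ with a hinge
photoinhibition term $\Omega = s\,\max(0, I - I_0)$, zero below the onset
$I_0$ and linear above.

Gross photosynthesis is $P = P^{Chl}_{max} f_I f_T\, Chl$. It is not
throttled directly by a full C store: light capture and electron transport
continue (measured daytime electron transfer rates keep rising toward
~700 µmol m^-2^ s^-1^), and the surplus that cannot enter storage is
excreted (`Exc`), while the sustained regulatory response is the
withdrawal of iron from photosystems. This overflow formulation is what
lets daily gross photosynthesis track $f_I$ in light scans instead of
being capped at the community's consumption.

Cell size acclimates to ambient O~2~ through a piecewise-linear map
between two anchors (2.0 µm at 46 µM, 2.5 µm at 186 µM): larger cells
have a smaller surface-to-volume ratio and thus a smaller volumetric O~2~
load. Scenario patches turn each O~2~-management strategy off:
`no_size_change` (radius pinned at the low-O~2~ anchor — identical to the
default at 46 µM by construction), `no_respiratory_protection`
($R_{max}=0$; at air saturation intracellular O~2~ then never falls below
the critical level and fixation is abolished, while at 5% O~2~ fixation's
own respiration still suffices), and `high_diffusivity` (the
*Azotobacter* membrane factor; the interior never reaches anoxia and
respiration is much elevated at 5%).

## Parameters

The physical constants ($\kappa$ ratios, solubilities, the conversion of
the 20% and 5% sparging treatments to 186 and 46 µM at 28 °C and salinity
35 — pinned exactly, with a rescaled Garcia-Gordon fit supplying the
temperature dependence elsewhere) come from the literature values quoted
above. The cellular rate constants and capacities are not published as a
table; they were fixed once, jointly, so that the model reproduces the
reported system-level behaviour at the laboratory conditions (square
12L:12D, 150 µmol m^-2^ s^-1^, 28 °C):

* intracellular O~2~ reaches zero essentially at dark onset at 46 µM but
  only ~3–5 h into the night at 186 µM (the observed fixation delay);
* daily fixation at 46 µM exceeds that at 186 µM, while dark-period
  respiration is higher at 186 µM (respiratory protection);
* daily-integrated fixation over a 20–35 °C scan peaks near 30 °C and
  collapses toward ~25 °C and below;
* daily photosynthesis over a light scan peaks near 700 µmol m^-2^ s^-1^
  and fixation saturates near 100 µmol m^-2^ s^-1^;
* division rates of ~0.1–0.2 d^-1^ and pool sizes (quota
  $Q_C = 3\times10^{-14}$ mol C, C-storage capacity
  $2.55\times10^{-14}$ mol C, total Fe $10^{-18}$ mol) in the range
  reported for this organism.

Notable calibrated values: $A_T = 15000$ K. As a Q~10~ this is high
(~5), but the organism's observed thermal response is extreme — fixation
drops from its maximum near 30 °C to almost nothing by 22 °C — and in the
model the steep emergent response arises jointly from $f_T$ and the
O~2~-threshold amplification (capacity falls below the influx requirement,
intracellular O~2~ rises above critical, fixation stops entirely).
$A_{N_2fix} = 600$ mol N (mol Fe)^-1^ h^-1^, $Y^{C:N}_{resp} = 12$ mol C
(mol N)^-1^ total with 15% aerobic, $R_{max} = 6.3\times10^{-16}$ mol O~2~
cell^-1^ h^-1^ (about 0.8 of the 186-µM diffusive ceiling at 28 °C — the
gap is what delays anoxia until nitrogenase has been built), and
$m = 9.6\times10^{-16}$ mol C cell^-1^ h^-1^ maintenance.

## Numerical choices

* Explicit forward Euler, default `dt = 0.01` h, with the step grid split
  exactly at the light/dark boundary. Halving the step changes daily
  integrals by well under 1%.
* Per-step flux limiting keeps every pool non-negative (scaling the dark
  fluxes proportionally when storage would be overdrawn) and iron updates
  are written as paired transfers so total iron is conserved to machine
  precision over arbitrarily long runs.
* Periodic steady state: the run stops when the maximum day-over-day
  relative change of the per-cell state at matched clock times falls below
  `tol = 1e-4` (population density compared through its within-day growth
  profile), up to `max_days = 60`; typical runs converge in 6–20 days, and
  some strongly C-limited regimes approach the orbit through a weak
  period-two alternation of amplitude below ~1%. Scan summaries therefore
  average the last two simulated days, which cancels the alternation
  exactly. The light-phase iron switches use narrow continuous ramps (5%
  of the storage capacity; 10% of the photosystem target) rather than hard
  on/off triggers, which would otherwise lock the orbit into larger
  period-two flip-flops.
* The dawn-start initial condition (iron all in the buffer, stores at half
  capacity) is erased by convergence to the periodic orbit.

## Measurement-side toolkit

`etr()` computes the PSII electron transfer rate from fast-repetition-rate
fluorometry quantities, $ETR = \sigma_{PSII}\, n_{PSII}\,
(F_q'/F_v')\, \Phi_{RCII}\, E$ with $F_q' = F_m' - F'$ and $F_v' = F_m' -
F_o'$; units are relative and follow the inputs, since the absolute
normalisation of $\sigma_{PSII}$ and $n_{PSII}$ is instrument-dependent.
`fit_eilers_peeters()` fits $ETR(E) = E/(aE^2+bE+c)$ by
Levenberg-Marquardt on log-coefficients from a small multistart, and
reports $ETR_{max} = 1/(b+2\sqrt{ac})$, $\alpha = 1/c$ and
$E_K = ETR_{max}/\alpha$. `acetylene_to_n2()` converts
acetylene-reduction (ethylene) rates with the theoretical 3:1
C~2~H~4~:N~2~ factor. `calibrate()` minimises an sd-weighted least-squares
objective over the five diel observation channels and both O~2~
treatments with derivative-free searches (golden-section on a log scale
for one parameter, Nelder-Mead on log-parameters otherwise).

## Synthetic data, and what the tests do and do not show

`generate_fixtures()` creates the data sets the test suite closes its
loops on: diel series sampled hourly from the simulator at known ("true")
parameters for both O~2~ treatments with seeded relative Gaussian noise
(default 10%, comparable to the scatter of published diel culture
measurements), and light-response curves from known Eilers-Peeters
coefficients. Because the generator *is* the model, recovery tests
demonstrate identifiability and correctness of the fitting machinery —
that the membrane factor is recoverable to a few percent from noiseless
series and to ~20% from 10% noise — not that the model is structurally
correct for real cultures. Real data bring features the generator omits:
non-Gaussian and autocorrelated errors, cell-cycle heterogeneity,
acetylene-assay conversion uncertainty, and day-to-day drift of the
culture state.

The test suite runs the simulator at coarser resolution than production
(`dt = 0.02`–0.05 h, shortened horizons for the calibration loops); the
dt-halving test ties these settings to the production default.

## Known limitations

* Ambient O~2~ is constant within a run; diel fluctuations of ~10 µM in
  the field are not represented.
* The O~2~ balance folds boundary layer and membrane into one effective
  resistance; a series formulation would separate them.
* Iron exchange is strictly buffer-mediated with first-order kinetics and
  one clock-based switch; the real regulation is richer, and the model
  does not resolve nitrogenase subunit assembly.
* Photoinhibition acts only on photosynthesis; the observed decline of
  fixation itself under very high light (direct damage to nitrogenase
  synthesis) is deliberately not modelled, so light scans of fixation
  plateau rather than decline.
* Fixed stoichiometric quotients (PQ = RQ = 1 mol O~2~ per mol C) and a
  fixed biomass N:C of 0.15.
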