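#' Cell state constructor
#'
#' Per-cell pools and population density for the flux model. Iron is
#' partitioned among photosystems (`FeP`), an intracellular buffer (`FeB`,
#' e.g. ferritin/bacterioferritin) and nitrogenase (`FeN`); their sum is
#' conserved throughout a run. Chlorophyll is tied to photosystem iron.
#'
#' @param CS C storage (mol C cell-1).
#' @param NS N storage (mol N cell-1).
#' @param FeP,FeB,FeN Iron pools (mol Fe cell-1).
#' @param Chl Chlorophyll (mol Chl cell-1).
#' @param X Population density (cells m-3).
#' @param r Cell radius (m).
#' @param O2cell Diagnostic intracellular O2 (mol O2 m-3).
#' @return Named numeric vector of class `croco_state`.
#' @export
croco_state <- function(CS, NS, FeP, FeB, FeN, Chl, X = 1e11, r = 2.5e-6,
                        O2cell = 0) {
  v <- c(CS = CS, NS = NS, FeP = FeP, FeB = FeB, FeN = FeN, Chl = Chl,
         X = X, r = r, O2cell = O2cell)
  if (any(v[c("CS", "NS", "FeP", "FeB", "FeN", "Chl", "X")] < 0))
    stop("pools must be >= 0")
  if (r <= 0) stop("radius must be > 0")
  structure(v, class = "croco_state")
}

## Temperature factors per process, honouring the selective mask used in the
## temperature-decomposition experiments.
.phase_temp_factors <- function(temperature, p) {
  fT <- temperature_factor(temperature, p$env)
  m <- p$met$temp_mask
  list(n2fix = if (isTRUE(m[["n2fix"]])) fT else 1,
       photo = if (isTRUE(m[["photo"]])) fT else 1,
       resp  = if (isTRUE(m[["resp"]]))  fT else 1)
}

#' Nitrogen fixation kinetics
#'
#' `N2fix = A_N2fix * f_T * FeN * fN(CS, NS, O2cell)` where the limitation
#' term is the product of a Michaelis-Menten factor in C storage (fixation is
#' fuelled by stored carbohydrate), a linear decline in N storage reaching
#' zero at capacity `NSmax` (product inhibition by accumulated fixed N), and
#' a linear decline in intracellular O2 reaching zero at the critical
#' concentration `O2cri` (nitrogenase inactivation). The rate is linear in
#' nitrogenase iron `FeN`; each limitation factor is clipped to \[0, 1\].
#'
#' @param FeN Nitrogenase iron (mol Fe cell-1).
#' @param CS C storage (mol C cell-1).
#' @param NS N storage (mol N cell-1).
#' @param O2cell Intracellular O2 (mol O2 m-3).
#' @param temperature Absolute temperature (K).
#' @param p A [croco_params()].
#' @return Fixation rate (mol N cell-1 h-1).
#' @export
n2_fixation_rate <- function(FeN, CS, NS, O2cell, temperature, p) {
  if (any(c(FeN, CS, NS, O2cell) < 0)) stop("pools must be >= 0")
  fT <- .phase_temp_factors(temperature, p)$n2fix
  f_cs <- CS / (CS + p$met$K_CS)
  f_ns <- pmax(0, 1 - NS / p$met$NSmax)
  f_o2 <- pmax(0, 1 - O2cell / p$met$O2cri)
  p$met$A_N2fix * fT * FeN * f_cs * f_ns * f_o2
}

#' Gross photosynthesis rate
#'
#' Carbon fixation per cell: `P = P_max_chl * f_I(I) * f_T(T) * Chl`
#' (mol C cell-1 h-1). The rate is proportional to chlorophyll, which the
#' iron module ties to photosystem Fe, and zero in the dark. Gross fixation
#' is not shut down by a full C store: the surplus that cannot enter storage
#' is excreted (see [excretion_rate()]), and the sustained storage response
#' is the withdrawal of photosystem iron once C storage approaches capacity.
#' The associated O2 evolution is `P * PQ` (photosynthetic quotient, default
#' 1 mol O2 per mol C).
#'
#' @param Chl Chlorophyll (mol Chl cell-1).
#' @param irradiance Photon flux (umol m-2 s-1).
#' @param temperature Absolute temperature (K).
#' @param p A [croco_params()].
#' @return Gross C fixation rate (mol C cell-1 h-1).
#' @export
photosynthesis_rate <- function(Chl, irradiance, temperature, p) {
  if (any(Chl < 0)) stop("Chl must be >= 0")
  fI <- light_factor(irradiance, p$env)
  fT <- .phase_temp_factors(temperature, p)$photo
  p$met$P_max_chl * fI * fT * Chl
}

#' Biomass production rate
#'
#' Light-phase only: `lambda = lambda_max * f_T * CS/(CS+K_CS) *
#' NS/(NS+K_NS)`; zero in the dark. Biomass production consumes C storage at
#' `lambda * (1 + E)` (the overhead `E` is biosynthetic CO2) and N storage at
#' `lambda * Y_bio_NC`; the N source is storage only.
#'
#' @param CS,NS Storage pools (mol cell-1).
#' @param temperature Absolute temperature (K).
#' @param phase `"light"` or `"dark"`.
#' @param p A [croco_params()].
#' @return Biomass production rate lambda (mol C cell-1 h-1).
#' @export
biomass_production_rate <- function(CS, NS, temperature, phase, p) {
  phase <- match.arg(phase, c("light", "dark"))
  if (phase == "dark") return(0)
  fT <- .phase_temp_factors(temperature, p)$resp
  p$met$lambda_max * fT * (CS / (CS + p$met$K_CS)) * (NS / (NS + p$met$K_NS))
}

#' Respiration flux breakdown
#'
#' Collects the CO2-producing fluxes: biosynthetic overhead `E * lambda`,
#' fixation-coupled CO2 `Y_resp_CN * n2fix` (electron donation to nitrogenase
#' plus respiratory ATP production), basal maintenance carbon expenditure,
#' and respiratory protection `RP`. The O2 drawdown counts only the
#' O2-consuming part: biosynthetic overhead and `RP` at the respiratory
#' quotient plus the fraction `resp_o2_frac` of the fixation-coupled term;
#' electron donation to N2 and the substrate-level maintenance loss produce
#' CO2 without consuming O2.
#'
#' @param lambda Biomass production rate (mol C cell-1 h-1).
#' @param n2fix N2 fixation rate (mol N cell-1 h-1).
#' @param RP Respiratory-protection flux (mol C cell-1 h-1), from the dark
#'   O2 solver.
#' @param p A [croco_params()].
#' @param maint Realised maintenance respiration (mol C cell-1 h-1).
#' @return List with `biosynthetic` (E*lambda), `PCO2N2fix`, `PCO2RP`,
#'   `maint`, `resp_co2` (their sum) and `resp_o2` (O2-consuming total,
#'   mol O2 cell-1 h-1).
#' @export
respiration_fluxes <- function(lambda, n2fix, RP, p, maint = 0) {
  if (any(c(lambda, n2fix, RP, maint) < 0)) stop("rates must be >= 0")
  bio <- p$met$E * lambda
  pn2 <- p$met$Y_resp_CN * n2fix
  list(biosynthetic = bio, PCO2N2fix = pn2, PCO2RP = RP, maint = maint,
       resp_co2 = bio + pn2 + maint + RP,
       resp_o2 = p$met$RQ * (bio + p$met$resp_o2_frac * pn2 + RP))
}

#' Overflow excretion of fixed carbon
#'
#' The fraction of gross photosynthesis that cannot enter a full C store is
#' excreted (e.g. as extracellular polymeric substances). Zero whenever the
#' store has room; equal to the full gross rate when the store is at
#' capacity. Dark-phase excretion is zero because photosynthesis is.
#'
#' @param photo Gross photosynthesis (mol C cell-1 h-1).
#' @param CS Current C storage (mol C cell-1).
#' @param room_rate Storage uptake the pool can absorb this step
#'   (mol C cell-1 h-1), i.e. remaining capacity divided by the step length.
#' @param p A [croco_params()].
#' @return Excretion rate (mol C cell-1 h-1).
#' @export
excretion_rate <- function(photo, CS, room_rate, p) {
  if (CS >= p$met$CSmax) return(photo)
  max(0, photo - room_rate)
}

#' Growth and storage dilution
#'
#' Biomass production makes new cells: `X <- X * (1 + lambda/Q_C * dt)`.
#' Per-cell storage pools are diluted by the same factor so that
#' population-level storage `X * CS` and `X * NS` are conserved by division
#' itself. Iron pools and chlorophyll are not diluted: total cellular iron is
#' held constant (implicit uptake balances growth).
#'
#' @param state Named vector/list with `X`, `CS`, `NS` (other entries pass
#'   through).
#' @param lambda Biomass production rate (mol C cell-1 h-1).
#' @param dt Time step (h), > 0.
#' @param p A [croco_params()].
#' @return The state with `X`, `CS`, `NS` updated.
#' @export
growth_and_dilution <- function(state, lambda, dt, p) {
  if (dt <= 0) stop("dt must be > 0")
  g <- 1 + lambda / p$met$Q_C * dt
  state[["X"]] <- state[["X"]] * g
  state[["CS"]] <- state[["CS"]] / g
  state[["NS"]] <- state[["NS"]] / g
  state
}

#' Cell radius acclimated to ambient O2
#'
#' Cells acclimate to higher ambient O2 by growing larger, decreasing their
#' surface-to-volume ratio and hence the volumetric O2 load. Piecewise-linear
#' interpolation between two anchors (radius at the low-O2 and high-O2
#' treatments), clamped outside; monotone non-decreasing in ambient O2. When
#' the no-size-change scenario fixes the radius (`cell$radius_fixed`), that
#' value is returned for all inputs.
#'
#' @param o2_env Ambient O2 (mol m-3).
#' @param p A [croco_params()].
#' @return Radius (m).
#' @export
cell_radius_for_o2 <- function(o2_env, p) {
  if (any(o2_env < 0)) stop("o2_env must be >= 0")
  cc <- p$cell
  if (!is.na(cc$radius_fixed)) return(rep(cc$radius_fixed, length(o2_env)))
  w <- (o2_env - cc$o2_anchor_low) / (cc$o2_anchor_high - cc$o2_anchor_low)
  w <- pmin(1, pmax(0, w))
  cc$r_lowO2 + w * (cc$r_highO2 - cc$r_lowO2)
}
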