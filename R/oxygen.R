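#' Effective O2 diffusivity of the cell membrane layers
#'
#' The diffusion-respiration balance uses a single effective diffusivity that
#' folds the molecular boundary layer and the semipermeable membrane layers
#' into one coefficient, taken proportional to the diffusivity of O2 in water:
#' `kappa(T) = membrane_factor * D_water(T)`. The default factor 1/(6.45e4)
#' is the value required to reproduce the observed diel O2 fluxes; the
#' high-diffusivity sensitivity scenario uses 1/(1.27e3), the cell-wall
#' permeability inferred for *Azotobacter vinelandii*.
#'
#' @param temperature Absolute temperature (K).
#' @param p Parameter list with `D_ref`, `T_ref_D`, `membrane_factor`
#'   (the `diff` block of [croco_params()]).
#' @return Effective diffusivity (m2 s-1).
#' @export
effective_diffusivity <- function(temperature, p) {
  if (p$membrane_factor <= 0 || p$membrane_factor > 1)
    stop("membrane_factor must lie in (0, 1]")
  water_o2_diffusivity(temperature, p) * p$membrane_factor
}

#' Intracellular O2 of a respiring spherical cell
#'
#' Pseudo-steady balance of diffusive influx against volumetric net
#' consumption over a sphere:
#' `[O2cell] = [O2] - r^2 * gamma_net / (3 * kappa)`, floored at zero. The
#' result never exceeds the ambient concentration.
#'
#' @param o2_env Ambient O2 (mol O2 m-3).
#' @param r Cell radius (m), > 0.
#' @param gamma_net Net volumetric O2 consumption (mol O2 m-3 s-1), >= 0.
#' @param kappa Effective diffusivity (m2 s-1), > 0.
#' @return Intracellular O2 concentration (mol O2 m-3).
#' @export
#' @examples
#' intracellular_o2(0.186, 2.5e-6, 0, 3.5e-14)  # no consumption: ambient
intracellular_o2 <- function(o2_env, r, gamma_net, kappa) {
  if (any(o2_env < 0) || any(gamma_net < 0)) stop("inputs must be >= 0")
  if (any(r <= 0)) stop("cell radius must be > 0")
  if (any(kappa <= 0)) stop("kappa must be > 0")
  pmin(o2_env, pmax(0, o2_env - r^2 * gamma_net / (3 * kappa)))
}

#' Net volumetric respiration that exactly depletes intracellular O2
#'
#' Rearranging the diffusion-respiration balance, the volumetric consumption
#' rate driving intracellular O2 to zero is `3 * kappa * [O2] / r^2`. Scales
#' inversely with the square of the radius: larger cells need proportionally
#' less volumetric respiration to stay anoxic inside.
#'
#' @inheritParams intracellular_o2
#' @return Volumetric consumption rate (mol O2 m-3 s-1).
#' @export
critical_volumetric_respiration <- function(o2_env, r, kappa) {
  if (any(o2_env < 0)) stop("o2_env must be >= 0")
  if (any(r <= 0)) stop("cell radius must be > 0")
  if (any(kappa <= 0)) stop("kappa must be > 0")
  3 * kappa * o2_env / r^2
}

## Maximum per-cell diffusive O2 influx (mol O2 cell-1 h-1), i.e. the influx
## when the interior is held at zero: 4 pi r kappa [O2] * 3600.
.o2_influx_max <- function(o2_env, r, kappa) {
  4 * pi * r * kappa * o2_env * 3600
}

#' Self-consistent dark-period O2 state
#'
#' During the dark period the intracellular O2 concentration, the rate of N2
#' fixation and the respiratory fluxes are mutually dependent: fixation is
#' inhibited by intracellular O2, fixation drives respiration (its
#' O2-consuming energetic fraction), basal maintenance carbon loss proceeds
#' at its temperature-scaled rate (substrate-level, drawing no O2), and
#' total O2-consuming respiration sets the intracellular O2 through the
#' diffusion balance. Respiratory protection
#' tops respiration up toward the rate that would hold the interior at zero,
#' limited by a temperature- and C-storage-dependent capacity
#' `R_max * f_T(T) * C_S / (C_S + K_CS)`. The solver finds the fixed point by
#' damped iteration (damping 0.5, initial guess `O2cell = 0`, relative
#' tolerance 1e-8, at most 100 iterations), with Aitken acceleration when the
#' local contraction slope approaches one (the map's slope passes through 1
#' exactly at the onset of self-sustained anoxia, where plain damping
#' stalls). When the map sits above the identity with near-unit slope the
#' solution lies on the fixation-free branch and the iterate jumps there.
#'
#' At the returned state the O2 budget closes: total O2 consumption equals
#' the diffusive influx at the returned intracellular concentration.
#'
#' @param state Named list or vector with pools `CS`, `NS`, `FeN` and radius
#'   `r` (m).
#' @param f A [croco_forcing()]; supplies ambient O2 and temperature.
#' @param p A [croco_params()].
#' @return List with `O2cell` (mol m-3), `n2fix` (mol N cell-1 h-1), `RP`
#'   (respiratory-protection flux, mol C cell-1 h-1), `maint` (mol C cell-1
#'   h-1), `resp_o2` (mol O2 cell-1 h-1), `resp_co2` (mol C cell-1 h-1),
#'   `v_o2` (diffusive influx, mol O2 cell-1 h-1), `influx_max`,
#'   `capacity`, `iterations`, `residual`.
#' @export
solve_dark_o2_state <- function(state, f, p) {
  st <- as.list(state)
  kappa <- effective_diffusivity(f$temperature, p$diff)
  req <- .o2_influx_max(f$ambient_o2, st$r, kappa)
  fT <- .phase_temp_factors(f$temperature, p)
  cs_fac <- st$CS / (st$CS + p$met$K_CS)
  cap <- p$met$R_max * fT$resp * cs_fac
  ## kinetic fixation ceiling at zero intracellular O2
  fix0 <- n2_fixation_rate(st$FeN, st$CS, st$NS, 0, f$temperature, p)
  rhoY <- p$met$resp_o2_frac * p$met$Y_resp_CN
  ## maintenance is not storage-throttled: it draws on C until the store is
  ## actually empty (the stepper limits fluxes to available C)
  mnt <- if (st$CS > 0) p$met$maint * fT$resp else 0

  step_map <- function(o2) {
    fix <- fix0 * max(0, 1 - o2 / p$met$O2cri)
    demand <- rhoY * fix  # maintenance C loss is substrate-level, no O2 draw
    rp <- min(max(0, req - demand), cap)
    o2_new <- if (req > 0) {
      max(0, f$ambient_o2 * (1 - (demand + rp) / req))
    } else 0
    list(o2 = o2_new, fix = fix, rp = rp, demand = demand)
  }

  o2 <- 0
  scale <- max(f$ambient_o2, 1e-12)
  it <- 0L
  converged <- FALSE
  o2_prev <- NA_real_
  F_prev <- NA_real_
  repeat {
    it <- it + 1L
    m <- step_map(o2)
    if (abs(m$o2 - o2) < 1e-8 * scale) { converged <- TRUE; break }
    if (it >= 100L) break
    slope <- if (!is.na(o2_prev) && abs(o2 - o2_prev) > 0)
      (m$o2 - F_prev) / (o2 - o2_prev) else NA_real_
    o2_prev <- o2; F_prev <- m$o2
    if (!is.na(slope) && is.finite(slope) && slope < 0.99) {
      ## Aitken step: exact for the locally linear map
      o2 <- min(scale, max(0, o2 + (m$o2 - o2) / (1 - slope)))
    } else if (!is.na(slope) && is.finite(slope) && m$o2 > o2) {
      ## near-unit slope above the identity: solution is fixation-free
      o2 <- max(o2, p$met$O2cri)
    } else {
      o2 <- o2 + 0.5 * (m$o2 - o2)
    }
  }
  if (!converged) {
    ## Safeguarded fallback: the map is continuous on [0, ambient] with
    ## F(0) >= 0 and F(ambient) <= ambient, so a self-consistent state is
    ## bracketed; bisection on F(x) - x cannot fail. The accelerated
    ## iteration only stalls when the fixed point sits on the kink at the
    ## critical O2 concentration.
    lo <- 0; hi <- scale
    glo <- step_map(lo)$o2 - lo
    if (glo <= 0) {
      o2 <- 0
    } else {
      for (k in seq_len(200)) {
        mid <- 0.5 * (lo + hi)
        gmid <- step_map(mid)$o2 - mid
        if (abs(gmid) < 1e-10 * scale) break
        if (gmid > 0) lo <- mid else hi <- mid
      }
      o2 <- mid
    }
    m <- step_map(o2)
    if (abs(m$o2 - o2) > 1e-6 * scale)
      stop(sprintf(paste0("dark O2 solver did not converge: last O2cell = ",
                          "%.3e, residual = %.3e"), o2, abs(m$o2 - o2)))
  }
  o2 <- m$o2  # exact fixed point of the final iterate
  fix <- m$fix
  rp <- m$rp
  demand <- m$demand
  resp_o2 <- min(demand + rp, req)  # O2 drawdown cannot exceed influx
  resp_co2 <- p$met$Y_resp_CN * fix + mnt + rp
  v_o2 <- resp_o2
  influx_at_state <- req * (1 - o2 / max(f$ambient_o2, 1e-300))
  list(O2cell = o2, n2fix = fix, RP = rp, maint = mnt,
       resp_o2 = resp_o2, resp_co2 = resp_co2, v_o2 = v_o2,
       influx_max = req, capacity = cap, iterations = it,
       residual = abs(resp_o2 - influx_at_state))
}
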