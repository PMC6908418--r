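#' Advance the cell state by one time step
#'
#' Evaluates the phase-appropriate fluxes (light: photosynthesis, biomass
#' production, excretion; dark: N2 fixation, fixation-coupled respiration and
#' respiratory protection via the pseudo-steady O2 solver), applies the iron
#' translocation and chlorophyll update, storage updates with overflow/
#' depletion limiting, and growth dilution. The step must not straddle a
#' light/dark boundary; [run_diel()] splits steps at the boundary.
#'
#' @param state Named numeric vector (see [croco_state()]).
#' @param t Clock hour at the start of the step, in \[0, 24).
#' @param dt Step length (h), > 0.
#' @param f A [croco_forcing()].
#' @param p A [croco_params()].
#' @return List with `state` (advanced) and `flux`, a named vector of the
#'   instantaneous rates over the step: `photo_c`, `photo_o2`, `resp_o2`,
#'   `resp_co2`, `n2fix`, `v_o2`, `exc`, `lambda`, `RP`, `PCO2N2fix`,
#'   `maint`, `O2cell`.
#' @export
step_cell <- function(state, t, dt, f, p) {
  if (dt <= 0) stop("dt must be > 0")
  L <- f$photoperiod_light_h
  phase <- if (t < L) "light" else "dark"
  CS <- state[["CS"]]; NS <- state[["NS"]]
  met <- p$met
  kappa <- effective_diffusivity(f$temperature, p$diff)
  req <- .o2_influx_max(f$ambient_o2, state[["r"]], kappa)

  if (phase == "light") {
    irr <- diel_irradiance(t, f)
    photo <- photosynthesis_rate(state[["Chl"]], irr, f$temperature, p)
    lambda <- biomass_production_rate(CS, NS, f$temperature, "light", p)
    mnt <- if (CS > 0) {
      met$maint * .phase_temp_factors(f$temperature, p)$resp
    } else 0
    ## keep storage pools non-negative within the step
    if (lambda > 0 || mnt > 0) {
      lim_c <- (CS + photo * dt) / ((lambda * (1 + met$E) + mnt) * dt)
      if (is.finite(lim_c) && lim_c < 1) { lambda <- lambda * lim_c
                                           mnt <- mnt * lim_c }
      lim_n <- if (lambda > 0) NS / (lambda * met$Y_bio_NC * dt) else Inf
      if (lim_n < 1) lambda <- lambda * lim_n
    }
    resp <- respiration_fluxes(lambda, 0, 0, p, maint = mnt)
    cs_next <- max(0, CS + (photo - lambda * (1 + met$E) - mnt) * dt)
    exc <- 0
    if (cs_next > met$CSmax) {           # overflow excretion
      exc <- (cs_next - met$CSmax) / dt
      cs_next <- met$CSmax
    }
    ns_next <- max(0, NS - lambda * met$Y_bio_NC * dt)
    photo_o2 <- photo * met$PQ
    ## pseudo-steady intracellular O2 during the light period
    o2cell <- if (req > 0) {
      min(f$ambient_o2,
          max(0, f$ambient_o2 * (1 - (resp$resp_o2 - photo_o2) / req)))
    } else 0
    v_o2 <- resp$resp_o2 - photo_o2      # negative: net O2 export
    n2fix <- 0; rp <- 0
  } else {
    sol <- solve_dark_o2_state(
      list(CS = max(0, CS), NS = NS, FeN = state[["FeN"]], r = state[["r"]]),
      f, p)
    n2fix <- sol$n2fix; rp <- sol$RP; mnt <- sol$maint
    ## limit to available C storage and N storage headroom
    sc <- 1
    if (sol$resp_co2 * dt > CS && sol$resp_co2 > 0)
      sc <- CS / (sol$resp_co2 * dt)
    if (n2fix * sc * dt > met$NSmax - NS && n2fix > 0)
      n2fix <- max(0, (met$NSmax - NS) / dt) / sc
    n2fix <- n2fix * sc; rp <- rp * sc; mnt <- mnt * sc
    resp_co2 <- met$Y_resp_CN * n2fix + mnt + rp
    resp_o2 <- min(met$RQ * (met$resp_o2_frac * met$Y_resp_CN * n2fix + rp),
                   req)
    o2cell <- if (req > 0) {
      max(0, f$ambient_o2 * (1 - resp_o2 / req))
    } else 0
    cs_next <- max(0, CS - resp_co2 * dt)
    ns_next <- min(met$NSmax, NS + n2fix * dt)
    photo <- 0; photo_o2 <- 0; lambda <- 0; exc <- 0
    v_o2 <- resp_o2
    resp <- list(resp_o2 = resp_o2, resp_co2 = resp_co2,
                 PCO2N2fix = met$Y_resp_CN * n2fix, maint = mnt)
  }

  state[["CS"]] <- cs_next
  state[["NS"]] <- ns_next
  fe_flux <- iron_fluxes(t, phase, state, p$iron, met$CSmax)
  state <- update_iron_and_chl(state, fe_flux, dt, p$iron)
  if (lambda > 0) state <- growth_and_dilution(state, lambda, dt, p)
  state[["O2cell"]] <- o2cell

  flux <- c(photo_c = photo, photo_o2 = photo_o2,
            resp_o2 = resp$resp_o2, resp_co2 = resp$resp_co2,
            n2fix = n2fix, v_o2 = v_o2, exc = exc, lambda = lambda,
            RP = rp, PCO2N2fix = resp$PCO2N2fix, maint = resp$maint,
            O2cell = o2cell)
  list(state = state, flux = flux)
}

.default_initial_state <- function(f, p) {
  croco_state(CS = 0.5 * p$met$CSmax, NS = 0.5 * p$met$NSmax,
              FeP = 0, FeB = p$cell$Fe_total, FeN = 0, Chl = 0,
              X = 1e11, r = cell_radius_for_o2(f$ambient_o2, p),
              O2cell = f$ambient_o2)
}

## Step grid for one 24-h day: uniform dt split exactly at the light/dark
## boundary.
.day_breaks <- function(dt, light_h) {
  br <- sort(unique(round(c(seq(0, 24, by = dt), light_h, 24), 10)))
  br[br <= 24]
}

#' Run the diel simulation to periodic steady state
#'
#' Integrates repeated 24-h cycles with explicit forward Euler (steps split
#' at the light/dark boundary) from a dawn-start initial condition (iron all
#' in the buffer, storage pools at half capacity) until the trajectory
#' repeats: the maximum day-over-day relative change of the per-cell state
#' variables at matched clock times falls below `tol` (population density is
#' compared after detrending by its growth within the day). Returns the final
#' day's state and flux series together with per-day integrated fluxes.
#'
#' @param f A [croco_forcing()].
#' @param p A [croco_params()].
#' @param dt Time step (h), default 0.01.
#' @param max_days Maximum number of 24-h cycles (default 60).
#' @param tol Relative day-over-day convergence tolerance (default 1e-4).
#' @param init Optional initial [croco_state()].
#' @return An object of class `croco_sim`: list with `time` (step-start
#'   clock hours of the final day), `state` (matrix, rows = time points,
#'   state at step start), `flux` (matrix of instantaneous rates), `daily`
#'   (data.frame of per-day integrals, mol cell-1 d-1), `converged`,
#'   `days_run`, `max_rel_change`, `forcing`, `params`, `scenario`.
#' @export
run_diel <- function(f, p, dt = 0.01, max_days = 60, tol = 1e-4,
                     init = NULL) {
  if (dt <= 0 || dt > 0.05) stop("dt must lie in (0, 0.05] h")
  if (max_days < 2) stop("max_days must be >= 2")
  breaks <- .day_breaks(dt, f$photoperiod_light_h)
  nstep <- length(breaks) - 1L
  state <- if (is.null(init)) .default_initial_state(f, p) else init
  state_names <- names(state)
  flux_names <- c("photo_c", "photo_o2", "resp_o2", "resp_co2", "n2fix",
                  "v_o2", "exc", "lambda", "RP", "PCO2N2fix", "maint",
                  "O2cell")
  prev_states <- NULL
  daily <- vector("list", max_days)
  converged <- FALSE
  delta <- NA_real_
  day <- 0L
  while (day < max_days) {
    day <- day + 1L
    states <- matrix(NA_real_, nstep + 1L, length(state_names),
                     dimnames = list(NULL, state_names))
    fluxes <- matrix(NA_real_, nstep, length(flux_names),
                     dimnames = list(NULL, flux_names))
    for (i in seq_len(nstep)) {
      states[i, ] <- state
      h <- breaks[i + 1L] - breaks[i]
      out <- step_cell(state, breaks[i], h, f, p)
      state <- out$state
      fluxes[i, ] <- out$flux[flux_names]
    }
    states[nstep + 1L, ] <- state
    widths <- diff(breaks)
    ints <- colSums(fluxes[, setdiff(flux_names, "O2cell")] * widths)
    daily[[day]] <- c(day = day, ints,
                      growth = unname(state[["X"]] / states[1, "X"]))
    if (!is.null(prev_states)) {
      delta <- .day_rel_change(prev_states, states)
      if (delta < tol) { converged <- TRUE; break }
    }
    prev_states <- states
  }
  if (!converged)
    warning(sprintf("no periodic steady state within %d days (change %.2e)",
                    max_days, delta))
  daily_df <- as.data.frame(do.call(rbind, daily[seq_len(day)]))
  structure(list(time = breaks[-length(breaks)],
                 state = states[-nrow(states), , drop = FALSE],
                 state_end = state,
                 flux = fluxes, daily = daily_df,
                 converged = converged, days_run = day,
                 max_rel_change = delta,
                 forcing = f, params = p, scenario = "default",
                 dt = dt),
            class = "croco_sim")
}

## Max relative day-over-day change across per-cell state variables;
## population density is compared through its within-day growth profile.
.day_rel_change <- function(prev, cur) {
  vars <- setdiff(colnames(cur), "X")
  rel <- vapply(vars, function(v) {
    sc <- max(abs(prev[, v]), 1e-30)
    max(abs(cur[, v] - prev[, v])) / sc
  }, numeric(1))
  gprev <- prev[, "X"] / prev[1, "X"]
  gcur <- cur[, "X"] / cur[1, "X"]
  max(rel, max(abs(gcur - gprev)) / max(abs(gprev)))
}

#' @export
print.croco_sim <- function(x, ...) {
  cat("<croco_sim>", x$scenario, "scenario\n")
  cat(sprintf("  %d day(s), %s (day-over-day change %.2e), dt = %g h\n",
              x$days_run,
              if (x$converged) "periodic steady state" else "NOT converged",
              x$max_rel_change, x$dt))
  di <- daily_integrals(x)
  last <- di[nrow(di), ]
  cat(sprintf("  final day: N2fix %.3e mol N cell-1 d-1, photo %.3e mol C cell-1 d-1, resp %.3e mol O2 cell-1 d-1\n",
              last$n2fix, last$photo_c, last$resp_o2))
  invisible(x)
}

#' Named sensitivity scenarios
#'
#' Applies one of the O2-management / temperature-decomposition scenario
#' patches and runs the diel simulation:
#' `no_size_change` fixes the cell radius at the low-O2 anchor regardless of
#' ambient O2; `no_respiratory_protection` sets the respiratory-protection
#' capacity to zero, so respiration serves only N2-fixation energetics;
#' `high_diffusivity` sets the membrane diffusivity factor to 1/(1.27e3)
#' (the *Azotobacter*-derived cell-wall permeability); `temp_only_n2fix`,
#' `temp_only_photo`, `temp_only_resp` apply the Arrhenius factor to a
#' single metabolic process.
#'
#' @param scenario Scenario name.
#' @param f A [croco_forcing()].
#' @param p A [croco_params()].
#' @param ... Passed to [run_diel()].
#' @return A `croco_sim` with the scenario recorded.
#' @export
run_scenario <- function(scenario = c("default", "no_size_change",
                                      "no_respiratory_protection",
                                      "high_diffusivity", "temp_only_n2fix",
                                      "temp_only_photo", "temp_only_resp"),
                         f, p = croco_params(), ...) {
  scenario <- match.arg(scenario)
  p2 <- scenario_params(scenario, p)
  res <- run_diel(f, p2, ...)
  res$scenario <- scenario
  res
}

#' Parameter patch for a named scenario
#'
#' @inheritParams run_scenario
#' @param p A [croco_params()].
#' @return The patched `croco_params`.
#' @export
scenario_params <- function(scenario, p) {
  switch(scenario,
    default = p,
    no_size_change = { p$cell$radius_fixed <- p$cell$r_lowO2; p },
    no_respiratory_protection = { p$met$R_max <- 0; p },
    high_diffusivity = { p$diff$membrane_factor <- 1 / 1.27e3; p },
    temp_only_n2fix = {
      p$met$temp_mask <- c(n2fix = TRUE, photo = FALSE, resp = FALSE); p },
    temp_only_photo = {
      p$met$temp_mask <- c(n2fix = FALSE, photo = TRUE, resp = FALSE); p },
    temp_only_resp = {
      p$met$temp_mask <- c(n2fix = FALSE, photo = FALSE, resp = TRUE); p },
    stop("unknown scenario: ", scenario))
}

#' Per-day integrated fluxes
#'
#' Integrals of each instantaneous flux over each simulated 24-h window
#' (mol cell-1 d-1), consistent with the Euler scheme (left-rectangle sum on
#' the step grid, which matches the pool bookkeeping exactly).
#'
#' @param res A `croco_sim`.
#' @return data.frame with one row per simulated day: `day`, integrated
#'   `photo_c`, `photo_o2`, `resp_o2`, `resp_co2`, `n2fix`, `v_o2`, `exc`,
#'   `lambda`, `RP`, `PCO2N2fix`, and the within-day population `growth`
#'   factor.
#' @export
daily_integrals <- function(res) {
  stopifnot(inherits(res, "croco_sim"))
  res$daily
}

#' First clock hour at which intracellular O2 reaches zero
#'
#' Scans the converged day of a simulation for the first time point at which
#' the diagnostic intracellular O2 is zero (to within `tol`, mol m-3).
#'
#' @param res A `croco_sim`.
#' @param tol Absolute threshold (mol m-3).
#' @return Clock hour (h), or `NA` if the interior never reaches zero.
#' @export
first_o2_depletion_hour <- function(res, tol = 1e-9) {
  i <- which(res$flux[, "O2cell"] <= tol)
  if (length(i) == 0) return(NA_real_)
  res$time[min(i)]
}

#' Scan daily-integrated fluxes over temperature or irradiance
#'
#' For each grid value the model is run to periodic steady state and the
#' daily integrals of N2 fixation, gross photosynthesis and respiration
#' (averaged over the last two simulated days) are recorded. Temperature scans (grid in degC) use the air-saturated
#' (20%) dissolved O2 for each temperature at the forcing's salinity, with
#' the cell radius following its O2 acclimation map; irradiance scans vary
#' the peak of the light schedule at fixed temperature and ambient O2.
#'
#' @param variable `"temperature"` (grid in degC) or `"irradiance"`
#'   (grid in umol m-2 s-1).
#' @param grid Sorted numeric grid, at least 2 points.
#' @param f Base [croco_forcing()].
#' @param p A [croco_params()].
#' @param ... Passed to [run_diel()].
#' @return data.frame of class `croco_scan`: grid `value`, daily `n2fix`
#'   (mol N cell-1 d-1), `photo_c` (mol C cell-1 d-1), `resp_o2`
#'   (mol O2 cell-1 d-1), `o2_zero_h`, `converged`, `days`. Rows for failed
#'   runs carry `NA`s.
#' @export
scan_forcing <- function(variable = c("temperature", "irradiance"), grid,
                         f = croco_forcing(), p = croco_params(), ...) {
  variable <- match.arg(variable)
  if (length(grid) < 2 || is.unsorted(grid))
    stop("grid must be sorted with >= 2 points")
  rows <- lapply(grid, function(v) {
    fv <- f
    if (variable == "temperature") {
      fv$temperature <- v + 273.15
      fv$ambient_o2 <- o2_treatment_concentration(0.20, fv$temperature,
                                                  fv$salinity)
    } else {
      fv$irradiance_peak <- v
    }
    res <- tryCatch(run_diel(fv, p, ...), error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(value = v, n2fix = NA, photo_c = NA, resp_o2 = NA,
                        o2_zero_h = NA, converged = FALSE, days = NA,
                        error = conditionMessage(res)))
    ## average the last two days: cancels residual period-two alternation
    ## of the periodic orbit when the run stops at max_days
    di <- colMeans(utils::tail(res$daily, 2))
    data.frame(value = v, n2fix = di[["n2fix"]], photo_c = di[["photo_c"]],
               resp_o2 = di[["resp_o2"]],
               o2_zero_h = first_o2_depletion_hour(res),
               converged = res$converged, days = res$days_run,
               error = NA_character_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("croco_scan", "data.frame")
  attr(out, "variable") <- variable
  out
}

#' Write the final-day series of a simulation as CSV
#'
#' Columns: `time_h`, `phase`, `c_s`, `n_s`, `fe_p`, `fe_b`, `fe_n`, `chl`,
#' `x`, `o2cell`, `photo_o2`, `resp_o2`, `n2fix`, `v_o2`, `exc`.
#'
#' @param res A `croco_sim`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(res, path) {
  s <- res$state; fl <- res$flux
  df <- data.frame(
    time_h = res$time,
    phase = ifelse(res$time < res$forcing$photoperiod_light_h,
                   "light", "dark"),
    c_s = s[, "CS"], n_s = s[, "NS"], fe_p = s[, "FeP"], fe_b = s[, "FeB"],
    fe_n = s[, "FeN"], chl = s[, "Chl"], x = s[, "X"],
    o2cell = fl[, "O2cell"], photo_o2 = fl[, "photo_o2"],
    resp_o2 = fl[, "resp_o2"], n2fix = fl[, "n2fix"], v_o2 = fl[, "v_o2"],
    exc = fl[, "exc"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
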