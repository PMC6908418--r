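#' Iron translocation fluxes
#'
#' Phase-specific first-order exchange of iron among photosystems (`FeP`),
#' the buffer (`FeB`) and nitrogenase (`FeN`), all routed through the buffer.
#' During the light period no iron moves to nitrogenase; any nitrogenase iron
#' remaining from the night is torn down back to the buffer, and buffer iron
#' builds photosystems until either the photosystem ceiling `FeP_target` is
#' reached or C storage approaches capacity, after which photosystem iron
#' returns to the buffer (no benefit to further photosynthesis once the C
#' store is nearly full). During the dark period no iron moves to
#' photosystems; idle photosystems release iron to the buffer, and the
#' buffer feeds nitrogenase until the clock hour `t_NB_start` (circadian
#' teardown, ~2 h before dawn), after which nitrogenase iron returns to the
#' buffer and accumulates there for the morning photosystem rebuild.
#'
#' @param t Clock hour in \[0, 24).
#' @param phase `"light"` or `"dark"`.
#' @param state Named vector/list with `FeP`, `FeB`, `FeN`, `CS`.
#' @param sched The `iron` block of [croco_params()].
#' @param CSmax C-storage capacity (mol C cell-1), for the drawdown trigger.
#' @return Named vector `c(F_BP, F_PB, F_BN, F_NB)` (mol Fe cell-1 h-1).
#' @export
iron_fluxes <- function(t, phase, state, sched, CSmax) {
  phase <- match.arg(phase, c("light", "dark"))
  st <- as.list(state)
  F_BP <- F_PB <- F_BN <- F_NB <- 0
  if (phase == "light") {
    F_NB <- sched$k_NB * st$FeN  # residual nitrogenase teardown
    ## continuous switches: a narrow ramp (5% of CSmax) around the C-storage
    ## drawdown threshold, and full-speed buildup until within 10% of the
    ## photosystem ceiling; hard on/off triggers induce day-to-day
    ## period-two flip-flops of the periodic orbit
    w_pb <- min(1, max(0, (st$CS / CSmax - sched$CS_drawdown_threshold) /
                            0.05))
    w_bp <- min(1, max(0, (sched$FeP_target - st$FeP) /
                            (0.1 * sched$FeP_target)))
    F_PB <- sched$k_PB * st$FeP * w_pb
    F_BP <- sched$k_BP * st$FeB * w_bp * (1 - w_pb)
  } else {
    ## idle photosystems release iron to the buffer throughout the night,
    ## feeding nitrogenase synthesis via the buffer
    F_PB <- sched$k_PB * st$FeP
    if (t < sched$t_NB_start) {
      F_BN <- sched$k_BN * st$FeB
    } else {
      F_NB <- sched$k_NB * st$FeN
    }
  }
  c(F_BP = F_BP, F_PB = F_PB, F_BN = F_BN, F_NB = F_NB)
}

#' Advance iron pools and chlorophyll by one Euler step
#'
#' Applies the four translocation fluxes over `dt`, limiting each flux so no
#' pool is driven negative within the step, and moves chlorophyll in
#' proportion to the net photosystem-iron change:
#' `dChl = (F_BP - F_PB) * Y_Chl_Fe * dt` (floored at zero). Total iron
#' `FeP + FeB + FeN` is conserved exactly: the update is written in paired
#' transfers whose contributions cancel.
#'
#' @param state Named vector/list with `FeP`, `FeB`, `FeN`, `Chl`.
#' @param fluxes Named vector from [iron_fluxes()].
#' @param dt Time step (h), > 0.
#' @param sched The `iron` block of [croco_params()].
#' @return The state with iron pools and `Chl` advanced; attribute
#'   `"limited"` is `TRUE` if any flux was capped.
#' @export
update_iron_and_chl <- function(state, fluxes, dt, sched) {
  if (dt <= 0) stop("dt must be > 0")
  fe_p <- state[["FeP"]]; fe_b <- state[["FeB"]]; fe_n <- state[["FeN"]]
  f <- as.list(fluxes)
  limited <- FALSE

  ## per-pool outflow limiting (explicit-Euler safety)
  out_b <- (f$F_BP + f$F_BN) * dt
  if (out_b > fe_b && out_b > 0) {
    sc <- fe_b / out_b; f$F_BP <- f$F_BP * sc; f$F_BN <- f$F_BN * sc
    limited <- TRUE
  }
  if (f$F_PB * dt > fe_p) { f$F_PB <- fe_p / dt; limited <- TRUE }
  if (f$F_NB * dt > fe_n) { f$F_NB <- fe_n / dt; limited <- TRUE }

  d_bp <- (f$F_BP - f$F_PB) * dt   # buffer -> photosystems (net)
  d_bn <- (f$F_BN - f$F_NB) * dt   # buffer -> nitrogenase (net)
  fe_p <- fe_p + d_bp
  fe_n <- fe_n + d_bn
  fe_b <- fe_b - d_bp - d_bn
  if (min(fe_p, fe_b, fe_n) < -1e-25)
    stop("iron pool negative after flux limiting (internal inconsistency)")
  state[["FeP"]] <- max(0, fe_p)
  state[["FeB"]] <- max(0, fe_b)
  state[["FeN"]] <- max(0, fe_n)
  state[["Chl"]] <- max(0, state[["Chl"]] + d_bp * sched$Y_Chl_Fe)
  attr(state, "limited") <- limited
  state
}
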