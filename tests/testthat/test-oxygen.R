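test_that("effective diffusivity scales water diffusivity by the membrane factor", {
  p <- croco_params()$diff
  dw <- water_o2_diffusivity(301.15, p)
  p1 <- p; p1$membrane_factor <- 1
  expect_equal(effective_diffusivity(301.15, p1), dw)
  expect_equal(effective_diffusivity(301.15, p), dw / 6.45e4)
  p2 <- p; p2$membrane_factor <- 1 / 1.27e3
  expect_equal(effective_diffusivity(301.15, p2), dw / 1.27e3)
  p3 <- p; p3$membrane_factor <- 0
  expect_error(effective_diffusivity(301.15, p3), "membrane_factor")
})

test_that("intracellular O2 obeys the diffusion-respiration balance", {
  kappa <- 2.27e-9 / 6.45e4
  expect_equal(intracellular_o2(0.186, 2.5e-6, 0, kappa), 0.186)
  # exact depletion at the critical consumption rate
  gcrit <- 3 * kappa * 0.186 / (2.5e-6)^2
  expect_equal(intracellular_o2(0.186, 2.5e-6, gcrit, kappa), 0)
  # mid-range hand evaluation
  expect_equal(intracellular_o2(0.186, 2e-6, 2e-3, kappa),
               1.1022907489e-01, tolerance = 1e-9)
  expect_error(intracellular_o2(0.186, 0, 1e-3, kappa), "radius")
  expect_error(intracellular_o2(0.186, 2e-6, 1e-3, 0), "kappa")
})

test_that("intracellular O2 stays within [0, ambient] over random inputs", {
  set.seed(42)
  n <- 500
  o2 <- runif(n, 0, 0.3)
  r <- runif(n, 0.5e-6, 5e-6)
  g <- 10^runif(n, -6, 0)
  k <- 10^runif(n, -15, -12)
  val <- intracellular_o2(o2, r, g, k)
  expect_true(all(val >= 0 & val <= o2))
})

test_that("critical volumetric respiration is the closed-form depletion rate", {
  kappa <- 2.27e-9 / 6.45e4
  expect_equal(critical_volumetric_respiration(0, 2.5e-6, kappa), 0)
  # r^-2 scaling: doubling the radius quarters the requirement
  g1 <- critical_volumetric_respiration(0.186, 2e-6, kappa)
  g2 <- critical_volumetric_respiration(0.186, 4e-6, kappa)
  expect_equal(g1 / g2, 4)
  expect_equal(critical_volumetric_respiration(0.186, 2.5e-6, kappa),
               3.1421023256e-03, tolerance = 1e-9)
})

test_that("dark O2 solver saturates protection when capacity is ample", {
  p <- croco_params(R_max = 1e-13)  # capacity far above the requirement
  f <- forcing_20()
  st <- list(CS = 2e-14, NS = 1e-15, FeN = 0, r = 2.5e-6)
  sol <- solve_dark_o2_state(st, f, p)
  expect_equal(sol$O2cell, 0)
  # protection tops respiration up to the O2-limited total
  expect_equal(sol$resp_o2, sol$influx_max, tolerance = 1e-8)
  expect_lt(sol$residual, 1e-8 * f$ambient_o2)
})

test_that("dark O2 solver returns ambient O2 and no fixation when C is empty", {
  p <- croco_params()
  f <- forcing_20()   # 186 uM, above the critical concentration
  st <- list(CS = 0, NS = 1e-15, FeN = 5e-19, r = 2.5e-6)
  sol <- solve_dark_o2_state(st, f, p)
  expect_equal(sol$O2cell, f$ambient_o2)
  expect_equal(sol$n2fix, 0)
  expect_equal(sol$RP, 0)
})

test_that("dark O2 solver matches a brute-force grid search", {
  p <- croco_params()
  f <- forcing_20()
  # mid-transition state: partial fixation, protection at capacity
  st <- list(CS = 2.2e-14, NS = 8e-16, FeN = 2.5e-19, r = 2.5e-6)
  sol <- solve_dark_o2_state(st, f, p)
  # independent oracle: scan intracellular O2 on a 1e6-point grid and
  # minimise the self-consistency residual of the balance map
  kappa <- effective_diffusivity(f$temperature, p$diff)
  req <- 4 * pi * st$r * kappa * f$ambient_o2 * 3600
  cap <- p$met$R_max * st$CS / (st$CS + p$met$K_CS)
  fix0 <- n2_fixation_rate(st$FeN, st$CS, st$NS, 0, f$temperature, p)
  rhoY <- p$met$resp_o2_frac * p$met$Y_resp_CN
  grid <- seq(0, f$ambient_o2, length.out = 1e6)
  fixg <- fix0 * pmax(0, 1 - grid / p$met$O2cri)
  rpg <- pmin(pmax(0, req - rhoY * fixg), cap)
  mapped <- pmax(0, f$ambient_o2 * (1 - (rhoY * fixg + rpg) / req))
  best <- grid[which.min(abs(mapped - grid))]
  expect_equal(sol$O2cell, best, tolerance = 1e-4)
  expect_lt(sol$residual, 1e-8 * f$ambient_o2)
  expect_gt(sol$n2fix, 0)
})

test_that("lowering ambient O2 never raises the returned intracellular O2", {
  p <- croco_params()
  st <- list(CS = 2.2e-14, NS = 8e-16, FeN = 2e-19, r = 2.5e-6)
  o2s <- seq(0.03, 0.25, by = 0.01)
  vals <- vapply(o2s, function(o2) {
    f <- croco_forcing(ambient_o2 = o2)
    solve_dark_o2_state(st, f, p)$O2cell
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
})
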