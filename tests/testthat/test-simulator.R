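test_that("phase rules: no photosynthesis in the dark, no fixation in the light", {
  res <- run_default_20()
  dark <- res$time >= 12
  expect_true(all(res$flux[dark, "photo_c"] == 0))
  expect_true(all(res$flux[dark, "photo_o2"] == 0))
  expect_true(all(res$flux[dark, "lambda"] == 0))
  expect_true(all(res$flux[dark, "exc"] == 0))
  expect_true(all(res$flux[!dark, "n2fix"] == 0))
  expect_true(all(res$flux[!dark, "RP"] == 0))
})

test_that("a step with all rate constants zero leaves the state unchanged", {
  p <- croco_params(A_N2fix = 0, P_max_chl = 0, lambda_max = 0, maint = 0,
                    R_max = 0,
                    iron = list(k_BP = 0, k_PB = 0, k_BN = 0, k_NB = 0))
  f <- forcing_20()
  st <- croco_state(CS = 2e-14, NS = 1e-15, FeP = 5e-19, FeB = 3e-19,
                    FeN = 2e-19, Chl = 4e-18, X = 1e11, r = 2.5e-6)
  pools <- c("CS", "NS", "FeP", "FeB", "FeN", "Chl", "X", "r")
  for (t in c(3, 15)) {
    out <- step_cell(st, t, 0.01, f, p)
    expect_equal(out$state[pools], st[pools], tolerance = 1e-12)
  }
})

test_that("the converged orbit is periodic within tolerance", {
  res <- run_default_20()
  expect_true(res$converged)
  expect_lt(res$max_rel_change, 1e-4)
  # end-of-day per-cell state returns to the start-of-day state
  s0 <- res$state[1, c("CS", "NS", "FeP", "FeB", "FeN", "Chl")]
  s1 <- res$state_end[c("CS", "NS", "FeP", "FeB", "FeN", "Chl")]
  expect_equal(unname(s1 / pmax(s0, 1e-25)),
               rep(1, 6), tolerance = 5e-3)
})

test_that("carbon and nitrogen budgets close over the converged day", {
  for (res in list(run_default_20(), run_default_5())) {
    err <- mass_closure_errors(res)
    expect_lt(err[["C"]], 5e-3)
    expect_lt(err[["N"]], 5e-3)
  }
})

test_that("daily integrals agree with a trapezoidal sum of the series", {
  res <- run_default_20()
  di <- last_daily(res)
  w <- diff(c(res$time, 24))
  for (ch in c("photo_c", "resp_o2", "n2fix")) {
    y <- res$flux[, ch]
    trap <- sum(0.5 * (y + c(y[-1], y[1])) * w)  # periodic closure
    expect_equal(di[[ch]], trap, tolerance = 5e-3)
  }
})

test_that("intracellular O2 is depleted earlier at 5% than at 20% ambient O2", {
  t5 <- first_o2_depletion_hour(run_default_5())
  t20 <- first_o2_depletion_hour(run_default_20())
  expect_false(is.na(t5))
  expect_false(is.na(t20))
  expect_lt(t5, t20)
  # and daily N2 fixation is at least as high at 5% as at 20%
  expect_gte(last_daily(run_default_5())$n2fix,
             last_daily(run_default_20())$n2fix)
})

test_that("dark respiration is higher at 20% than at 5% (respiratory protection)", {
  r20 <- run_default_20(); r5 <- run_default_5()
  dark20 <- sum(r20$flux[r20$time >= 12, "resp_o2"]) * r20$dt
  dark5 <- sum(r5$flux[r5$time >= 12, "resp_o2"]) * r5$dt
  expect_gt(dark20, dark5)
})

test_that("scenario patches modify the expected parameters", {
  p <- croco_params()
  expect_equal(scenario_params("no_respiratory_protection", p)$met$R_max, 0)
  expect_equal(scenario_params("high_diffusivity", p)$diff$membrane_factor,
               1 / 1.27e3)
  expect_equal(scenario_params("no_size_change", p)$cell$radius_fixed,
               p$cell$r_lowO2)
  m <- scenario_params("temp_only_resp", p)$met$temp_mask
  expect_equal(unname(m), c(FALSE, FALSE, TRUE))
  expect_error(scenario_params("bogus", p))
})

test_that("irradiance scan table reports daily integrals over the grid", {
  p <- croco_params()
  sc <- suppressWarnings(scan_forcing("irradiance", c(0, 150, 400),
                                      croco_forcing(), p,
                                      dt = 0.05, max_days = 12, tol = 1e-3))
  expect_s3_class(sc, "croco_scan")
  expect_equal(sc$value, c(0, 150, 400))
  expect_equal(sc$n2fix[1], 0)         # no light, no storage, no fixation
  expect_true(all(diff(sc$photo_c) > 0))
  expect_error(scan_forcing("irradiance", 5, croco_forcing(), p), "grid")
})

test_that("run configuration round-trips through YAML", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "forcing:",
    "  photoperiod: 12L:12D",
    "  irradiance: 150",
    "  irradiance_shape: square",
    "  o2_percent: 5",
    "  temperature_C: 28",
    "  salinity: 35",
    "diffusion:",
    "  membrane_factor: 6.45e4",
    "metabolism:",
    "  R_max: 5.0e-16",
    "cell_size:",
    "  r_lowO2_um: 2.0"), cfg)
  rc <- read_run_config(cfg)
  expect_equal(rc$forcing$ambient_o2, 0.046)
  expect_equal(rc$params$diff$membrane_factor, 1 / 6.45e4)
  expect_equal(rc$params$met$R_max, 5.0e-16)
  expect_equal(rc$params$cell$r_lowO2, 2.0e-6)
})

test_that("the final-day CSV export has the documented columns", {
  res <- run_default_20()
  path <- tempfile(fileext = ".csv")
  write_sim_csv(res, path)
  df <- read.csv(path)
  expect_named(df, c("time_h", "phase", "c_s", "n_s", "fe_p", "fe_b",
                     "fe_n", "chl", "x", "o2cell", "photo_o2", "resp_o2",
                     "n2fix", "v_o2", "exc"))
  expect_equal(nrow(df), length(res$time))
})
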