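test_that("N2 fixation kinetics multiply the five limitation factors", {
  p <- croco_params()
  T28 <- 301.15
  # nitrogenase inactivated at and above the critical O2
  expect_equal(n2_fixation_rate(5e-19, 2e-14, 1e-15, p$met$O2cri, T28, p), 0)
  expect_equal(n2_fixation_rate(5e-19, 2e-14, 1e-15, 0.15, T28, p), 0)
  expect_equal(n2_fixation_rate(0, 2e-14, 1e-15, 0, T28, p), 0)
  # linear in nitrogenase iron
  r1 <- n2_fixation_rate(2e-19, 2e-14, 1e-15, 0.01, T28, p)
  r2 <- n2_fixation_rate(4e-19, 2e-14, 1e-15, 0.01, T28, p)
  expect_equal(r2, 2 * r1)
  # direct product evaluation at mid-range arguments (f_T = 1 at T_ref)
  hand <- p$met$A_N2fix * 3e-19 * (2e-14 / (2e-14 + p$met$K_CS)) *
    (1 - 1e-15 / p$met$NSmax) * (1 - 0.02 / p$met$O2cri)
  expect_equal(n2_fixation_rate(3e-19, 2e-14, 1e-15, 0.02, T28, p), hand)
})

test_that("N2 fixation is monotone in each limitation argument", {
  p <- croco_params()
  T28 <- 301.15
  cs <- seq(0, 3e-14, length.out = 30)
  ns <- seq(0, p$met$NSmax, length.out = 30)
  o2 <- seq(0, p$met$O2cri * 1.2, length.out = 30)
  fe <- seq(0, 1e-18, length.out = 30)
  expect_true(all(diff(n2_fixation_rate(3e-19, cs, 1e-15, 0.01, T28, p)) >= 0))
  expect_true(all(diff(n2_fixation_rate(3e-19, 2e-14, ns, 0.01, T28, p)) <= 0))
  expect_true(all(diff(n2_fixation_rate(3e-19, 2e-14, 1e-15, o2, T28, p)) <= 0))
  expect_true(all(diff(n2_fixation_rate(fe, 2e-14, 1e-15, 0.01, T28, p)) >= 0))
})

test_that("photosynthesis needs chlorophyll and light", {
  p <- croco_params()
  expect_equal(photosynthesis_rate(0, 150, 301.15, p), 0)
  expect_equal(photosynthesis_rate(5e-18, 0, 301.15, p), 0)
  hand <- p$met$P_max_chl * light_factor(150, p$env) * 5e-18
  expect_equal(photosynthesis_rate(5e-18, 150, 301.15, p), hand)
})

test_that("biomass production is a light-phase Michaelis product", {
  p <- croco_params()
  expect_equal(biomass_production_rate(2e-14, 1e-15, 301.15, "dark", p), 0)
  expect_equal(biomass_production_rate(2e-14, 0, 301.15, "light", p), 0)
  hand <- p$met$lambda_max * (2e-14 / (2e-14 + p$met$K_CS)) *
    (1e-15 / (1e-15 + p$met$K_NS))
  expect_equal(biomass_production_rate(2e-14, 1e-15, 301.15, "light", p),
               hand)
})

test_that("respiration fluxes decompose and sum consistently", {
  p <- croco_params()
  z <- respiration_fluxes(0, 0, 0, p)
  expect_equal(z$resp_co2, 0)
  expect_equal(z$resp_o2, 0)
  # single-term case: fixation-coupled CO2 only
  r <- respiration_fluxes(0, 1e-16, 0, p)
  expect_equal(r$PCO2N2fix, p$met$Y_resp_CN * 1e-16)
  expect_equal(r$resp_co2, p$met$Y_resp_CN * 1e-16)
  expect_equal(r$resp_o2, p$met$resp_o2_frac * p$met$Y_resp_CN * 1e-16)
  # term-by-term addition with all components active
  a <- respiration_fluxes(2e-16, 1e-16, 3e-16, p, maint = 5e-16)
  expect_equal(a$resp_co2,
               a$biosynthetic + a$PCO2N2fix + a$PCO2RP + a$maint)
  expect_error(respiration_fluxes(-1, 0, 0, p), ">= 0")
})

test_that("excretion is pure storage overflow", {
  p <- croco_params()
  # room to store: nothing excreted
  expect_equal(excretion_rate(1e-15, 1e-14, room_rate = 1e-13, p), 0)
  # full store: the whole gross rate overflows
  expect_equal(excretion_rate(1e-15, p$met$CSmax, room_rate = 0, p), 1e-15)
  # partial room
  expect_equal(excretion_rate(1e-15, 2.5e-14, room_rate = 4e-16, p), 6e-16)
})

test_that("growth dilutes storage but conserves population-level mass", {
  p <- croco_params()
  st <- croco_state(CS = 2e-14, NS = 1e-15, FeP = 5e-19, FeB = 3e-19,
                    FeN = 2e-19, Chl = 4e-18, X = 1e11)
  expect_identical(growth_and_dilution(st, 0, 0.01, p), st)
  lam <- 0.03 * p$met$Q_C   # lambda/Q_C = 0.03 h^-1
  out <- growth_and_dilution(st, lam, 0.01, p)
  expect_equal(out[["X"]] / st[["X"]], 1.0003)
  expect_equal(out[["X"]] * out[["CS"]], st[["X"]] * st[["CS"]])
  expect_equal(out[["X"]] * out[["NS"]], st[["X"]] * st[["NS"]])
  # iron and chlorophyll are not diluted
  expect_equal(out[["FeP"]], st[["FeP"]])
  expect_equal(out[["Chl"]], st[["Chl"]])
})

test_that("cell radius acclimates to ambient O2 between the anchors", {
  p <- croco_params()
  expect_equal(cell_radius_for_o2(0.046, p), p$cell$r_lowO2)
  expect_equal(cell_radius_for_o2(0.186, p), p$cell$r_highO2)
  expect_equal(cell_radius_for_o2(0.3, p), p$cell$r_highO2)   # clamped
  o2s <- seq(0, 0.3, by = 0.01)
  expect_true(all(diff(cell_radius_for_o2(o2s, p)) >= 0))
  # fixed-size scenario ignores ambient O2
  p2 <- scenario_params("no_size_change", p)
  expect_equal(cell_radius_for_o2(0.186, p2), p$cell$r_lowO2)
})
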