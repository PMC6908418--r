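test_that("ETR follows the FRRf formula", {
  expect_equal(etr(0, 4, 0.7, 1, 0.4), 0)
  # fully open reaction centres: Fq'/Fv' collapses to 1
  expect_equal(etr(100, 4, 0.4, 1, 0.4, n_psii = 0.002),
               4 * 0.002 * 100)
  # hand-evaluated product with Fq'/Fv' = 0.5
  expect_equal(etr(100, 4, 0.7, 1, 0.4, n_psii = 0.002, phi_rcii = 1),
               4 * 0.002 * 0.5 * 1 * 100)
  expect_error(etr(100, 4, 1, 1, 1), "Fv'")
  expect_error(etr(100, 4, 1.2, 1, 0.4), "fluorescence")
})

test_that("ETR is linear in E, sigma, n_PSII and Phi_RCII", {
  base <- etr(200, 4, 0.7, 1, 0.4, n_psii = 0.002, phi_rcii = 0.5)
  expect_equal(etr(400, 4, 0.7, 1, 0.4, 0.002, 0.5), 2 * base)
  expect_equal(etr(200, 8, 0.7, 1, 0.4, 0.002, 0.5), 2 * base)
  expect_equal(etr(200, 4, 0.7, 1, 0.4, 0.004, 0.5), 2 * base)
  expect_equal(etr(200, 4, 0.7, 1, 0.4, 0.002, 1.0), 2 * base)
})

test_that("Eilers-Peeters fit recovers exact curve parameters", {
  truth <- c(a = 4e-6, b = 2.667e-3, c = 1)
  E <- c(0, 20, 50, 100, 150, 200, 300, 450, 600, 800, 1100, 1500)
  y <- eilers_peeters(E, truth[1], truth[2], truth[3])
  fit <- fit_eilers_peeters(E, y)
  etr_max_true <- 1 / (truth[["b"]] + 2 * sqrt(truth[["a"]] * truth[["c"]]))
  expect_equal(fit$ETR_max, etr_max_true, tolerance = 1e-6)
  expect_equal(fit$alpha, 1 / truth[["c"]], tolerance = 1e-6)
  expect_equal(fit$E_K, etr_max_true * truth[["c"]], tolerance = 1e-6)
  expect_equal(fit$E_K, fit$ETR_max / fit$alpha)   # internal consistency
  expect_lt(fit$residual_sse, 1e-12)
})

test_that("Eilers-Peeters fit rejects degenerate input and absorbs 1% noise", {
  E <- c(0, 50, 100, 200, 400, 800)
  expect_error(fit_eilers_peeters(E, rep(0, 6)), "degenerate")
  expect_error(fit_eilers_peeters(E[1:3], c(0, 1, 2)), "at least 4")
  pve <- generate_fixtures("pve", seed = 11, noise_sd = 0.01)
  truth <- attr(pve, "truth")
  fit <- fit_eilers_peeters(pve$E, pve$ETR)
  etr_max_true <- 1 / (truth[["b"]] + 2 * sqrt(truth[["a"]] * truth[["c"]]))
  expect_equal(fit$ETR_max, etr_max_true, tolerance = 0.05)
  expect_equal(fit$alpha, 1 / truth[["c"]], tolerance = 0.05)
})

test_that("acetylene reduction converts with the theoretical factor of 3", {
  expect_equal(acetylene_to_n2(3)$n2_rate, 1)
  expect_equal(acetylene_to_n2(0)$n2_rate, 0)
  out <- acetylene_to_n2(6)
  expect_equal(out$n2_rate, 2)
  expect_equal(out$n_rate, 4)
  expect_error(acetylene_to_n2(-1), ">= 0")
})

test_that("fixture generation is seeded and reduces to the model when noiseless", {
  a <- generate_fixtures("pve", seed = 5, noise_sd = 0.1)
  b <- generate_fixtures("pve", seed = 5, noise_sd = 0.1)
  expect_identical(a$ETR, b$ETR)
  clean <- generate_fixtures("pve", seed = 5, noise_sd = 0)
  truth <- attr(clean, "truth")
  expect_equal(clean$ETR,
               eilers_peeters(clean$E, truth[[1]], truth[[2]], truth[[3]]))
  # law of large numbers: the mean of many noisy replicates approaches the
  # noiseless curve
  reps <- vapply(seq_len(1000), function(s)
    generate_fixtures("pve", seed = s, noise_sd = 0.1)$ETR,
    numeric(nrow(clean)))
  keep <- clean$ETR > 0
  expect_equal(rowMeans(reps)[keep], clean$ETR[keep], tolerance = 0.02)
})

test_that("diel fixtures sample both treatments with recorded truth", {
  obs <- suppressWarnings(
    generate_fixtures("diel", seed = 3, noise_sd = 0, times = c(2, 14),
                      dt = 0.05, max_days = 6))
  df <- obs$observations
  expect_setequal(unique(df$treatment), c("5%", "20%"))
  expect_equal(sort(unique(df$ambient_o2)), c(0.046, 0.186))
  # noiseless fixtures carry the model's own values
  expect_true(all(df$photo_o2[df$time_h == 14] == 0))
  expect_true(all(df$n2fix[df$time_h == 2] == 0))
  expect_s3_class(obs$truth, "croco_params")
  # CSV round trip
  path <- tempfile(fileext = ".csv")
  write_obs_csv(obs, path)
  expect_equal(read_obs_csv(path)$observations$n2fix, df$n2fix)
})
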