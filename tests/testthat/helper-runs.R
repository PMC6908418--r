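# Shared simulation cache: the expensive periodic-steady-state runs are
# computed once per test session and reused across files. Test-resolution
# runs use dt = 0.02 h (the production default is 0.01 h); recovery tests
# use coarser, matched settings for generator and fit.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, fn) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, suppressWarnings(fn()), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

forcing_20 <- function() croco_forcing(ambient_o2 = 0.186)
forcing_5 <- function() croco_forcing(ambient_o2 = 0.046)

run_default_20 <- function() cached_run("d20", function()
  run_diel(forcing_20(), croco_params(), dt = 0.02))
run_default_5 <- function() cached_run("d5", function()
  run_diel(forcing_5(), croco_params(), dt = 0.02))

last_daily <- function(res) {
  di <- daily_integrals(res)
  di[nrow(di), ]
}

# Population-level C and N closure over the final simulated day: the change
# in X * (quota + storage) must equal the integrated net fluxes.
mass_closure_errors <- function(res) {
  p <- res$params
  s <- res$state
  fl <- res$flux
  w <- diff(c(res$time, 24))
  x <- s[, "X"]
  n <- nrow(s)
  x_end <- res$state_end[["X"]]
  cs_end <- res$state_end[["CS"]]
  ns_end <- res$state_end[["NS"]]

  c_pool <- x * (p$met$Q_C + s[, "CS"])
  c_pool_end <- x_end * (p$met$Q_C + cs_end)
  net_c <- sum(x * (fl[, "photo_c"] - p$met$E * fl[, "lambda"] -
                      fl[, "PCO2N2fix"] - fl[, "RP"] - fl[, "maint"] -
                      fl[, "exc"]) * w)
  c_err <- abs((c_pool_end - c_pool[1]) - net_c) / c_pool[1]

  n_pool <- x * (p$met$Y_bio_NC * p$met$Q_C + s[, "NS"])
  n_pool_end <- x_end * (p$met$Y_bio_NC * p$met$Q_C + ns_end)
  net_n <- sum(x * fl[, "n2fix"] * w)
  n_err <- abs((n_pool_end - n_pool[1]) - net_n) / n_pool[1]
  c(C = c_err, N = n_err)
}
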