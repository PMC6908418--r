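#' Generate synthetic observations
#'
#' Produces the two kinds of synthetic data sets used for testing and for
#' parameter-recovery studies:
#'
#' * `kind = "diel"`: runs the simulator at the supplied ("true") parameters
#'   for both canonical O2 treatments (5% = 46 uM and 20% = 186 uM at
#'   28 degC, square 12L:12D at 150 umol m-2 s-1), samples the converged day
#'   at 1-h resolution, and adds seeded Gaussian noise with relative
#'   standard deviation `noise_sd` (default 10%, comparable to the scatter
#'   of published diel culture measurements) to the observation channels:
#'   photosynthetic O2 flux, respiratory O2 flux, N2 fixation, C per cell
#'   and N per cell.
#' * `kind = "pve"`: evaluates an Eilers-Peeters curve with true
#'   coefficients `truth = c(a, b, c)` on an irradiance grid and adds seeded
#'   relative Gaussian noise.
#'
#' The generator records the seed and the truth so recovery tests can close
#' the loop. With `noise_sd = 0` the output is the noiseless model curve;
#' the same seed always reproduces the same data set.
#'
#' @param kind `"diel"` or `"pve"`.
#' @param seed Integer seed for the noise generator.
#' @param truth For `"diel"`: a [croco_params()] (defaults to the package
#'   defaults). For `"pve"`: numeric `c(a, b, c)`.
#' @param noise_sd Relative noise standard deviation (default 0.1).
#' @param times Sampling clock hours for `"diel"` (default `0:23`).
#' @param E_grid Irradiance grid for `"pve"`.
#' @param dt,max_days Simulator resolution for `"diel"` (coarser than the
#'   production default to keep fixture generation fast).
#' @return For `"diel"`: object of class `croco_obs` — list with
#'   `observations` (data.frame: `treatment`, `ambient_o2`, `time_h`, then
#'   `photo_o2`, `resp_o2`, `n2fix`, `c_cell`, `n_cell` and their `sd_*`
#'   columns), `seed`, `truth`, `noise_sd`, `forcing` (list of the two
#'   treatment forcings). For `"pve"`: data.frame with `E`, `ETR`, `sd`,
#'   plus attributes `seed` and `truth`.
#' @export
generate_fixtures <- function(kind = c("diel", "pve"), seed = 1,
                              truth = NULL, noise_sd = 0.1,
                              times = 0:23,
                              E_grid = c(0, 20, 50, 100, 150, 200, 300,
                                         450, 600, 800, 1100, 1500),
                              dt = 0.02, max_days = 20) {
  kind <- match.arg(kind)
  if (kind == "pve") {
    if (is.null(truth)) truth <- c(a = 4e-6, b = 2.667e-3, c = 1)
    y0 <- eilers_peeters(E_grid, truth[[1]], truth[[2]], truth[[3]])
    old <- .Random.seed_save()
    set.seed(seed)
    y <- y0 * (1 + noise_sd * stats::rnorm(length(y0)))
    .Random.seed_restore(old)
    out <- data.frame(E = E_grid, ETR = y, sd = noise_sd * abs(y0))
    attr(out, "seed") <- seed
    attr(out, "truth") <- truth
    return(out)
  }

  p <- if (is.null(truth)) croco_params() else truth
  treatments <- list(
    `5%` = croco_forcing(ambient_o2 = 0.046),
    `20%` = croco_forcing(ambient_o2 = 0.186))
  old <- .Random.seed_save()
  set.seed(seed)
  obs <- lapply(names(treatments), function(tr) {
    f <- treatments[[tr]]
    res <- run_diel(f, p, dt = dt, max_days = max_days)
    idx <- vapply(times, function(t) which.min(abs(res$time - t)),
                  integer(1))
    clean <- data.frame(
      photo_o2 = res$flux[idx, "photo_o2"],
      resp_o2 = res$flux[idx, "resp_o2"],
      n2fix = res$flux[idx, "n2fix"],
      c_cell = p$met$Q_C + res$state[idx, "CS"],
      n_cell = p$met$Y_bio_NC * p$met$Q_C + res$state[idx, "NS"])
    noisy <- clean * (1 + noise_sd * matrix(stats::rnorm(length(times) * 5),
                                            ncol = 5))
    sds <- abs(clean) * noise_sd
    names(sds) <- paste0("sd_", names(clean))
    cbind(data.frame(treatment = tr, ambient_o2 = f$ambient_o2,
                     time_h = res$time[idx]),
          noisy, sds)
  })
  .Random.seed_restore(old)
  structure(list(observations = do.call(rbind, obs),
                 seed = seed, truth = p, noise_sd = noise_sd,
                 forcing = treatments, times = times,
                 dt = dt, max_days = max_days),
            class = "croco_obs")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Write / read diel observation CSV
#'
#' @param obs A `croco_obs`.
#' @param path File path.
#' @return `path` invisibly, or the data.frame.
#' @export
write_obs_csv <- function(obs, path) {
  utils::write.csv(obs$observations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_obs_csv
#' @export
read_obs_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  structure(list(observations = df, seed = NA, truth = NULL,
                 noise_sd = NA,
                 forcing = lapply(split(df$ambient_o2, df$treatment),
                                  function(o2) croco_forcing(
                                    ambient_o2 = o2[1]))),
            class = "croco_obs")
}
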