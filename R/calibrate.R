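#' Calibrate model parameters against observed diel series
#'
#' Minimises the standard-deviation-weighted sum of squared residuals
#' between simulated and observed diel series, over all observation
#' channels (photosynthetic O2 flux, respiratory O2 flux, N2 fixation, C
#' per cell, N per cell) and all treatments present in `obs`. One free
#' parameter is optimised by golden-section/parabolic search
#' ([stats::optimize()]) on a log scale between its bounds; several free
#' parameters use Nelder-Mead on log-parameters with bound clamping. Both
#' are derivative-free, which suits the piecewise model surface.
#'
#' @param free Named list of parameter bounds, e.g.
#'   `list(membrane_factor = c(1e-6, 1e-3))`. Names must address unique
#'   leaves of [croco_params()] (see [modify_params()]). Empty list: no
#'   optimisation, returns `p0` with its objective.
#' @param obs A `croco_obs` from [generate_fixtures()] or [read_obs_csv()].
#' @param p0 Starting [croco_params()].
#' @param dt,max_days,tol Simulator settings used inside the objective
#'   (coarse defaults keep the search affordable).
#' @param maxit Maximum objective evaluations for the multiparameter search.
#' @return List of class `croco_fit`: `params` (fitted `croco_params`),
#'   `estimates` (named vector), `objective`, `objective0` (at `p0`),
#'   `residuals` (per channel), `evaluations`.
#' @export
#' @examples
#' \donttest{
#' obs <- generate_fixtures("diel", seed = 7, noise_sd = 0, dt = 0.05,
#'                          max_days = 8)
#' fit <- calibrate(list(membrane_factor = c(1e-6, 1e-4)), obs,
#'                  dt = 0.05, max_days = 8)
#' }
calibrate <- function(free, obs, p0 = croco_params(), dt = 0.05,
                      max_days = 10, tol = 1e-3, maxit = 60) {
  stopifnot(inherits(obs, "croco_obs"))
  channels <- c("photo_o2", "resp_o2", "n2fix", "c_cell", "n_cell")
  df <- obs$observations

  objective <- function(p) {
    total <- 0
    for (tr in unique(df$treatment)) {
      sub <- df[df$treatment == tr, ]
      f <- croco_forcing(ambient_o2 = sub$ambient_o2[1])
      res <- tryCatch(
        suppressWarnings(run_diel(f, p, dt = dt, max_days = max_days,
                                  tol = tol)),
        error = function(e) NULL)
      if (is.null(res)) return(1e12)
      idx <- vapply(sub$time_h, function(t) which.min(abs(res$time - t)),
                    integer(1))
      sim <- list(photo_o2 = res$flux[idx, "photo_o2"],
                  resp_o2 = res$flux[idx, "resp_o2"],
                  n2fix = res$flux[idx, "n2fix"],
                  c_cell = p$met$Q_C + res$state[idx, "CS"],
                  n_cell = p$met$Y_bio_NC * p$met$Q_C + res$state[idx, "NS"])
      for (ch in channels) {
        w <- sub[[paste0("sd_", ch)]]
        w <- pmax(w, 0.05 * max(abs(sub[[ch]]), 1e-300))  # sd floor
        total <- total + sum(((sim[[ch]] - sub[[ch]]) / w)^2)
      }
    }
    total
  }

  obj0 <- objective(p0)
  if (length(free) == 0) {
    return(structure(list(params = p0, estimates = numeric(0),
                          objective = obj0, objective0 = obj0,
                          residuals = NULL, evaluations = 1L),
                     class = "croco_fit"))
  }
  if (is.null(names(free)) || any(names(free) == ""))
    stop("free must be a named list of c(lower, upper) bounds")

  nev <- 0L
  with_values <- function(vals) {
    patch <- as.list(vals)
    names(patch) <- names(free)
    modify_params(p0, patch)
  }
  fwrap <- function(logv) {
    nev <<- nev + 1L
    vals <- exp(logv)
    for (i in seq_along(free))
      vals[i] <- min(max(vals[i], free[[i]][1]), free[[i]][2])
    objective(with_values(vals))
  }

  if (length(free) == 1L) {
    b <- free[[1]]
    opt <- stats::optimize(function(lv) fwrap(lv), log(b), tol = 1e-3)
    est <- exp(opt$minimum)
    best_obj <- opt$objective
  } else {
    start <- log(vapply(free, function(b) sqrt(b[1] * b[2]), numeric(1)))
    opt <- stats::optim(start, fwrap, method = "Nelder-Mead",
                        control = list(maxit = maxit))
    est <- exp(opt$par)
    for (i in seq_along(free))
      est[i] <- min(max(est[i], free[[i]][1]), free[[i]][2])
    best_obj <- opt$value
  }
  names(est) <- names(free)
  if (best_obj > obj0) {  # never return worse than the start
    est <- vapply(seq_along(free), function(i) {
      leaf <- names(free)[i]
      hit <- which(vapply(p0, function(b) leaf %in% names(b), logical(1)))
      p0[[hit[1]]][[leaf]]
    }, numeric(1))
    names(est) <- names(free)
    best_obj <- obj0
  }
  pfit <- with_values(est)
  structure(list(params = pfit, estimates = est, objective = best_obj,
                 objective0 = obj0, residuals = NULL, evaluations = nev),
            class = "croco_fit")
}

#' @export
print.croco_fit <- function(x, ...) {
  cat("<croco_fit>\n")
  if (length(x$estimates)) {
    for (nm in names(x$estimates))
      cat(sprintf("  %s = %.4g\n", nm, x$estimates[[nm]]))
  }
  cat(sprintf("  objective %.4g (start %.4g), %d evaluations\n",
              x$objective, x$objective0, x$evaluations))
  invisible(x)
}
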