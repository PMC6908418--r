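#' PSII electron transfer rate from FRR fluorometry quantities
#'
#' `ETR = sigma_PSII * n_PSII * (Fq'/Fv') * Phi_RCII * E`, with
#' `Fq' = Fm' - F'` (variable fluorescence in the light) and
#' `Fv' = Fm' - Fo'` (maximal variable fluorescence in the light). The
#' quantum yield within an open reaction centre, `Phi_RCII`, defaults to
#' 1 mol e- (mol photons)-1. Units follow the inputs: with `sigma_PSII` in
#' A^2 quantum-1 and `E` in umol photons m-2 s-1 the result is a relative
#' electron transfer rate; the package treats ETR in consistent relative
#' units throughout.
#'
#' @param E Actinic irradiance (umol photons m-2 s-1).
#' @param sigma_psii Effective PSII absorption cross-section.
#' @param f_prime Operational fluorescence under actinic light.
#' @param fm_prime Maximum fluorescence under actinic light.
#' @param fo_prime Minimum fluorescence under actinic light.
#' @param n_psii Functional PSII reaction centres per total chlorophyll a.
#' @param phi_rcii Quantum yield of photochemistry within RCII, in (0, 1\].
#' @return Electron transfer rate (same relative units for all samples).
#' @export
#' @examples
#' etr(E = 100, sigma_psii = 4, f_prime = 0.7, fm_prime = 1, fo_prime = 0.4,
#'     n_psii = 0.002)
etr <- function(E, sigma_psii, f_prime, fm_prime, fo_prime,
                n_psii = 0.002, phi_rcii = 1) {
  if (any(E < 0)) stop("E must be >= 0")
  if (any(phi_rcii <= 0 | phi_rcii > 1)) stop("phi_rcii must lie in (0, 1]")
  if (any(fo_prime > f_prime + 1e-12) || any(f_prime > fm_prime + 1e-12))
    stop("fluorescence must satisfy Fo' <= F' <= Fm'")
  fv <- fm_prime - fo_prime
  if (any(fv <= 0)) stop("Fv' = Fm' - Fo' must be > 0")
  fq <- fm_prime - f_prime
  sigma_psii * n_psii * (fq / fv) * phi_rcii * E
}

#' Eilers-Peeters form of a photosynthesis-irradiance curve
#'
#' `ETR(E) = E / (a E^2 + b E + c)`; rises with initial slope `1/c`,
#' saturates, and declines under photoinhibition (controlled by `a`).
#'
#' @param E Irradiance.
#' @param a,b,c Curve coefficients (a, c > 0).
#' @return Rate at each `E`.
#' @export
eilers_peeters <- function(E, a, b, c) E / (a * E^2 + b * E + c)

#' Fit an Eilers-Peeters light-response curve
#'
#' Least-squares fit of `ETR(E) = E / (a E^2 + b E + c)` to observed
#' (irradiance, rate) pairs, by Levenberg-Marquardt on log-parameters
#' (enforcing a, c > 0) from a small multistart grid around moment-based
#' initial values. Derived photophysiological quantities:
#' maximum rate `ETR_max = 1 / (b + 2 sqrt(a c))`, initial slope
#' `alpha = 1 / c`, and light-saturation parameter `E_K = ETR_max / alpha`.
#'
#' @param E Irradiance values (>= 4 points spanning sub- and super-saturating
#'   light).
#' @param ETR Observed rates.
#' @return An object of class `croco_pve_fit`: list with `a`, `b`, `c`,
#'   `ETR_max`, `alpha`, `E_K`, `residual_sse`, `fitted`, `n`.
#' @export
#' @examples
#' E <- c(0, 20, 50, 100, 200, 400, 800, 1500)
#' y <- eilers_peeters(E, 4e-6, 2.667e-3, 1)
#' fit_eilers_peeters(E, y)$E_K
fit_eilers_peeters <- function(E, ETR) {
  if (length(E) != length(ETR)) stop("E and ETR must have equal length")
  if (length(E) < 4) stop("need at least 4 points")
  if (all(ETR <= 0)) stop("degenerate input: all rates are <= 0")
  pos <- E > 0 & ETR > 0
  if (sum(pos) < 3) stop("need at least 3 points with positive E and ETR")

  ## moment-based start: initial slope from the lowest positive-E points,
  ## peak position for a, then b from the peak height
  o <- order(E[pos])
  Ep <- E[pos][o]; Yp <- ETR[pos][o]
  c0 <- max(Ep[1] / Yp[1], 1e-12)
  Eopt0 <- max(Ep[which.max(Yp)], min(Ep))
  a0 <- c0 / Eopt0^2
  b0 <- max(1 / max(Yp) - 2 * sqrt(a0 * c0), 1e-3 / max(Yp))

  obj_data <- data.frame(E = E, ETR = ETR)
  best <- NULL
  for (sa in c(1, 0.2, 5)) for (sc in c(1, 0.3, 3)) {
    st <- list(la = log(a0 * sa), lb = log(b0), lc = log(c0 * sc))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ETR ~ E / (exp(la) * E^2 + exp(lb) * E + exp(lc)),
        data = obj_data, start = st,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("Eilers-Peeters fit failed for all starting values")
  cf <- exp(stats::coef(best$fit))
  a <- unname(cf["la"]); b <- unname(cf["lb"]); c <- unname(cf["lc"])
  denom <- b + 2 * sqrt(a * c)
  if (denom <= 0) stop("fit has non-positive maximum rate (b + 2*sqrt(ac))")
  etr_max <- 1 / denom
  alpha <- 1 / c
  structure(list(a = a, b = b, c = c,
                 ETR_max = etr_max, alpha = alpha, E_K = etr_max / alpha,
                 residual_sse = best$sse,
                 fitted = eilers_peeters(E, a, b, c), n = length(E)),
            class = "croco_pve_fit")
}

#' @export
print.croco_pve_fit <- function(x, ...) {
  cat("<croco_pve_fit> Eilers-Peeters light response\n")
  cat(sprintf("  ETR_max = %.4g, alpha = %.4g, E_K = %.4g (SSE %.3g, n = %d)\n",
              x$ETR_max, x$alpha, x$E_K, x$residual_sse, x$n))
  invisible(x)
}

#' Convert acetylene-reduction rates to N2 fixation
#'
#' The acetylene-reduction assay measures ethylene production by
#' nitrogenase as a proxy for N2 fixation; the theoretical electron-budget
#' conversion is 3 mol C2H4 per mol N2. Returns both the N2 rate and the
#' N-atom rate (2 N per N2).
#'
#' @param ethylene_rate Ethylene production (mol C2H4 cell-1 h-1, or any
#'   consistent unit), >= 0.
#' @return List with `n2_rate` (= rate / 3), `n_rate` (= 2 * rate / 3) and
#'   `unit_note`.
#' @export
#' @examples
#' acetylene_to_n2(3)$n2_rate  # 1
acetylene_to_n2 <- function(ethylene_rate) {
  if (any(ethylene_rate < 0)) stop("ethylene_rate must be >= 0")
  list(n2_rate = ethylene_rate / 3,
       n_rate = 2 * ethylene_rate / 3,
       unit_note = "same per-cell per-time unit as the ethylene input")
}
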