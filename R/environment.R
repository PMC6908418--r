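#' Physical forcing for a diel simulation
#'
#' Bundles the environmental conditions of one culture / one model run: the
#' photoperiod, the irradiance schedule, the ambient dissolved O2, temperature
#' and salinity. The default corresponds to the canonical laboratory
#' condition: a square-wave 12 h : 12 h light-dark cycle at
#' 150 umol photons m-2 s-1, 28 degC, salinity 35, air-saturated (20% O2,
#' 186 uM) seawater.
#'
#' @param photoperiod_light_h Hours of light per 24-h day.
#' @param photoperiod_dark_h Hours of darkness per 24-h day. Must sum with
#'   `photoperiod_light_h` to 24.
#' @param irradiance_peak Peak photon flux (umol photons m-2 s-1).
#' @param irradiance_shape `"square"` (constant at `irradiance_peak` during the
#'   light window) or `"sinusoidal"` (half-sine over the light window).
#' @param ambient_o2 Dissolved O2 in the medium (mol O2 m-3). 0.186 mol m-3 is
#'   the 20% (air) treatment at 28 degC; 0.046 the 5% treatment.
#' @param temperature Absolute temperature (K).
#' @param salinity Practical salinity (dimensionless).
#'
#' @return An object of class `croco_forcing`.
#' @export
#' @examples
#' f <- croco_forcing()
#' diel_irradiance(6, f)
croco_forcing <- function(photoperiod_light_h = 12,
                          photoperiod_dark_h = 24 - photoperiod_light_h,
                          irradiance_peak = 150,
                          irradiance_shape = c("square", "sinusoidal"),
                          ambient_o2 = 0.186,
                          temperature = 301.15,
                          salinity = 35) {
  irradiance_shape <- match.arg(irradiance_shape)
  stopifnot(photoperiod_light_h >= 0, photoperiod_dark_h >= 0)
  if (abs(photoperiod_light_h + photoperiod_dark_h - 24) > 1e-9)
    stop("photoperiod_light_h + photoperiod_dark_h must equal 24")
  if (irradiance_peak < 0) stop("irradiance_peak must be >= 0")
  if (ambient_o2 < 0) stop("ambient_o2 must be >= 0")
  if (temperature <= 0) stop("temperature must be > 0 (kelvin)")
  structure(list(photoperiod_light_h = photoperiod_light_h,
                 photoperiod_dark_h = photoperiod_dark_h,
                 irradiance_peak = irradiance_peak,
                 irradiance_shape = irradiance_shape,
                 ambient_o2 = ambient_o2,
                 temperature = temperature,
                 salinity = salinity),
            class = "croco_forcing")
}

#' @export
print.croco_forcing <- function(x, ...) {
  cat("<croco_forcing>\n")
  cat(sprintf("  photoperiod : %gL:%gD\n",
              x$photoperiod_light_h, x$photoperiod_dark_h))
  cat(sprintf("  irradiance  : %g umol m-2 s-1 (%s)\n",
              x$irradiance_peak, x$irradiance_shape))
  cat(sprintf("  ambient O2  : %g mol m-3 (%.0f uM)\n",
              x$ambient_o2, 1000 * x$ambient_o2))
  cat(sprintf("  temperature : %.2f K (%.2f degC), S = %g\n",
              x$temperature, x$temperature - 273.15, x$salinity))
  invisible(x)
}

#' Arrhenius temperature factor
#'
#' `f_T(T) = exp(A_T * (1/T_ref - 1/T))`, the dimensionless modulation applied
#' to metabolic rates. Equal to 1 at the reference temperature for any slope,
#' and strictly increasing in temperature when `A_T > 0`.
#'
#' @param temperature Absolute temperature (K), vectorised.
#' @param p Parameter list with elements `A_T` (K) and `T_ref` (K); typically
#'   the `env` block of [croco_params()].
#' @return Dimensionless factor(s).
#' @export
#' @examples
#' p <- croco_params()$env
#' temperature_factor(p$T_ref, p)  # exactly 1
temperature_factor <- function(temperature, p) {
  if (any(temperature <= 0)) stop("temperature must be > 0 (kelvin)")
  exp(p$A_T * (1 / p$T_ref - 1 / temperature))
}

#' Light saturation factor with photoinhibition
#'
#' `f_I(I) = clip(1 - exp(-A_I * I) - Omega(I), 0, 1)` where the
#' photoinhibition term is a hinge, `Omega(I) = inhib_slope * max(0, I -
#' inhib_I0)`: zero up to the onset irradiance, linear above it. The factor
#' rises from 0 at darkness toward saturation, then declines once irradiance
#' exceeds the photoinhibition onset.
#'
#' @param irradiance Photon flux (umol photons m-2 s-1), vectorised.
#' @param p Parameter list with `A_I`, `inhib_I0`, `inhib_slope`.
#' @return Dimensionless factor(s) in \[0, 1\].
#' @export
light_factor <- function(irradiance, p) {
  if (any(irradiance < 0)) stop("irradiance must be >= 0")
  omega <- p$inhib_slope * pmax(0, irradiance - p$inhib_I0)
  pmin(1, pmax(0, 1 - exp(-p$A_I * irradiance) - omega))
}

#' Irradiance at a given time of day
#'
#' Lights-on is at clock hour 0. A square schedule holds
#' `irradiance_peak` throughout the light window; a sinusoidal schedule is a
#' half-sine peaking at mid-light. Dark-window irradiance is 0.
#'
#' @param t Time of day (h), in \[0, 24); vectorised.
#' @param f A [croco_forcing()].
#' @return Photon flux (umol photons m-2 s-1).
#' @export
diel_irradiance <- function(t, f) {
  if (any(t < 0 | t >= 24)) stop("t must lie in [0, 24)")
  L <- f$photoperiod_light_h
  lit <- t < L
  out <- numeric(length(t))
  if (f$irradiance_shape == "square") {
    out[lit] <- f$irradiance_peak
  } else {
    out[lit] <- f$irradiance_peak * sin(pi * t[lit] / L)
  }
  out
}

## Garcia & Gordon (1992) air-saturation O2 fit (Benson & Krause coefficients),
## umol kg-1; adequate over the liquid range of seawater culturing.
.gg_o2_sat <- function(temperature_K, salinity) {
  tC <- temperature_K - 273.15
  Ts <- log((298.15 - tC) / (273.15 + tC))
  A <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  B <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  C0 <- -2.75915e-7
  lnC <- A[1] + A[2] * Ts + A[3] * Ts^2 + A[4] * Ts^3 + A[5] * Ts^4 +
    A[6] * Ts^5 +
    salinity * (B[1] + B[2] * Ts + B[3] * Ts^2 + B[4] * Ts^3) +
    C0 * salinity^2
  exp(lnC)
}

## Rescale so that air saturation at 28 degC / S = 35 is exactly 186 uM, the
## concentration assigned to the 20% treatment; keeps the fit's temperature and
## salinity dependence while pinning the canonical culture value.
.o2_sat_scaled <- function(temperature_K, salinity) {
  186 / .gg_o2_sat(301.15, 35) * .gg_o2_sat(temperature_K, salinity)
}

#' Dissolved O2 concentration of a gas-mixture treatment
#'
#' Converts the O2 fraction of the sparging gas into the dissolved O2
#' concentration of the culture medium, assuming equilibrium. Air (fraction
#' 0.20) corresponds to saturation; other fractions scale linearly. The two
#' canonical treatments at 28 degC and salinity 35 return the laboratory
#' values exactly: 0.20 -> 186 uM and 0.05 -> 46 uM. Elsewhere a Garcia-Gordon
#' seawater solubility fit (rescaled through the 186 uM anchor) is used.
#'
#' @param gas_fraction O2 mole fraction of the gas phase, in \[0, 1\].
#' @param temperature Absolute temperature (K).
#' @param salinity Practical salinity.
#' @param unit `"molar"` for mol O2 m-3 (the model's unit) or `"uM"`.
#' @return Dissolved O2 concentration.
#' @export
#' @examples
#' o2_treatment_concentration(0.20, 301.15, 35, unit = "uM")  # 186
#' o2_treatment_concentration(0.05, 301.15, 35, unit = "uM")  # 46
o2_treatment_concentration <- function(gas_fraction, temperature = 301.15,
                                       salinity = 35,
                                       unit = c("molar", "uM")) {
  unit <- match.arg(unit)
  if (any(gas_fraction < 0 | gas_fraction > 1))
    stop("gas_fraction must lie in [0, 1]")
  canonical <- abs(temperature - 301.15) < 1e-6 && abs(salinity - 35) < 1e-6
  sat <- .o2_sat_scaled(temperature, salinity)  # uM at air saturation
  uM <- gas_fraction / 0.20 * sat
  if (canonical) {
    uM[abs(gas_fraction - 0.20) < 1e-12] <- 186
    uM[abs(gas_fraction - 0.05) < 1e-12] <- 46
  }
  if (unit == "uM") uM else uM / 1000
}

## Vogel-type correlation for the dynamic viscosity of pure water (Pa s),
## valid over ~273-373 K.
.water_viscosity <- function(temperature_K) {
  if (any(temperature_K < 273.15 | temperature_K > 373.15))
    stop("temperature outside the viscosity correlation range (273-373 K)")
  2.414e-5 * 10^(247.8 / (temperature_K - 140))
}

#' Diffusivity of O2 in water at a given temperature
#'
#' Walden's-rule scaling from a reference value:
#' `D(T) = D_ref * (T / T_ref_D) * (mu(T_ref_D) / mu(T))`, with `mu` the
#' dynamic viscosity of pure water from a Vogel-type correlation. Monotonically
#' increasing in temperature over the liquid range.
#'
#' @param temperature Absolute temperature (K).
#' @param p Parameter list with `D_ref` (m2 s-1) and `T_ref_D` (K); typically
#'   the `diff` block of [croco_params()].
#' @return Diffusivity (m2 s-1).
#' @export
water_o2_diffusivity <- function(temperature, p) {
  mu_ref <- .water_viscosity(p$T_ref_D)
  mu <- .water_viscosity(temperature)
  p$D_ref * (temperature / p$T_ref_D) * (mu_ref / mu)
}
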