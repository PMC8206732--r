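#' Daily thermal-time increment
#'
#' @param tmin,tmax Daily minimum and maximum temperature (deg C),
#'   tmin <= tmax; vectorized.
#' @param t_base Base temperature (deg C).
#' @return max(0, (tmin + tmax)/2 - t_base), in deg C d.
#' @examples
#' thermal_time_increment(2, 10, 0)
#' @export
thermal_time_increment <- function(tmin, tmax, t_base = 0) {
  if (any(tmin > tmax)) abort("tmin must not exceed tmax")
  pmax(0, (tmin + tmax) / 2 - t_base)
}

#' CO2 fertilization multiplier on radiation-use efficiency
#'
#' RUE increases linearly with CO2 concentration: +30% for a doubling
#' relative to the 364 ppm baseline.
#'
#' @param co2_ppm Atmospheric CO2 (umol/mol), > 0; vectorized.
#' @return Dimensionless multiplier, 1 at 364 ppm.
#' @examples
#' co2_rue_factor(c(364, 541, 728))
#' @export
co2_rue_factor <- function(co2_ppm) {
  if (any(co2_ppm <= 0)) abort("co2_ppm must be > 0")
  1 + 0.30 * (co2_ppm - 364) / 364
}

#' Moisture choking function
#'
#' Piecewise-linear response of the water stress multiplier to the fraction
#' of transpirable soil water (FTSW) in the root zone: no limitation above
#' the threshold, linear decline to zero below it. Applied to RUE, soil
#' evaporation, transpiration and leaf senescence.
#'
#' @param ftsw Fraction of transpirable soil water, in [0, 1]; vectorized.
#' @param threshold FTSW below which stress sets in (default 0.5).
#' @return Multiplier in [0, 1], non-decreasing in `ftsw`.
#' @examples
#' water_stress_factor(c(0, 0.25, 0.5, 1))
#' @export
water_stress_factor <- function(ftsw, threshold = 0.5) {
  if (any(ftsw < -1e-12 | ftsw > 1 + 1e-12)) abort("ftsw must be in [0, 1]")
  pmin(1, pmax(0, ftsw) / threshold)
}

#' Potential evapotranspiration (equilibrium-evaporation type)
#'
#' PET = alpha * s/(s + gamma) * Rn/lambda with alpha = 1.26,
#' Rn = 0.6 * srad, lambda = 2.45 MJ/kg, gamma = 0.066 kPa/degC and s the
#' slope of the saturation vapour pressure curve at `tmean`.
#'
#' @param srad Global solar radiation (MJ m-2 d-1), >= 0; vectorized.
#' @param tmean Daily mean temperature (deg C).
#' @return Potential ET in mm d-1, non-negative.
#' @examples
#' potential_et(20, 15)
#' @export
potential_et <- function(srad, tmean) {
  if (any(srad < 0)) abort("srad must be >= 0")
  s <- svp_slope(tmean)
  gamma <- 0.066
  rn <- 0.6 * srad
  pmax(0, 1.26 * s / (s + gamma) * rn / 2.45)
}

# Slope of the saturation vapour pressure curve (kPa per degC).
svp_slope <- function(t) {
  4098 * (0.6108 * exp(17.27 * t / (t + 237.3))) / (t + 237.3)^2
}

# Temperature limitation on assimilation: ramp 0->1 over 0..8 degC,
# plateau to 25, decline to 0 at 37.
temperature_factor <- function(tmean) {
  pmin(1, pmax(0, pmin(tmean / 8, (37 - tmean) / 12)))
}

# Triangular vernalization effectiveness: 1 at the midpoint of
# [vern_t_min, vern_t_max], 0 at and beyond the bounds.
vernalization_effectiveness <- function(tmean, cultivar) {
  mid <- (cultivar$vern_t_min + cultivar$vern_t_max) / 2
  half <- (cultivar$vern_t_max - cultivar$vern_t_min) / 2
  pmax(0, 1 - abs(tmean - mid) / half)
}

# Photoperiod modulation of development rate: 1 at or above saturating
# daylength, linear reduction below, clamped to [0, 1].
photoperiod_factor <- function(dl, cultivar) {
  f <- 1 - cultivar$photoperiod_sens *
    pmax(0, cultivar$daylength_saturation - dl) / cultivar$daylength_saturation
  pmin(1, pmax(0, f))
}

#' One day of the layered soil-water balance
#'
#' Rain infiltrates top-down, filling layers to capacity; excess beyond the
#' bottom layer leaves as drainage. Soil evaporation is drawn from the
#' surface evaporation layers, transpiration from the layers inside the
#' current root zone, each capped by the layer's content (withdrawals are
#' distributed proportionally to content). The balance closes exactly:
#' rain = change in storage + actual evaporation + actual transpiration +
#' drainage.
#'
#' @param soil_water Numeric vector of per-layer water contents (mm).
#' @param rain Rainfall (mm), >= 0.
#' @param soil_evap Potential soil evaporation demand (mm), >= 0.
#' @param transpiration Potential transpiration demand (mm), >= 0.
#' @param soil A [soil_profile()].
#' @param n_root_layers Number of layers currently reachable by roots.
#' @return List with `soil_water` (updated vector), `drainage`,
#'   `evap_actual`, `transp_actual` (mm).
#' @export
soil_water_update <- function(soil_water, rain, soil_evap, transpiration,
                              soil, n_root_layers = soil$n_layers) {
  if (rain < 0 || soil_evap < 0 || transpiration < 0) {
    abort("water fluxes must be non-negative")
  }
  cap <- soil$layer_capacity
  sw <- soil_water

  # Infiltration top-down.
  inflow <- rain
  if (inflow > 0) {
    for (i in seq_along(sw)) {
      take <- min(inflow, cap - sw[i])
      sw[i] <- sw[i] + take
      inflow <- inflow - take
      if (inflow <= 0) break
    }
  }
  drainage <- inflow

  evap_actual <- withdraw(sw, soil_evap, seq_len(soil$n_evap_layers))
  sw <- evap_actual$sw
  transp_actual <- withdraw(sw, transpiration,
                            seq_len(max(1L, min(length(sw), n_root_layers))))
  sw <- transp_actual$sw

  list(soil_water = sw, drainage = drainage,
       evap_actual = evap_actual$taken, transp_actual = transp_actual$taken)
}

# Withdraw up to `demand` mm from the given layers, proportionally to
# content, never below zero.
withdraw <- function(sw, demand, layers) {
  avail <- sum(sw[layers])
  taken <- min(demand, avail)
  if (taken > 0 && avail > 0) {
    sw[layers] <- sw[layers] * (1 - taken / avail)
  }
  list(sw = sw, taken = taken)
}

#' Grain-set factor from stress exposure around anthesis
#'
#' For a cultivar tolerant to both stresses the factor is exactly 1.
#' A drought-sensitive cultivar loses grain set in proportion to the mean
#' water stress (1 - water stress factor) over the anthesis window; a
#' heat-sensitive cultivar loses grain set in proportion to accumulated
#' degree-days of tmax above its threshold. Both responses are floored.
#'
#' @param exposure A data frame with one row per day of the anthesis window
#'   and columns `f_water` (daily water stress multiplier in [0, 1]) and
#'   `tmax` (deg C).
#' @param cultivar A [cultivar_params()].
#' @return Dimensionless factor in (0, 1].
#' @examples
#' ex <- data.frame(f_water = rep(0.8, 11), tmax = rep(20, 11))
#' grain_set_factor(ex, cultivar_params(drought_sensitive = TRUE))
#' @export
grain_set_factor <- function(exposure, cultivar) {
  f <- 1
  if (isTRUE(cultivar$drought_sensitive)) {
    stress <- mean(1 - exposure$f_water)
    f <- f * max(cultivar$grain_set_floor, 1 - cultivar$s_d * stress)
  }
  if (isTRUE(cultivar$heat_sensitive)) {
    dose <- sum(pmax(0, exposure$tmax - cultivar$heat_threshold))
    f <- f * max(cultivar$grain_set_floor, 1 - cultivar$s_h * dose)
  }
  f
}
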