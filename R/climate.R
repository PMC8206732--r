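#' Describe the monthly climate statistics of a site
#'
#' A `site_climate` object holds the parameters the weather generator is
#' driven by: monthly mean temperature and diurnal range, the day-to-day
#' temperature residual process (standard deviation and lag-1
#' autocorrelation), the first-order Markov precipitation occurrence chain
#' (monthly wet-after-dry and wet-after-wet probabilities), gamma wet-day
#' amounts (monthly mean, shared shape), a clearness index for solar
#' radiation, and the wet-day cross-effects (tmax depression, radiation
#' reduction).
#'
#' @param site_id Character label for the site.
#' @param latitude Degrees north; must satisfy |latitude| < 66.5.
#' @param monthly_tmean Numeric length 12, monthly mean temperature (deg C).
#' @param monthly_trange Numeric length 12, mean diurnal range (deg C).
#' @param temp_sd Day-to-day residual standard deviation (deg C).
#' @param temp_ar1 Lag-1 autocorrelation of the temperature residual, in [0,1).
#' @param p_wet_given_dry,p_wet_given_wet Numeric length 12, monthly Markov
#'   transition probabilities for precipitation occurrence, each in [0,1].
#' @param gamma_shape Shape of the gamma wet-day amount distribution (shared
#'   across months), > 0.
#' @param gamma_mean_wet Numeric length 12, mean wet-day precipitation (mm).
#' @param srad_clearness Fraction of extraterrestrial radiation reaching the
#'   ground on a dry day, in (0, 1].
#' @param wet_day_temp_offset Depression of tmax on wet days (deg C), >= 0.
#' @param wet_day_srad_factor Multiplier on radiation for wet days, in (0, 1].
#' @param srad_factor Numeric length 12, monthly radiation multiplier
#'   (scenario change factor; 1 for an unperturbed site).
#' @return A `site_climate` list.
#' @examples
#' dry <- demo_site_climate("dry")
#' dry$monthly_tmean
#' @export
site_climate <- function(site_id, latitude,
                         monthly_tmean, monthly_trange,
                         temp_sd = 2.5, temp_ar1 = 0.65,
                         p_wet_given_dry, p_wet_given_wet,
                         gamma_shape = 0.75, gamma_mean_wet,
                         srad_clearness = 0.5,
                         wet_day_temp_offset = 1.5,
                         wet_day_srad_factor = 0.55,
                         srad_factor = rep(1, 12)) {
  len12 <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, 12L)
    if (length(x) != 12L) abort(paste0("`", nm, "` must have length 12 (or 1)"))
    as.numeric(x)
  }
  obj <- structure(list(
    site_id = as.character(site_id),
    latitude = as.numeric(latitude),
    monthly_tmean = len12(monthly_tmean, "monthly_tmean"),
    monthly_trange = len12(monthly_trange, "monthly_trange"),
    temp_sd = as.numeric(temp_sd),
    temp_ar1 = as.numeric(temp_ar1),
    p_wet_given_dry = len12(p_wet_given_dry, "p_wet_given_dry"),
    p_wet_given_wet = len12(p_wet_given_wet, "p_wet_given_wet"),
    gamma_shape = as.numeric(gamma_shape),
    gamma_mean_wet = len12(gamma_mean_wet, "gamma_mean_wet"),
    srad_clearness = as.numeric(srad_clearness),
    wet_day_temp_offset = as.numeric(wet_day_temp_offset),
    wet_day_srad_factor = as.numeric(wet_day_srad_factor),
    srad_factor = len12(srad_factor, "srad_factor")
  ), class = "site_climate")
  validate_site_climate(obj)
}

validate_site_climate <- function(x) {
  stopifnot(inherits(x, "site_climate"))
  if (abs(x$latitude) >= 66.5) abort("polar latitudes (|lat| >= 66.5) are not supported")
  probs <- c(x$p_wet_given_dry, x$p_wet_given_wet)
  if (any(probs < 0 | probs > 1)) abort("transition probabilities must lie in [0, 1]")
  if (any(x$monthly_trange < 0)) abort("monthly_trange must be non-negative")
  if (x$gamma_shape <= 0) abort("gamma_shape must be > 0")
  if (any(x$gamma_mean_wet < 0)) abort("gamma_mean_wet must be non-negative")
  if (x$srad_clearness <= 0 || x$srad_clearness > 1) abort("srad_clearness must be in (0, 1]")
  if (x$temp_ar1 < 0 || x$temp_ar1 >= 1) abort("temp_ar1 must be in [0, 1)")
  if (x$wet_day_srad_factor <= 0 || x$wet_day_srad_factor > 1) {
    abort("wet_day_srad_factor must be in (0, 1]")
  }
  if (any(x$srad_factor <= 0)) abort("srad_factor must be > 0")
  x
}

#' @export
print.site_climate <- function(x, ...) {
  cat("<site_climate>", x$site_id, "at", x$latitude, "degN\n")
  cat("  annual tmean:", round(mean(x$monthly_tmean), 2), "degC;",
      "expected annual rain:", round(expected_annual_rain(x)), "mm\n")
  invisible(x)
}

# Stationary wet-day frequency of the monthly two-state chain.
stationary_wet_freq <- function(p_wd, p_ww) {
  p_wd / (1 + p_wd - p_ww)
}

expected_annual_rain <- function(climate) {
  pw <- stationary_wet_freq(climate$p_wet_given_dry, climate$p_wet_given_wet)
  sum(pw * climate$gamma_mean_wet * .MONTH_DAYS)
}

#' Define a climate-change scenario (change factors plus CO2)
#'
#' A scenario perturbs a site's climate statistics the way downscaled GCM
#' projections perturb a weather generator: additive monthly temperature
#' deltas, multiplicative monthly precipitation and radiation factors, and
#' an atmospheric CO2 concentration used by the crop model's fertilization
#' rule.
#'
#' @param label Character scenario label (e.g. a GCM name crossed with an RCP).
#' @param co2_ppm Atmospheric CO2 (umol/mol), > 0.
#' @param delta_tmean Numeric length 12 (or 1), additive monthly temperature
#'   change (deg C).
#' @param precip_factor Numeric length 12 (or 1), multiplier on mean wet-day
#'   precipitation, >= 0.
#' @param srad_factor Numeric length 12 (or 1), multiplier on solar
#'   radiation, > 0.
#' @return A `climate_scenario` list.
#' @examples
#' climate_scenario("warm+2", co2_ppm = 487, delta_tmean = 2)
#' @export
climate_scenario <- function(label, co2_ppm,
                             delta_tmean = 0, precip_factor = 1,
                             srad_factor = 1) {
  rep12 <- function(x) if (length(x) == 1L) rep(as.numeric(x), 12L) else as.numeric(x)
  obj <- structure(list(
    label = as.character(label),
    co2_ppm = as.numeric(co2_ppm),
    delta_tmean = rep12(delta_tmean),
    precip_factor = rep12(precip_factor),
    srad_factor = rep12(srad_factor)
  ), class = "climate_scenario")
  if (obj$co2_ppm <= 0) abort("co2_ppm must be > 0")
  if (length(obj$delta_tmean) != 12L || length(obj$precip_factor) != 12L ||
      length(obj$srad_factor) != 12L) {
    abort("monthly scenario fields must have length 12 (or 1)")
  }
  if (any(obj$precip_factor < 0)) abort("precip_factor must be >= 0")
  if (any(obj$srad_factor <= 0)) abort("srad_factor must be > 0")
  obj
}

#' Baseline (1981-2010-like) scenario: 363.8 ppm CO2, no perturbation
#'
#' @return A `climate_scenario` with co2_ppm = 363.8, zero temperature
#'   deltas and unit precipitation/radiation factors.
#' @export
baseline_scenario <- function() {
  climate_scenario("baseline", co2_ppm = 363.8)
}

#' @export
print.climate_scenario <- function(x, ...) {
  cat("<climate_scenario>", x$label, "| CO2", x$co2_ppm, "ppm |",
      "mean dT", round(mean(x$delta_tmean), 2), "degC |",
      "mean P factor", round(mean(x$precip_factor), 3), "\n")
  invisible(x)
}

#' Apply a climate scenario's change factors to a site climate
#'
#' Temperature deltas are added to the monthly means, precipitation factors
#' multiply the monthly mean wet-day amounts, and radiation factors multiply
#' the monthly effective clearness. All other statistics (occurrence chain,
#' variability, cross-effects) are left unchanged; the input is not modified.
#'
#' @param base A `site_climate`.
#' @param scenario A `climate_scenario`.
#' @return A new `site_climate` representing the perturbed climate.
#' @examples
#' shifted <- apply_scenario(demo_site_climate("dry"),
#'                           climate_scenario("p2", 487, delta_tmean = 2))
#' shifted$monthly_tmean - demo_site_climate("dry")$monthly_tmean
#' @export
apply_scenario <- function(base, scenario) {
  validate_site_climate(base)
  stopifnot(inherits(scenario, "climate_scenario"))
  out <- base
  out$monthly_tmean <- base$monthly_tmean + scenario$delta_tmean
  out$gamma_mean_wet <- base$gamma_mean_wet * scenario$precip_factor
  out$srad_factor <- base$srad_factor * scenario$srad_factor
  validate_site_climate(out)
}
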