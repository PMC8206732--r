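#' Generate seeded multi-year synthetic daily weather for a site
#'
#' Each harvest year is generated as an independent season-spanning series
#' running from 1 October of the previous calendar year through 31 August of
#' the harvest year (365-day non-leap calendar), which covers the fixed
#' 20 October sowing date. Precipitation occurrence follows a monthly
#' first-order two-state Markov chain; wet-day amounts are gamma-distributed
#' with month-specific means and a shared shape. Daily mean temperature is a
#' smooth seasonal cycle (monthly means interpolated to days) plus an AR(1)
#' residual; tmax/tmin are tmean +/- half the monthly diurnal range, with a
#' tmax depression on wet days. Radiation is clearness times extraterrestrial
#' radiation at the site latitude, reduced on wet days.
#'
#' One child RNG seed is derived per year from `seed`, so years are
#' independent and the output is bitwise reproducible.
#'
#' @param climate A [site_climate()] object (possibly perturbed by
#'   [apply_scenario()]).
#' @param n_years Number of harvest years to generate (>= 1).
#' @param seed Integer master seed.
#' @param first_year First harvest-year label (cosmetic; default 2001).
#' @return A tibble with columns `site`, `year` (harvest year), `doy`,
#'   `tmin`, `tmax`, `rain`, `srad`, one row per day, days consecutive
#'   within each year's series.
#' @examples
#' w <- generate_weather(demo_site_climate("dry"), n_years = 2, seed = 1)
#' dplyr::count(w, year)
#' @export
generate_weather <- function(climate, n_years, seed, first_year = 2001L) {
  validate_site_climate(climate)
  if (n_years < 1) abort("n_years must be >= 1")
  seeds <- derive_seeds(seed, n_years)
  years <- purrr::map(seq_len(n_years), function(i) {
    generate_season_weather(climate, seeds[i], first_year + i - 1L)
  })
  dplyr::bind_rows(years)
}

# doy sequence for one season: 1 Oct (doy 274) year-1 .. 31 Aug (doy 243).
season_doys <- function() {
  c(274:365, 1:243)
}

generate_season_weather <- function(climate, seed, harvest_year) {
  doys <- season_doys()
  n <- length(doys)
  mon <- month_of_doy(doys)

  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  # Precipitation occurrence: monthly first-order Markov chain.
  p_wd <- climate$p_wet_given_dry[mon]
  p_ww <- climate$p_wet_given_wet[mon]
  u <- runif(n)
  wet <- logical(n)
  state <- u[1] < stationary_wet_freq(p_wd[1], p_ww[1])
  wet[1] <- state
  for (i in 2:n) {
    p <- if (state) p_ww[i] else p_wd[i]
    state <- u[i] < p
    wet[i] <- state
  }

  # Wet-day amounts: gamma with monthly mean, shared shape.
  rain <- numeric(n)
  mu <- climate$gamma_mean_wet[mon]
  idx <- which(wet & mu > 0)
  if (length(idx)) {
    rain[idx] <- rgamma(length(idx), shape = climate$gamma_shape,
                        scale = mu[idx] / climate$gamma_shape)
  }

  # Temperature: interpolated seasonal cycle + AR(1) residual. Knots are
  # adjusted so that calendar-month averages of the daily cycle reproduce
  # the configured monthly means exactly.
  cycle <- seasonal_cycle(monthly_knots(climate$monthly_tmean), doys)
  trange <- seasonal_cycle(climate$monthly_trange, doys)
  z <- rnorm(n)
  e <- numeric(n)
  phi <- climate$temp_ar1
  e[1] <- climate$temp_sd * z[1]
  innov_sd <- climate$temp_sd * sqrt(1 - phi^2)
  for (i in 2:n) e[i] <- phi * e[i - 1] + innov_sd * z[i]
  tmean <- cycle + e
  tmax <- tmean + trange / 2 - ifelse(wet, climate$wet_day_temp_offset, 0)
  tmin <- tmean - trange / 2
  tmax <- pmax(tmax, tmin) # wet-day depression never inverts the range

  # Radiation: clearness x extraterrestrial, monthly change factor,
  # wet-day reduction.
  ra <- extraterrestrial_radiation(climate$latitude, doys)
  srad <- climate$srad_clearness * climate$srad_factor[mon] * ra
  srad <- srad * ifelse(wet, climate$wet_day_srad_factor, 1)

  tibble::tibble(
    site = climate$site_id,
    year = as.integer(harvest_year),
    doy = as.integer(doys),
    tmin = tmin, tmax = tmax,
    rain = rain, srad = pmax(0, srad)
  )
}

# Periodic linear interpolation of 12 mid-month knot values to daily values.
seasonal_cycle <- function(monthly, doys) {
  x <- c(.MONTH_MID[12] - 365, .MONTH_MID, .MONTH_MID[1] + 365)
  y <- c(monthly[12], monthly, monthly[1])
  stats::approx(x, y, xout = doys)$y
}

# Mid-month knot values whose interpolated daily cycle averages back to the
# given monthly means (12x12 linear system; the averaging matrix is fixed
# by the calendar).
monthly_knots <- function(monthly) {
  as.numeric(solve(month_avg_matrix(), monthly))
}

.calendar_cache <- new.env(parent = emptyenv())

month_avg_matrix <- function() {
  if (is.null(.calendar_cache$A)) {
    doys <- 1:365
    mon <- month_of_doy(doys)
    A <- matrix(0, 12, 12)
    for (j in 1:12) {
      e <- numeric(12)
      e[j] <- 1
      A[, j] <- tapply(seasonal_cycle(e, doys), mon, mean)
    }
    .calendar_cache$A <- A
  }
  .calendar_cache$A
}

#' Build a synthetic GCM-like scenario ensemble for one RCP
#'
#' Emulates the spread of a multi-model climate ensemble for a 2050 horizon:
#' all members share the RCP's CO2 concentration (487 ppm for RCP 4.5,
#' 541 ppm for RCP 8.5) but differ in monthly temperature deltas and
#' precipitation/radiation factors. Each member draws a winter and a summer
#' anomaly from normal distributions given in `spread_spec`; monthly values
#' are a smooth cosine interpolation between the two (January = winter,
#' July = summer).
#'
#' @param n_members Number of ensemble members (the study design uses 19).
#' @param rcp `"RCP4.5"` or `"RCP8.5"`.
#' @param seed Integer seed; the same seed reproduces the same ensemble.
#' @param spread_spec Named list overriding any of the spread parameters:
#'   `dt_winter_mean`, `dt_winter_sd`, `dt_summer_mean`, `dt_summer_sd`
#'   (deg C), `pf_winter_mean`, `pf_winter_sd`, `pf_summer_mean`,
#'   `pf_summer_sd` (precipitation factors), `sf_sd` (radiation factor sd).
#'   Defaults represent mid-century anomalies over Great Britain: modest
#'   warming (stronger in summer), slightly wetter winters, drier summers.
#' @return A list of `n_members` [climate_scenario()] objects.
#' @examples
#' ens <- make_gcm_ensemble(3, "RCP8.5", seed = 7)
#' vapply(ens, function(s) s$co2_ppm, numeric(1))
#' @export
make_gcm_ensemble <- function(n_members, rcp, seed, spread_spec = list()) {
  if (n_members < 1) abort("n_members must be >= 1")
  defaults <- switch(rcp,
    "RCP4.5" = list(co2 = 487,
                    dt_winter_mean = 1.4, dt_winter_sd = 0.45,
                    dt_summer_mean = 1.9, dt_summer_sd = 0.55,
                    pf_winter_mean = 1.05, pf_winter_sd = 0.06,
                    pf_summer_mean = 0.90, pf_summer_sd = 0.08,
                    sf_sd = 0.02),
    "RCP8.5" = list(co2 = 541,
                    dt_winter_mean = 1.8, dt_winter_sd = 0.55,
                    dt_summer_mean = 2.5, dt_summer_sd = 0.65,
                    pf_winter_mean = 1.07, pf_winter_sd = 0.07,
                    pf_summer_mean = 0.85, pf_summer_sd = 0.10,
                    sf_sd = 0.03),
    abort(paste0("unknown RCP label: ", rcp))
  )
  spec <- utils::modifyList(defaults, spread_spec)

  # January is fully "winter", July fully "summer".
  wgt_summer <- (1 - cos(2 * pi * (1:12 - 1) / 12)) / 2

  seeds <- derive_seeds(seed, n_members)
  purrr::map(seq_len(n_members), function(m) {
    old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seeds[m])
    dt_w <- rnorm(1, spec$dt_winter_mean, spec$dt_winter_sd)
    dt_s <- rnorm(1, spec$dt_summer_mean, spec$dt_summer_sd)
    pf_w <- max(0, rnorm(1, spec$pf_winter_mean, spec$pf_winter_sd))
    pf_s <- max(0, rnorm(1, spec$pf_summer_mean, spec$pf_summer_sd))
    sf <- max(0.5, rnorm(1, 1, spec$sf_sd))
    climate_scenario(
      label = sprintf("%s-gcm%02d", rcp, m),
      co2_ppm = spec$co2,
      delta_tmean = dt_w + (dt_s - dt_w) * wgt_summer,
      precip_factor = pf_w + (pf_s - pf_w) * wgt_summer,
      srad_factor = rep(sf, 12)
    )
  })
}
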