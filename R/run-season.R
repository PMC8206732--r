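#' Advance vernalization by one day
#'
#' Vernal-day accumulation uses a triangular effectiveness over the
#' cultivar's effective temperature range: a full vernal-day at the range
#' midpoint, declining linearly to zero at the bounds. Progress saturates at
#' 1; the final mainstem leaf number interpolates from the unvernalized
#' maximum down to the fully-vernalized minimum.
#'
#' @param vern_progress Current progress, fraction in [0, 1].
#' @param tmean Daily mean temperature (deg C).
#' @param cultivar A [cultivar_params()].
#' @return List with updated `vern_progress` and the implied
#'   `final_leaf_number`.
#' @examples
#' vernalization_step(0, 6, cultivar_params())
#' @export
vernalization_step <- function(vern_progress, tmean, cultivar) {
  eff <- vernalization_effectiveness(tmean, cultivar)
  vp <- min(1, vern_progress + eff / cultivar$vern_full)
  fln <- cultivar$max_leaf_number -
    (cultivar$max_leaf_number - cultivar$min_leaf_number) * vp
  list(vern_progress = vp, final_leaf_number = fln)
}

#' Simulate one winter wheat season
#'
#' Daily-timestep simulation from sowing to maturity. Emergence occurs a
#' fixed thermal time after sowing; thereafter development accumulates
#' thermal time modulated by a photoperiod factor, with vernalization
#' setting the final leaf number. Anthesis is reached when development
#' exceeds `phyllochron * (final_leaf_number + 2.5)`; maturity a further
#' `grain_fill_duration` later. Canopy LAI tracks leaf stage up to a cap
#' and senesces during grain fill (faster under water stress). Biomass
#' accumulates as RUE x intercepted PAR, multiplied by the CO2 fertilization
#' factor, a temperature factor and (when `water_limited`) the moisture
#' choking function of root-zone FTSW. Ear mass is a fixed fraction of
#' anthesis biomass; grain number is ear mass times the cultivar's potential
#' grains per gram, reduced by the anthesis-window grain-set factor; grain
#' mass is post-anthesis assimilation plus remobilized reserves, capped by
#' grain number times potential grain weight.
#'
#' @param weather A tibble of daily weather for one season (columns `doy`,
#'   `tmin`, `tmax`, `rain`, `srad`), consecutive days covering sowing
#'   through at least 31 August.
#' @param cultivar A [cultivar_params()].
#' @param soil A [soil_profile()].
#' @param co2_ppm Atmospheric CO2 concentration (umol/mol).
#' @param water_limited If `FALSE`, the water stress multiplier is forced to
#'   1 everywhere (potential run); the water balance is still tracked.
#' @param sowing_doy Sowing day-of-year (default 293 = 20 October).
#' @param latitude Site latitude (degrees north).
#' @return A one-row tibble: `yield` (t/ha), `anthesis_doy`, `maturity_doy`,
#'   `season_et` (mm), `swd_anthesis` (mm), `temp_sum` (deg C d),
#'   `rain_total` (mm), `intercepted_rad` (MJ m-2), `biomass` (g m-2),
#'   `grain_number` (m-2), `grain_set` (fraction), `failed` (logical).
#'   A season that fails to reach anthesis or maturity within the weather
#'   record has `failed = TRUE` and `NA` outcomes.
#' @examples
#' w <- generate_weather(demo_site_climate("wet"), 1, seed = 3)
#' run_season(w, cultivar_params(), soil_profile(), co2_ppm = 363.8,
#'            latitude = 54.5)
#' @export
run_season <- function(weather, cultivar, soil, co2_ppm,
                       water_limited = TRUE, sowing_doy = 293,
                       latitude = 52) {
  stopifnot(inherits(cultivar, "cultivar_params"), inherits(soil, "soil_profile"))
  doy <- weather$doy
  s <- match(sowing_doy, doy)
  if (is.na(s)) abort("weather does not contain the sowing day")
  n <- length(doy)
  idx <- s:n

  tmin <- weather$tmin[idx]; tmax <- weather$tmax[idx]
  rain <- weather$rain[idx]; srad <- weather$srad[idx]
  doy <- doy[idx]
  nd <- length(idx)

  tmean <- (tmin + tmax) / 2
  tt <- thermal_time_increment(tmin, tmax, cultivar$t_base)
  cum_tt <- cumsum(tt)
  dl <- daylength(latitude, doy)
  fp <- photoperiod_factor(dl, cultivar)
  ftemp <- temperature_factor(tmean)
  pet <- potential_et(srad, tmean)
  co2f <- co2_rue_factor(co2_ppm)

  failed_result <- function() {
    tibble::tibble(
      yield = NA_real_, anthesis_doy = NA_integer_, maturity_doy = NA_integer_,
      season_et = NA_real_, swd_anthesis = NA_real_, temp_sum = NA_real_,
      rain_total = NA_real_, intercepted_rad = NA_real_, biomass = NA_real_,
      grain_number = NA_real_, grain_set = NA_real_, failed = TRUE
    )
  }

  # Phenology, resolved ahead of the water loop (it does not depend on water).
  e <- match(TRUE, cum_tt >= cultivar$emergence_tt)
  if (is.na(e)) return(failed_result())
  post <- e:nd
  eff <- vernalization_effectiveness(tmean[post], cultivar)
  vp <- pmin(1, cumsum(eff) / cultivar$vern_full)
  fln <- cultivar$max_leaf_number -
    (cultivar$max_leaf_number - cultivar$min_leaf_number) * vp
  dev <- cumsum((tt * fp)[post])
  anth_rel <- match(TRUE, dev >= cultivar$phyllochron * (fln + 2.5))
  if (is.na(anth_rel)) return(failed_result())
  dev_anth <- dev[anth_rel]
  mat_rel <- match(TRUE, dev >= dev_anth + cultivar$grain_fill_duration)
  if (is.na(mat_rel)) return(failed_result())
  anth <- e + anth_rel - 1L
  mat <- e + mat_rel - 1L

  # Pre-anthesis LAI follows leaf stage; grain-fill senescence is handled in
  # the loop because water stress accelerates it.
  lai_pre <- pmin(cultivar$lai_max, cultivar$lai_per_leaf * dev / cultivar$phyllochron)

  cap <- soil$layer_capacity
  sw <- rep(cap * soil$initial_fill, soil$n_layers)
  n_evap <- soil$n_evap_layers
  # Root depth depends only on thermal time; precompute reachable layers.
  n_root_day <- pmax(1L, pmin(soil$n_layers,
    as.integer(pmin(soil$depth_mm, cultivar$root_growth * cum_tt) %/% 50) + 1L))

  biomass <- 0; ear_mass <- 0; biomass_anth <- 0
  grain_assim <- 0
  lai <- 0; lai_anth <- 0; senesced <- 0
  season_et <- 0; intercepted <- 0
  swd_anthesis <- NA_real_
  win_lo <- anth - cultivar$stress_window
  win_hi <- min(mat, anth + cultivar$stress_window)
  exp_f_water <- numeric(0); exp_tmax <- numeric(0)

  for (i in seq_len(mat)) {
    emerged <- i >= e
    j <- i - e + 1L # index into post-emergence vectors

    # Root zone and stress state at start of day.
    n_root <- n_root_day[i]
    ftsw <- sum(sw[1:n_root]) / (cap * n_root)
    f_w <- if (water_limited) min(1, max(0, ftsw) / 0.5) else 1

    if (emerged) {
      if (i <= anth) {
        lai <- lai_pre[j]
      } else {
        # Senescence during grain fill, accelerated by water stress.
        dtt <- tt[i] * fp[i]
        senesced <- senesced + dtt / cultivar$grain_fill_duration * (2 - f_w)
        lai <- max(0, lai_anth * (1 - senesced))
      }
      fint <- 1 - exp(-cultivar$k_ext * lai)
      db <- cultivar$rue * co2f * 0.5 * srad[i] * fint * ftemp[i] * f_w
      biomass <- biomass + db
      intercepted <- intercepted + srad[i] * fint
      if (i > anth) grain_assim <- grain_assim + db
      if (i == anth) {
        ear_mass <- cultivar$ear_partition * biomass
        biomass_anth <- biomass
        lai_anth <- lai
        swd_anthesis <- soil$awc_total - sum(sw)
      }
      if (i >= win_lo && i <= win_hi) {
        exp_f_water <- c(exp_f_water, f_w)
        exp_tmax <- c(exp_tmax, tmax[i])
      }
    } else {
      fint <- 0
    }

    # Water balance (the moisture choking function, threshold 0.5, also
    # limits soil evaporation). Inlined equivalent of soil_water_update():
    # top-down infiltration, surface-layer evaporation, root-zone
    # transpiration, each withdrawal proportional to content.
    f_evap <- min(1, (sum(sw[1:n_evap]) / (cap * n_evap)) / 0.5)
    evap_dem <- pet[i] * (1 - fint) * f_evap
    transp_dem <- pet[i] * fint * f_w
    inflow <- rain[i]
    if (inflow > 0) {
      for (l in 1:length(sw)) {
        take <- min(inflow, cap - sw[l])
        sw[l] <- sw[l] + take
        inflow <- inflow - take
        if (inflow <= 0) break
      }
    }
    avail_e <- sum(sw[1:n_evap])
    evap_act <- min(evap_dem, avail_e)
    if (evap_act > 0) sw[1:n_evap] <- sw[1:n_evap] * (1 - evap_act / avail_e)
    avail_t <- sum(sw[1:n_root])
    transp_act <- min(transp_dem, avail_t)
    if (transp_act > 0) sw[1:n_root] <- sw[1:n_root] * (1 - transp_act / avail_t)
    season_et <- season_et + evap_act + transp_act
  }

  exposure <- data.frame(f_water = exp_f_water, tmax = exp_tmax)
  gsf <- grain_set_factor(exposure, cultivar)
  grain_number <- ear_mass * cultivar$grains_per_ear_mass * gsf
  grain_cap <- grain_number * cultivar$potential_grain_weight / 1000 # g m-2
  grain_mass <- min(grain_assim + cultivar$reserve_fraction * biomass_anth,
                    grain_cap)

  tibble::tibble(
    yield = grain_mass / 100, # 1 t/ha = 100 g/m2
    anthesis_doy = as.integer(doy[anth]),
    maturity_doy = as.integer(doy[mat]),
    season_et = season_et,
    swd_anthesis = swd_anthesis,
    temp_sum = sum(tt[seq_len(mat)]),
    rain_total = sum(rain[seq_len(mat)]),
    intercepted_rad = intercepted,
    biomass = biomass,
    grain_number = grain_number,
    grain_set = gsf,
    failed = FALSE
  )
}

#' Run the four-cultivar stress-decomposition set on one season
#'
#' Runs the same weather through four configurations: potential (tolerant
#' cultivar, water limitation off), water-limited tolerant, water-limited
#' drought-sensitive, and water-limited heat-sensitive. The four yields
#' (Yp, Yw, Ywd, Ywh) feed the water/drought/heat stress indices; the
#' returned diagnostics are those of the water-limited tolerant run.
#'
#' @inheritParams run_season
#' @param base_cultivar A [cultivar_params()]; its sensitivity flags are
#'   overridden per run.
#' @return A one-row tibble with `yp`, `yw`, `ywd`, `ywh` (t/ha), `failed`,
#'   and the water-limited tolerant run's diagnostic columns.
#' @examples
#' w <- generate_weather(demo_site_climate("dry"), 1, seed = 9)
#' run_cultivar_set(w, cultivar_params(), soil_profile(), co2_ppm = 363.8,
#'                  latitude = 51.5)
#' @export
run_cultivar_set <- function(weather, base_cultivar, soil, co2_ppm,
                             sowing_doy = 293, latitude = 52) {
  variant <- function(drought, heat) {
    cv <- base_cultivar
    cv$drought_sensitive <- drought
    cv$heat_sensitive <- heat
    cv
  }
  tol <- variant(FALSE, FALSE)
  rp <- run_season(weather, tol, soil, co2_ppm, water_limited = FALSE,
                   sowing_doy = sowing_doy, latitude = latitude)
  rw <- run_season(weather, tol, soil, co2_ppm, water_limited = TRUE,
                   sowing_doy = sowing_doy, latitude = latitude)
  rd <- run_season(weather, variant(TRUE, FALSE), soil, co2_ppm,
                   water_limited = TRUE, sowing_doy = sowing_doy,
                   latitude = latitude)
  rh <- run_season(weather, variant(FALSE, TRUE), soil, co2_ppm,
                   water_limited = TRUE, sowing_doy = sowing_doy,
                   latitude = latitude)
  diag <- dplyr::select(rw, -"yield", -"failed")
  tibble::tibble(
    yp = rp$yield, yw = rw$yield, ywd = rd$yield, ywh = rh$yield,
    failed = rp$failed | rw$failed | rd$failed | rh$failed
  ) |>
    dplyr::bind_cols(diag)
}
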