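#' Built-in demonstration site climates
#'
#' Two synthetic GB-like sites spanning the national water-deficit contrast:
#' `"dry"` resembles the warm, low-rainfall southeast (about 600 mm/yr) and
#' `"wet"` the cool, high-rainfall northwest (about 1300 mm/yr). Their
#' statistics are invented but seasonally realistic; they are study
#' conditions for tests and demos, not fitted to any station.
#'
#' @param which `"dry"` or `"wet"`.
#' @return A [site_climate()].
#' @examples
#' demo_site_climate("wet")
#' @export
demo_site_climate <- function(which = c("dry", "wet")) {
  which <- match.arg(which)
  if (which == "dry") {
    site_climate(
      site_id = "dry_southeast", latitude = 51.5,
      monthly_tmean = c(4.5, 4.7, 6.5, 8.8, 12.0, 15.0, 17.2, 17.0, 14.5, 11.0, 7.2, 5.0),
      monthly_trange = c(6, 6.5, 7.5, 8.5, 9, 9, 9.5, 9.5, 8.5, 7, 6, 5.5),
      p_wet_given_dry = c(0.32, 0.28, 0.28, 0.26, 0.24, 0.22, 0.20, 0.22, 0.24, 0.30, 0.33, 0.33),
      p_wet_given_wet = c(0.57, 0.53, 0.53, 0.51, 0.49, 0.47, 0.45, 0.47, 0.49, 0.55, 0.58, 0.58),
      gamma_mean_wet = c(4.2, 3.8, 3.6, 3.6, 3.8, 4.2, 4.5, 4.8, 4.2, 4.8, 4.8, 4.5),
      srad_clearness = 0.50
    )
  } else {
    site_climate(
      site_id = "wet_northwest", latitude = 54.5,
      monthly_tmean = c(3.8, 3.9, 5.5, 7.6, 10.5, 13.2, 15.2, 15.0, 12.8, 9.8, 6.2, 4.2),
      monthly_trange = c(5.5, 6, 7, 8, 8.5, 8.5, 8.5, 8.5, 7.5, 6.5, 5.5, 5),
      p_wet_given_dry = c(0.48, 0.44, 0.44, 0.40, 0.38, 0.36, 0.36, 0.40, 0.42, 0.48, 0.50, 0.50),
      p_wet_given_wet = c(0.72, 0.68, 0.68, 0.64, 0.62, 0.60, 0.60, 0.64, 0.66, 0.72, 0.74, 0.74),
      gamma_mean_wet = c(6.8, 5.8, 5.5, 5.2, 5.0, 5.2, 5.8, 6.2, 6.2, 7.0, 7.2, 7.0),
      srad_clearness = 0.42
    )
  }
}

#' Assemble a run manifest
#'
#' The manifest fixes every axis of an ensemble run: the sites, the
#' scenarios (e.g. a baseline plus GCM-member scenarios), the cultivar and
#' soil, the sowing date, the number of years per cell and the master seed
#' from which all per-cell seeds are derived.
#'
#' @param sites List of [site_climate()] objects.
#' @param scenarios List of [climate_scenario()] objects.
#' @param cultivar A [cultivar_params()].
#' @param soil A [soil_profile()].
#' @param sowing_doy Sowing day-of-year (default 293 = 20 October).
#' @param n_years Years per site x scenario cell (default 100).
#' @param master_seed Integer master seed.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(sites, scenarios, cultivar = cultivar_params(),
                         soil = soil_profile(), sowing_doy = 293,
                         n_years = 100, master_seed = 1) {
  stopifnot(length(sites) >= 1, length(scenarios) >= 1,
            inherits(cultivar, "cultivar_params"),
            inherits(soil, "soil_profile"))
  purrr::walk(sites, validate_site_climate)
  if (sowing_doy < 274 || sowing_doy > 365) {
    abort("sowing_doy must fall in October-December (274..365)")
  }
  if (n_years < 2) abort("n_years must be >= 2")
  structure(list(
    sites = sites, scenarios = scenarios, cultivar = cultivar, soil = soil,
    sowing_doy = as.integer(sowing_doy), n_years = as.integer(n_years),
    master_seed = as.integer(master_seed)
  ), class = "run_manifest")
}

#' Desk-scale demonstration manifest
#'
#' A self-contained configuration exercising the dry-southeast versus
#' wet-northwest contrast: the two [demo_site_climate()] sites, the baseline
#' scenario plus a small GCM-like ensemble for one RCP, 30 years per cell.
#'
#' @param seed Master seed (also seeds the scenario ensemble).
#' @param n_gcms Number of GCM-like members (default 3).
#' @param n_years Years per cell (default 30).
#' @param rcp RCP label for the future members (default `"RCP8.5"`).
#' @return A `run_manifest`.
#' @examples
#' demo_fixture(seed = 1)
#' @export
demo_fixture <- function(seed = 1, n_gcms = 3, n_years = 30, rcp = "RCP8.5") {
  run_manifest(
    sites = list(demo_site_climate("dry"), demo_site_climate("wet")),
    scenarios = c(list(baseline_scenario()),
                  make_gcm_ensemble(n_gcms, rcp, seed = seed)),
    n_years = n_years,
    master_seed = seed
  )
}

WEATHER_COLS <- c("site", "year", "doy", "tmin", "tmax", "rain", "srad")

#' Write / read daily weather CSV
#'
#' Plain CSV with header `site,year,doy,tmin,tmax,rain,srad`, one row per
#' day, preceded by a comment line recording the 365-day calendar
#' convention. Reading validates the physical invariants (tmin <= tmax,
#' rain >= 0, srad >= 0, no missing values) and day continuity within each
#' site-year series, reporting offending data rows by number.
#'
#' @param weather A tibble as produced by [generate_weather()].
#' @param path File path.
#' @return `write_weather_csv()` returns `path` invisibly;
#'   `read_weather_csv()` returns the validated tibble.
#' @export
write_weather_csv <- function(weather, path) {
  stopifnot(all(WEATHER_COLS %in% names(weather)))
  writeLines("# wheatclim daily weather; non-leap 365-day calendar", path)
  readr::write_csv(weather[WEATHER_COLS], path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  w <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(
                         site = readr::col_character(),
                         year = readr::col_integer(),
                         doy = readr::col_integer(),
                         .default = readr::col_double()
                       ))
  if (nrow(w) == 0) abort("empty weather file")
  if (!identical(names(w), WEATHER_COLS)) {
    abort(paste0("weather CSV header must be: ", paste(WEATHER_COLS, collapse = ",")))
  }
  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond)) {
      rows <- which(cond | is.na(cond))
      abort(sprintf("%s at data row(s): %s", what,
                    paste(head(rows, 5), collapse = ", ")))
    }
  }
  bad_row(is.na(w$tmin) | is.na(w$tmax) | is.na(w$rain) | is.na(w$srad),
          "missing values")
  bad_row(w$tmin > w$tmax, "tmin > tmax")
  bad_row(w$rain < 0, "negative rain")
  bad_row(w$srad < 0, "negative srad")
  check_gaps <- function(d) {
    step <- diff(d$doy)
    ok <- step == 1L | step == (1L - 365L)
    if (any(!ok)) {
      abort(sprintf("non-consecutive days in series %s/%d near data row %d",
                    d$site[1], d$year[1], which(!ok)[1]))
    }
    d
  }
  w |> dplyr::group_by(.data$site, .data$year) |>
    dplyr::group_map(~check_gaps(.x), .keep = TRUE) # validation only
  w
}

#' Save / load a run manifest as YAML
#'
#' The manifest and its embedded site, scenario, cultivar and soil
#' definitions round-trip through a structured YAML file. Loading applies
#' strict schema validation: unknown keys are rejected (typo safety) and the
#' usual constructor checks run on every block. Defaults follow the study
#' design (sowing 20 October, AWC 177 mm soil, 100 years).
#'
#' @param manifest A `run_manifest`.
#' @param path File path.
#' @return `save_manifest()` returns `path` invisibly; `load_manifest()`
#'   returns a validated `run_manifest`.
#' @export
save_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.function, TRUE)]
  }
  doc <- list(
    sites = purrr::map(manifest$sites, strip),
    scenarios = purrr::map(manifest$scenarios, strip),
    cultivar = strip(manifest$cultivar)[names(formals(cultivar_params))],
    soil = strip(manifest$soil)[c("awc_total", "n_layers", "evap_layer_depth",
                                  "initial_fill")],
    sowing_doy = manifest$sowing_doy,
    n_years = manifest$n_years,
    master_seed = manifest$master_seed
  )
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname save_manifest
#' @export
load_manifest <- function(path) {
  doc <- yaml::read_yaml(path)
  known_top <- c("sites", "scenarios", "cultivar", "soil", "sowing_doy",
                 "n_years", "master_seed")
  reject_unknown(doc, known_top, "manifest")
  build <- function(block, constructor, what) {
    reject_unknown(block, names(formals(constructor)), what)
    do.call(constructor, block)
  }
  cultivar <- build(doc$cultivar %||% list(), cultivar_params, "cultivar")
  soil <- build(doc$soil %||% list(), soil_profile, "soil")
  sites <- purrr::map(doc$sites %||% list(),
                      ~build(.x, site_climate, "site"))
  scenarios <- purrr::map(doc$scenarios %||% list(list(label = "baseline",
                                                       co2_ppm = 363.8)),
                          ~build(.x, climate_scenario, "scenario"))
  run_manifest(
    sites = sites,
    scenarios = scenarios,
    cultivar = cultivar,
    soil = soil,
    sowing_doy = doc$sowing_doy %||% 293,
    n_years = doc$n_years %||% 100,
    master_seed = doc$master_seed %||% 1
  )
}

reject_unknown <- function(block, known, what) {
  extra <- setdiff(names(block), known)
  if (length(extra)) {
    abort(sprintf("unknown %s key(s): %s", what, paste(extra, collapse = ", ")))
  }
}
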