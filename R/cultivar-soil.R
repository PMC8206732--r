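#' Parameterize a winter wheat cultivar
#'
#' Defaults describe an obligate winter wheat with a moderate-to-weak
#' daylength response, loosely calibrated so that unstressed GB seasons
#' yield around 8-12 t/ha. The `drought_sensitive` and `heat_sensitive`
#' flags control whether grain set around flowering responds to window
#' stress; the four-run design of the stress-index analysis uses a tolerant
#' cultivar (both flags off, with and without water limitation) and the two
#' single-sensitivity variants.
#'
#' @param t_base Thermal-time base temperature (deg C).
#' @param phyllochron Thermal time per leaf (deg C d).
#' @param min_leaf_number,max_leaf_number Final mainstem leaf number when
#'   fully vernalized / unvernalized.
#' @param vern_full Vernal-days required for full vernalization.
#' @param vern_t_min,vern_t_max Bounds of the effective vernalizing
#'   temperature range (deg C); effectiveness is triangular, peaking at the
#'   midpoint.
#' @param photoperiod_sens Dimensionless photoperiod sensitivity (>= 0).
#' @param daylength_saturation Daylength (h) above which development is
#'   unrestricted by photoperiod.
#' @param rue Radiation-use efficiency (g DM per MJ intercepted PAR).
#' @param k_ext Canopy extinction coefficient.
#' @param lai_per_leaf Leaf area index added per mainstem leaf stage.
#' @param lai_max Maximum leaf area index.
#' @param ear_partition Fraction of pre-anthesis biomass in ears at anthesis.
#' @param grains_per_ear_mass Potential grain number per g ear dry mass.
#' @param potential_grain_weight Potential single-grain weight (mg).
#' @param grain_fill_duration Grain-filling duration (deg C d).
#' @param reserve_fraction Fraction of anthesis biomass remobilizable to
#'   grain during filling.
#' @param drought_sensitive,heat_sensitive Logical grain-set sensitivity
#'   flags for the anthesis stress window.
#' @param heat_threshold Daily tmax (deg C) above which heat damages florets.
#' @param stress_window Days before/after anthesis over which sink stress
#'   acts.
#' @param s_d Slope of the drought grain-set response (per unit mean water
#'   stress over the window).
#' @param s_h Slope of the heat grain-set response (per deg C d above
#'   `heat_threshold`).
#' @param grain_set_floor Lower bound on the grain-set factor.
#' @param emergence_tt Thermal time from sowing to emergence (deg C d).
#' @param root_growth Root-depth growth per unit thermal time (mm per deg C d).
#' @return A `cultivar_params` list.
#' @examples
#' cultivar_params(heat_sensitive = TRUE)$heat_threshold
#' @export
cultivar_params <- function(t_base = 0, phyllochron = 100,
                            min_leaf_number = 8, max_leaf_number = 14,
                            vern_full = 40, vern_t_min = 0, vern_t_max = 12,
                            photoperiod_sens = 0.6, daylength_saturation = 16,
                            rue = 2.2, k_ext = 0.45,
                            lai_per_leaf = 0.75, lai_max = 6.5,
                            ear_partition = 0.25, grains_per_ear_mass = 100,
                            potential_grain_weight = 45,
                            grain_fill_duration = 650,
                            reserve_fraction = 0.40,
                            drought_sensitive = FALSE, heat_sensitive = FALSE,
                            heat_threshold = 27, stress_window = 5,
                            s_d = 1.0, s_h = 0.05, grain_set_floor = 0.2,
                            emergence_tt = 150, root_growth = 1.0) {
  obj <- structure(as.list(environment()), class = "cultivar_params")
  num <- obj[!names(obj) %in% c("drought_sensitive", "heat_sensitive")]
  if (any(unlist(num) < 0)) abort("cultivar parameters must be non-negative")
  if (obj$vern_t_max <= obj$vern_t_min) abort("vern_t_max must exceed vern_t_min")
  if (obj$min_leaf_number > obj$max_leaf_number) {
    abort("min_leaf_number must not exceed max_leaf_number")
  }
  stopifnot(is.logical(obj$drought_sensitive), is.logical(obj$heat_sensitive))
  obj
}

#' Parameterize a layered soil profile
#'
#' The profile is discretized into 5-cm layers sharing the total available
#' water capacity equally. The default capacity (177 mm) corresponds to a
#' medium-AWC British soil; the profile is full at sowing by default.
#'
#' @param awc_total Total available water capacity (mm), > 0.
#' @param n_layers Number of 5-cm layers (default 30, i.e. 150 cm).
#' @param evap_layer_depth Depth (cm) subject to soil evaporation.
#' @param initial_fill Initial fraction of capacity filled, in [0, 1].
#' @return A `soil_profile` list with derived `layer_capacity` (mm) and
#'   `depth_mm`.
#' @examples
#' soil_profile()$layer_capacity
#' @export
soil_profile <- function(awc_total = 177, n_layers = 30,
                         evap_layer_depth = 10, initial_fill = 1.0) {
  if (awc_total <= 0) abort("awc_total must be > 0")
  if (initial_fill < 0 || initial_fill > 1) abort("initial_fill must be in [0, 1]")
  n_layers <- as.integer(n_layers)
  if (n_layers < 1) abort("n_layers must be >= 1")
  structure(list(
    awc_total = as.numeric(awc_total),
    n_layers = n_layers,
    layer_thickness = 5, # cm, fixed
    layer_capacity = awc_total / n_layers,
    depth_mm = n_layers * 50,
    evap_layer_depth = as.numeric(evap_layer_depth),
    n_evap_layers = max(1L, min(n_layers, as.integer(ceiling(evap_layer_depth / 5)))),
    initial_fill = as.numeric(initial_fill)
  ), class = "soil_profile")
}
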