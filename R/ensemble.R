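#' Simulate one site under one climate scenario for many years
#'
#' Applies the scenario's change factors to the site climate, generates
#' `n_years` of synthetic daily weather, runs the four-cultivar stress set
#' each year, computes the yearly stress indices, and summarizes them.
#' Fully deterministic for a fixed seed.
#'
#' @param site A [site_climate()].
#' @param scenario A [climate_scenario()].
#' @param n_years Number of simulated years (>= 2).
#' @param seed Integer seed for the weather generator.
#' @param cultivar A [cultivar_params()].
#' @param soil A [soil_profile()].
#' @param sowing_doy Sowing day-of-year (default 293 = 20 October).
#' @param keep_years If `TRUE`, attach the per-year table as attribute
#'   `"years"`.
#' @return A one-row tibble: `site`, `scenario`, `n_years`, `n_failed`,
#'   `mean_yield` (water-limited, t/ha), `cv` (%), the stress-index
#'   percentiles (`wsi_p50`..`hsi_p95`), and mean diagnostics
#'   (`mean_anthesis_doy`, `mean_maturity_doy`, `mean_season_et`,
#'   `mean_swd_anthesis`, `mean_temp_sum`, `mean_rain_total`,
#'   `mean_intercepted_rad`). Warns if more than 10% of seasons failed.
#' @export
run_site_scenario <- function(site, scenario, n_years, seed, cultivar, soil,
                              sowing_doy = 293, keep_years = FALSE) {
  if (n_years < 2) abort("n_years must be >= 2")
  perturbed <- apply_scenario(site, scenario)
  weather <- generate_weather(perturbed, n_years, seed)
  years <- weather |>
    dplyr::group_by(.data$year) |>
    dplyr::group_map(function(w, key) {
      dplyr::bind_cols(tibble::tibble(year = key$year),
                       run_cultivar_set(w, cultivar, soil,
                                        co2_ppm = scenario$co2_ppm,
                                        sowing_doy = sowing_doy,
                                        latitude = site$latitude))
    }) |>
    dplyr::bind_rows()

  n_failed <- sum(years$failed)
  if (n_failed > 0.1 * n_years) {
    warn(sprintf("%s / %s: %d of %d seasons failed",
                 site$site_id, scenario$label, n_failed, n_years))
  }
  ok <- dplyr::filter(years, !.data$failed)
  if (nrow(ok) < 2) abort("too few successful seasons to summarize")
  ix <- suppressWarnings(compute_indices(ok))

  if (nrow(ok) < 20) warn("fewer than 20 successful years; percentiles will be noisy")
  pct <- function(which) {
    p <- suppressWarnings(index_percentiles(ix, which))
    setNames(as.numeric(p[1, c("p50", "p75", "p90", "p95")]),
             paste0(which, "_", c("p50", "p75", "p90", "p95")))
  }
  out <- tibble::tibble(
    site = site$site_id,
    scenario = scenario$label,
    n_years = as.integer(n_years),
    n_failed = as.integer(n_failed),
    mean_yield = mean(ok$yw),
    cv = coefficient_of_variation(ok$yw),
    !!!pct("wsi"), !!!pct("dsi"), !!!pct("hsi"),
    mean_anthesis_doy = mean(ok$anthesis_doy),
    mean_maturity_doy = mean(ok$maturity_doy),
    mean_season_et = mean(ok$season_et),
    mean_swd_anthesis = mean(ok$swd_anthesis),
    mean_temp_sum = mean(ok$temp_sum),
    mean_rain_total = mean(ok$rain_total),
    mean_intercepted_rad = mean(ok$intercepted_rad)
  )
  if (keep_years) attr(out, "years") <- ix
  out
}

#' Boxplot statistics over an ensemble of values
#'
#' Follows the whisker convention used throughout the figures of this kind
#' of multi-model analysis: box at the 25th/75th percentiles, line at the
#' median, whiskers at the 10th and 90th percentiles, values outside the
#' whiskers listed as outliers.
#'
#' @param values Numeric vector, one value per ensemble member (>= 2).
#' @return A one-row tibble: `p10`, `q25`, `median`, `q75`, `p90`,
#'   `n_outliers`, and `outliers` (list-column of the outlying values).
#' @examples
#' boxplot_stats(1:19)
#' @export
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("need at least 2 values")
  p <- percentile(values, c(0.10, 0.25, 0.50, 0.75, 0.90))
  out <- values[values < p[1] | values > p[5]]
  tibble::tibble(p10 = p[1], q25 = p[2], median = p[3], q75 = p[4], p90 = p[5],
                 n_outliers = length(out), outliers = list(out))
}

#' Unweighted spatial average of per-site summaries
#'
#' Averages every numeric metric (including each index percentile,
#' metric-wise) across the sites of one scenario, mirroring countrywide
#' averaging over a site network.
#'
#' @param summaries A tibble of [run_site_scenario()] rows sharing one
#'   scenario.
#' @return A one-row tibble with `site = "spatial_mean"` and each numeric
#'   column averaged.
#' @export
spatial_average <- function(summaries) {
  stopifnot(nrow(summaries) >= 1)
  if (length(unique(summaries$scenario)) != 1) {
    abort("spatial_average requires summaries from a single scenario")
  }
  summaries |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                     .by = "scenario") |>
    dplyr::mutate(site = "spatial_mean", .before = 1)
}

#' Recurrence interval of a percentile-based loss level
#'
#' A loss at the `q` percentile is exceeded with probability `1 - q`, i.e.
#' on average once every `1/(1-q)` years: the 50th, 75th, 90th and 95th
#' percentiles correspond to 2-, 4-, 10- and 20-year events.
#'
#' @param q Percentile probability in (0, 1); vectorized.
#' @return Recurrence interval in years.
#' @examples
#' recurrence_interval(c(0.5, 0.75, 0.9, 0.95))
#' @export
recurrence_interval <- function(q) {
  if (any(q <= 0 | q >= 1)) abort("q must lie strictly in (0, 1)")
  1 / (1 - q)
}

#' Yield-loss versus recurrence-interval curve
#'
#' Expresses the water-stress-index percentiles of a summary as loss levels
#' against their average frequency of occurrence.
#'
#' @param summary A one-row tibble with `wsi_p50`, `wsi_p75`, `wsi_p90`,
#'   `wsi_p95` columns (a [run_site_scenario()] or [spatial_average()] row).
#' @return A tibble with columns `site`, `scenario`, `q`,
#'   `recurrence_years` (2, 4, 10, 20) and `wsi_loss`.
#' @export
loss_frequency_curve <- function(summary) {
  stopifnot(nrow(summary) == 1)
  q <- c(0.50, 0.75, 0.90, 0.95)
  tibble::tibble(
    site = summary$site %||% NA_character_,
    scenario = summary$scenario,
    q = q,
    recurrence_years = recurrence_interval(q),
    wsi_loss = as.numeric(summary[1, paste0("wsi_p", c(50, 75, 90, 95))])
  )
}

#' Run a full site x scenario ensemble
#'
#' Orchestrates every (site, scenario) cell of a run manifest with
#' deterministically derived per-cell seeds, so cells can be computed in any
#' order with identical results. Scenario ensembles (e.g. the GCM members of
#' an RCP) are summarized per member and then reduced to boxplot statistics
#' per site and metric.
#'
#' @param manifest A `run_manifest` from [run_manifest()], [load_manifest()]
#'   or [demo_fixture()].
#' @return A `wheat_ensemble` object: list with tibbles `summaries` (one row
#'   per site x scenario), `boxplots` (per site x scenario-group x metric),
#'   `loss_curves`, and the `manifest`. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
run_ensemble <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  sites <- manifest$sites
  scenarios <- manifest$scenarios
  cells <- tidyr::expand_grid(si = seq_along(sites), sc = seq_along(scenarios))
  cell_seeds <- derive_seeds(manifest$master_seed, nrow(cells))

  summaries <- purrr::pmap(
    list(cells$si, cells$sc, cell_seeds),
    function(si, sc, cell_seed) {
      run_site_scenario(sites[[si]], scenarios[[sc]], manifest$n_years,
                        cell_seed, manifest$cultivar, manifest$soil,
                        sowing_doy = manifest$sowing_doy)
    }
  ) |> dplyr::bind_rows()

  groups <- scenario_groups(scenarios)
  summaries$group <- groups[match(summaries$scenario,
                                  vapply(scenarios, `[[`, "", "label"))]

  metrics <- c("mean_yield", "cv", "wsi_p95", "dsi_p95", "hsi_p95",
               "mean_anthesis_doy", "mean_maturity_doy")
  boxplots <- summaries |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric") |>
    dplyr::group_by(.data$site, .data$group, .data$metric) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) >= 2) boxplot_stats(d$value)
      else tibble::tibble(p10 = d$value, q25 = d$value, median = d$value,
                          q75 = d$value, p90 = d$value, n_outliers = 0L,
                          outliers = list(numeric(0)))
    }) |>
    dplyr::ungroup()

  loss_curves <- summaries |>
    dplyr::rowwise() |>
    dplyr::group_map(function(d, ...) loss_frequency_curve(d)) |>
    dplyr::bind_rows()

  structure(list(summaries = summaries, boxplots = boxplots,
                 loss_curves = loss_curves, manifest = manifest),
            class = "wheat_ensemble")
}

# Group GCM-member scenarios by their RCP prefix (label "RCPx.y-gcmNN");
# anything else groups as itself.
scenario_groups <- function(scenarios) {
  vapply(scenarios, function(s) sub("-gcm[0-9]+$", "", s$label), "")
}

#' @export
print.wheat_ensemble <- function(x, ...) {
  cat("<wheat_ensemble>",
      length(x$manifest$sites), "site(s) x",
      length(x$manifest$scenarios), "scenario(s) x",
      x$manifest$n_years, "years\n")
  print(glance(x))
  invisible(x)
}

#' @rdname run_ensemble
#' @param x A `wheat_ensemble`.
#' @param ... Unused.
#' @export
tidy.wheat_ensemble <- function(x, ...) {
  x$summaries |>
    tidyr::pivot_longer(dplyr::where(is.numeric),
                        names_to = "metric", values_to = "value") |>
    dplyr::select("site", "scenario", "group", "metric", "value")
}

#' @rdname run_ensemble
#' @method glance wheat_ensemble
#' @export
glance.wheat_ensemble <- function(x, ...) {
  x$summaries |>
    dplyr::summarise(
      n_sites = dplyr::n_distinct(.data$site),
      n_members = dplyr::n(),
      mean_yield = mean(.data$mean_yield),
      mean_cv = mean(.data$cv),
      mean_wsi95 = mean(.data$wsi_p95),
      .by = "group"
    )
}
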