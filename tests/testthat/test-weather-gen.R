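test_that("baseline scenario application is the identity", {
  base <- demo_site_climate("dry")
  out <- apply_scenario(base, baseline_scenario())
  expect_identical(out, base)
})

test_that("temperature deltas are additive, precipitation factors multiplicative", {
  base <- demo_site_climate("wet")
  sc <- climate_scenario("shift", co2_ppm = 487, delta_tmean = 2,
                         precip_factor = 0.8, srad_factor = 1.1)
  out <- apply_scenario(base, sc)
  expect_equal(out$monthly_tmean, base$monthly_tmean + 2)
  expect_equal(out$gamma_mean_wet, base$gamma_mean_wet * 0.8)
  expect_equal(out$srad_factor, base$srad_factor * 1.1)
  # everything else untouched
  expect_identical(out$p_wet_given_dry, base$p_wet_given_dry)
  expect_identical(out$temp_sd, base$temp_sd)
  # input unmodified
  expect_identical(base, demo_site_climate("wet"))
})

test_that("negative precipitation factors are rejected", {
  expect_error(climate_scenario("bad", 400, precip_factor = -0.1), "precip_factor")
})

test_that("zero precipitation factor annihilates rainfall", {
  base <- demo_site_climate("dry")
  dryer <- apply_scenario(base, climate_scenario("none", 400, precip_factor = 0))
  w <- generate_weather(dryer, n_years = 2, seed = 4)
  expect_equal(sum(w$rain), 0)
})

test_that("a degenerate occurrence chain produces an all-dry series", {
  base <- demo_site_climate("dry")
  base$p_wet_given_dry[] <- 0
  base$p_wet_given_wet[] <- 0
  w <- generate_weather(base, n_years = 1, seed = 2)
  expect_equal(sum(w$rain), 0)
})

test_that("generation is bitwise reproducible for a fixed seed", {
  cl <- demo_site_climate("wet")
  expect_identical(generate_weather(cl, 3, seed = 42),
                   generate_weather(cl, 3, seed = 42))
  expect_false(identical(generate_weather(cl, 3, seed = 42),
                         generate_weather(cl, 3, seed = 43)))
})

test_that("every generated day satisfies the physical invariants", {
  withr::with_seed(7, {
    for (k in 1:3) {
      w <- generate_weather(random_site_climate(), n_years = 2, seed = k)
      expect_true(all(w$tmin <= w$tmax))
      expect_true(all(w$rain >= 0))
      expect_true(all(w$srad >= 0))
      # consecutive days (365-day calendar wrap)
      for (y in unique(w$year)) {
        step <- diff(w$doy[w$year == y])
        expect_true(all(step == 1L | step == -364L))
      }
    }
  })
})

test_that("long-run wet-day frequency matches the chain's stationary distribution", {
  # Stationary law of the 2-state chain: p_wd/(1 + p_wd - p_ww);
  # 0.3/(1 + 0.3 - 0.6) = 0.42857.
  base <- demo_site_climate("dry")
  base$p_wet_given_dry[] <- 0.3
  base$p_wet_given_wet[] <- 0.6
  w <- generate_weather(base, n_years = 300, seed = 5) # ~1e5 days
  expect_equal(mean(w$rain > 0), 0.3 / (1 + 0.3 - 0.6), tolerance = 0.02)
})

test_that("generated monthly means track the configured climate within 3 SE", {
  cl <- demo_site_climate("dry")
  w <- generate_weather(cl, n_years = 200, seed = 8)
  w$month <- wheatclim:::month_of_doy(w$doy)
  w$tmean <- (w$tmin + w$tmax) / 2
  per_year <- dplyr::summarise(w, tmean = mean(tmean),
                               .by = c("year", "month"))
  stats <- dplyr::summarise(per_year, m = mean(tmean),
                            se = sd(tmean) / sqrt(dplyr::n()), .by = "month")
  # wet-day tmax depression pulls the realized mean slightly below the
  # seasonal cycle; account for it exactly
  pw <- wheatclim:::stationary_wet_freq(cl$p_wet_given_dry, cl$p_wet_given_wet)
  target <- cl$monthly_tmean - pw * cl$wet_day_temp_offset / 2
  expect_true(all(abs(stats$m - target[stats$month]) <= 3 * stats$se))
})

test_that("wet-day amounts average to the configured gamma means within 3 SE", {
  cl <- demo_site_climate("wet")
  w <- generate_weather(cl, n_years = 200, seed = 9)
  w$month <- wheatclim:::month_of_doy(w$doy)
  wet <- dplyr::filter(w, rain > 0)
  stats <- dplyr::summarise(wet, m = mean(rain),
                            se = sd(rain) / sqrt(dplyr::n()), .by = "month")
  expect_true(all(abs(stats$m - cl$gamma_mean_wet[stats$month]) <= 3 * stats$se))
})

test_that("scenario warming shifts generated temperatures by the delta", {
  base <- demo_site_climate("dry")
  plus2 <- apply_scenario(base, climate_scenario("p2", 487, delta_tmean = 2))
  w0 <- generate_weather(base, 50, seed = 3)
  w2 <- generate_weather(plus2, 50, seed = 3)
  d <- mean((w2$tmin + w2$tmax) / 2) - mean((w0$tmin + w0$tmax) / 2)
  expect_equal(d, 2, tolerance = 0.05)
})

test_that("GCM-like ensembles share the RCP CO2 and are seeded", {
  ens <- make_gcm_ensemble(19, "RCP8.5", seed = 10)
  expect_length(ens, 19)
  expect_true(all(vapply(ens, function(s) s$co2_ppm, 1) == 541))
  ens45 <- make_gcm_ensemble(5, "RCP4.5", seed = 10)
  expect_true(all(vapply(ens45, function(s) s$co2_ppm, 1) == 487))
  expect_identical(make_gcm_ensemble(7, "RCP4.5", seed = 1),
                   make_gcm_ensemble(7, "RCP4.5", seed = 1))
  expect_error(make_gcm_ensemble(3, "RCP6.0", seed = 1), "unknown RCP")
})

test_that("a zero-spread single member equals the ensemble-mean anomalies", {
  spec <- list(dt_winter_mean = 1.5, dt_winter_sd = 0, dt_summer_mean = 2.5,
               dt_summer_sd = 0, pf_winter_mean = 1.05, pf_winter_sd = 0,
               pf_summer_mean = 0.85, pf_summer_sd = 0, sf_sd = 0)
  s <- make_gcm_ensemble(1, "RCP4.5", seed = 3, spread_spec = spec)[[1]]
  expect_equal(s$delta_tmean[1], 1.5)  # January = winter
  expect_equal(s$delta_tmean[7], 2.5)  # July = summer
  expect_equal(s$precip_factor[7], 0.85)
  expect_equal(s$srad_factor, rep(1, 12))
})
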