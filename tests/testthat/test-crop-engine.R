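test_that("daylength follows the sunrise equation", {
  # Equator: ~12 h year-round; equinox: ~12 h anywhere.
  expect_equal(daylength(0, 1), 12, tolerance = 0.02)
  expect_equal(daylength(0, 180), 12, tolerance = 0.02)
  expect_equal(daylength(51.8, 80), 12, tolerance = 0.02)
  # Independent hand computation near the summer solstice at 51.8 N:
  # decl = 0.409*sin(2*pi*172/365 - 1.39) = 0.40900 rad;
  # cos(ws) = -tan(0.90408)*tan(0.40900) = -0.55069; ws = 2.15417 rad;
  # daylength = 24/pi * ws = 16.454 h.
  expect_equal(daylength(51.8, 172), 16.454, tolerance = 0.01)
  expect_error(daylength(70, 172), "polar")
})

test_that("thermal time is the base-clamped daily mean", {
  expect_equal(thermal_time_increment(2, 10, 0), 6)
  expect_equal(thermal_time_increment(-5, -1, 0), 0)
  expect_equal(thermal_time_increment(-2, 6, 0), 2)
  expect_error(thermal_time_increment(5, 3, 0), "tmin")
})

test_that("CO2 fertilization of RUE is linear with +30% at doubling", {
  expect_equal(co2_rue_factor(364), 1)
  expect_equal(co2_rue_factor(728), 1.30)
  expect_equal(co2_rue_factor(541), 1 + 0.3 * 177 / 364) # = 1.14588
  expect_error(co2_rue_factor(0), "co2")
})

test_that("the moisture choking function is piecewise linear and monotone", {
  expect_equal(water_stress_factor(1), 1)
  expect_equal(water_stress_factor(0), 0)
  expect_equal(water_stress_factor(0.25), 0.5)
  expect_equal(water_stress_factor(0.5), 1)
  f <- water_stress_factor(seq(0, 1, by = 0.01))
  expect_ordered(f)
})

test_that("potential ET matches the stated formula and is linear in radiation", {
  expect_equal(potential_et(0, 15), 0)
  # Hand evaluation: s(15) = 4098*0.6108*exp(17.27*15/252.3)/252.3^2
  #                        = 0.10977 kPa/degC;
  # 1.26 * 0.10977/(0.10977+0.066) * (0.6*20)/2.45 = 3.8547 mm.
  expect_equal(potential_et(20, 15), 3.8547, tolerance = 1e-3)
  expect_equal(potential_et(40, 15), 2 * potential_et(20, 15))
  t_grid <- potential_et(20, seq(-5, 30, by = 1))
  expect_true(all(t_grid >= 0))
})

test_that("vernalization accumulates triangular vernal-days and saturates", {
  cv <- cultivar_params() # effective range 0..12, optimum 6, vern_full 40
  st <- list(vern_progress = 0)
  for (d in 1:40) st <- vernalization_step(st$vern_progress, 6, cv)
  expect_equal(st$vern_progress, 1)
  expect_equal(st$final_leaf_number, cv$min_leaf_number)
  # saturation: no further change
  st2 <- vernalization_step(1, 6, cv)
  expect_equal(st2$vern_progress, 1)
  # ineffective temperatures
  expect_equal(vernalization_step(0.5, 30, cv)$vern_progress, 0.5)
  expect_equal(vernalization_step(0.5, -3, cv)$vern_progress, 0.5)
  # half effectiveness halfway between optimum and edge
  st3 <- vernalization_step(0, 9, cv)
  expect_equal(st3$vern_progress, 0.5 / cv$vern_full)
})

test_that("soil water balance closes exactly and never goes negative", {
  soil <- soil_profile(awc_total = 177, n_layers = 30)
  withr::with_seed(21, {
    for (rep in 1:100) { # 100 random synthetic seasons of daily fluxes
      sw <- runif(soil$n_layers, 0, soil$layer_capacity)
      for (day in 1:60) {
        rain <- if (runif(1) < 0.4) rgamma(1, 0.7, scale = 6) else 0
        ev <- runif(1, 0, 3)
        tr <- runif(1, 0, 5)
        nr <- sample(soil$n_layers, 1)
        before <- sum(sw)
        upd <- soil_water_update(sw, rain, ev, tr, soil, nr)
        sw <- upd$soil_water
        expect_true(all(sw >= 0 & sw <= soil$layer_capacity + 1e-12))
        balance <- rain - upd$evap_actual - upd$transp_actual - upd$drainage
        expect_equal(sum(sw) - before, balance, tolerance = 1e-9)
      }
    }
  })
})

test_that("soil water update handles the degenerate cases", {
  soil <- soil_profile(awc_total = 100, n_layers = 10)
  full <- rep(soil$layer_capacity, 10)
  upd <- soil_water_update(full, 10, 0, 0, soil)
  expect_equal(upd$drainage, 10)
  expect_equal(upd$soil_water, full)
  empty <- rep(0, 10)
  upd2 <- soil_water_update(empty, 0, 0, 5, soil)
  expect_equal(upd2$transp_actual, 0)
  upd3 <- soil_water_update(full, 0, 0, 0, soil)
  expect_equal(upd3$soil_water, full)
  expect_equal(upd3$drainage, 0)
})

test_that("grain set responds to window stress per sensitivity flags", {
  win <- data.frame(f_water = rep(0.8, 11), tmax = rep(31, 11))
  tol <- cultivar_params()
  expect_equal(grain_set_factor(win, tol), 1)
  dr <- cultivar_params(drought_sensitive = TRUE) # s_d = 1
  expect_equal(grain_set_factor(win, dr), 1 - 1.0 * 0.2)
  ht <- cultivar_params(heat_sensitive = TRUE) # s_h = 0.05, threshold 27
  expect_equal(grain_set_factor(win, ht),
               max(0.2, 1 - 0.05 * sum(rep(31 - 27, 11))))
  # no heat exposure -> no heat loss
  cool <- data.frame(f_water = rep(1, 11), tmax = rep(20, 11))
  expect_equal(grain_set_factor(cool, ht), 1)
  # floor engages under extreme stress
  severe <- data.frame(f_water = rep(0, 11), tmax = rep(40, 11))
  expect_equal(grain_set_factor(severe, dr), 0.2)
  expect_equal(grain_set_factor(severe, ht), 0.2)
})
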