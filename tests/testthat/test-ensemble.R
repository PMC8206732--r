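test_that("boxplot statistics follow the 10/25/50/75/90 convention", {
  b <- boxplot_stats(1:19)
  expect_equal(b$median, 10)
  expect_equal(b$q25, percentile(1:19, 0.25))
  const <- boxplot_stats(rep(4.2, 8))
  expect_equal(as.numeric(const[1, c("p10", "q25", "median", "q75", "p90")]),
               rep(4.2, 5))
  expect_equal(const$n_outliers, 0L)
  withr::with_seed(11, {
    for (k in 1:10) {
      v <- rnorm(25)
      b <- boxplot_stats(v)
      expect_ordered(as.numeric(b[1, c("p10", "q25", "median", "q75", "p90")]))
      expect_true(all(b$outliers[[1]] < b$p10 | b$outliers[[1]] > b$p90))
    }
  })
})

test_that("spatial averaging is the unweighted metric-wise mean", {
  two <- tibble::tibble(site = c("a", "b"), scenario = "baseline",
                        mean_yield = c(8, 12), cv = c(10, 14),
                        wsi_p95 = c(0.1, 0.3))
  avg <- spatial_average(two)
  expect_equal(avg$mean_yield, 10)
  expect_equal(avg$cv, 12)
  expect_equal(avg$wsi_p95, 0.2)
  expect_equal(avg$site, "spatial_mean")
  # permutation symmetry and single-site identity
  expect_equal(spatial_average(two[2:1, ]), avg)
  one <- spatial_average(two[1, ])
  expect_equal(one$mean_yield, 8)
  expect_error(spatial_average(dplyr::mutate(two, scenario = c("a", "b"))),
               "single scenario")
})

test_that("percentiles map to recurrence intervals via 1/(1-q)", {
  expect_equal(recurrence_interval(0.95), 20)
  expect_equal(recurrence_interval(0.90), 10)
  expect_equal(recurrence_interval(0.75), 4)
  expect_equal(recurrence_interval(0.50), 2)
  expect_error(recurrence_interval(1), "strictly")
})

test_that("the loss-frequency curve pairs WSI percentiles with 2/4/10/20 years", {
  row <- tibble::tibble(site = "x", scenario = "baseline",
                        wsi_p50 = 0.05, wsi_p75 = 0.10,
                        wsi_p90 = 0.15, wsi_p95 = 0.20)
  lc <- loss_frequency_curve(row)
  expect_equal(lc$recurrence_years, c(2, 4, 10, 20))
  expect_equal(lc$wsi_loss, c(0.05, 0.10, 0.15, 0.20))
  expect_ordered(lc$wsi_loss)
  zero <- loss_frequency_curve(dplyr::mutate(row, dplyr::across(
    dplyr::starts_with("wsi"), ~0)))
  expect_equal(zero$wsi_loss, rep(0, 4))
})

test_that("a site-scenario run is reproducible and CO2-monotone", {
  site <- demo_site_climate("dry")
  cv <- cultivar_params()
  soil <- soil_profile()
  short_run <- function(...) suppressWarnings(run_site_scenario(...)) # < 20 yr warns
  s1 <- short_run(site, baseline_scenario(), 12, seed = 5, cv, soil)
  s2 <- short_run(site, baseline_scenario(), 12, seed = 5, cv, soil)
  expect_identical(s1, s2)
  # same climate, more CO2: fertilization alone raises mean yield
  rich <- climate_scenario("co2only", co2_ppm = 541)
  s3 <- short_run(site, rich, 12, seed = 5, cv, soil)
  expect_gt(s3$mean_yield, s1$mean_yield)
  # warming advances mean anthesis
  warm <- climate_scenario("warm", co2_ppm = 363.8, delta_tmean = 2)
  s4 <- short_run(site, warm, 12, seed = 5, cv, soil)
  expect_lt(s4$mean_anthesis_doy, s1$mean_anthesis_doy)
})

test_that("a full ensemble run is deterministic and summarizable", {
  mf <- demo_fixture(seed = 3, n_gcms = 2, n_years = 6)
  e1 <- suppressWarnings(run_ensemble(mf)) # 6-year cells warn about noise
  e2 <- suppressWarnings(run_ensemble(mf))
  expect_identical(e1$summaries, e2$summaries)
  expect_identical(e1$boxplots, e2$boxplots)
  expect_equal(nrow(e1$summaries), 2 * 3) # 2 sites x (baseline + 2 members)
  expect_setequal(unique(e1$summaries$group), c("baseline", "RCP8.5"))
  td <- tidy(e1)
  expect_true(all(c("site", "scenario", "metric", "value") %in% names(td)))
  gl <- glance(e1)
  expect_equal(nrow(gl), 2) # one row per scenario group
  lc <- e1$loss_curves
  expect_equal(sort(unique(lc$recurrence_years)), c(2, 4, 10, 20))
})

test_that("ensemble plots build without error", {
  mf <- demo_fixture(seed = 4, n_gcms = 2, n_years = 6)
  e <- suppressWarnings(run_ensemble(mf))
  p1 <- plot_ensemble_boxplots(e, "mean_yield")
  expect_s3_class(p1, "ggplot")
  p2 <- plot_loss_curves(e)
  expect_s3_class(p2, "ggplot")
  expect_s3_class(autoplot(e, "cv"), "ggplot")
  expect_error(plot_ensemble_boxplots(e, "nope"), "not summarized")
})
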