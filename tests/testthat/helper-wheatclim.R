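# Shared fixtures: all data is generated in code, seeded.

# A randomized but physically valid GB-like site climate, for property tests.
random_site_climate <- function(id = "rnd") {
  amp <- runif(1, 4, 7)
  base_t <- runif(1, 3.5, 6)
  tmean <- base_t + amp * (1 - cos(2 * pi * (1:12 - 1.2) / 12))
  p_wd <- runif(1, 0.2, 0.45)
  site_climate(
    site_id = id,
    latitude = runif(1, 50.5, 57),
    monthly_tmean = tmean,
    monthly_trange = runif(12, 5, 10),
    temp_sd = runif(1, 1.8, 3),
    temp_ar1 = runif(1, 0.4, 0.75),
    p_wet_given_dry = pmin(1, p_wd * runif(12, 0.8, 1.2)),
    p_wet_given_wet = pmin(1, (p_wd + runif(1, 0.15, 0.3)) * runif(12, 0.9, 1.1)),
    gamma_shape = runif(1, 0.6, 1.0),
    gamma_mean_wet = runif(12, 3, 7),
    srad_clearness = runif(1, 0.4, 0.55)
  )
}

# One season of weather for a given site climate (or the demo dry site).
one_season <- function(climate = demo_site_climate("dry"), seed = 1) {
  generate_weather(climate, n_years = 1, seed = seed)
}

expect_ordered <- function(x) {
  expect_true(all(diff(x) >= -1e-12))
}
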