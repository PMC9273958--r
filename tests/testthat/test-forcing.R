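test_that("flow and rain anomaly indices are simple scaled differences", {
  expect_equal(flow_index(9.2e11, 9.2e11), 0)
  expect_equal(flow_index(9.2e11 + 1e11, 9.2e11), 0.1)
  expect_equal(flow_index(9.2e11 - 2e11, 9.2e11), -0.2)
  expect_equal(rain_index(1.1, 1.1), 0)
  expect_equal(rain_index(1.35, 1.1), 0.25)
  expect_equal(rain_index(1.0, 1.1), -0.1)
})

test_that("annual series expand per step in both modes", {
  expect_equal(expand_annual(c(3, 3), grid = c(0, 200, 400), mode = "step"),
               c(3, 3, 3))
  # step mode: left-year value up to the boundary, right-year value after
  expect_equal(expand_annual(c(1, 2), grid = c(364.9, 365, 365.1),
                             mode = "step"), c(1, 2, 2))
  # linear mode: interpolation between year midpoints
  expect_equal(expand_annual(c(0.002, 0.004), grid = 365, mode = "linear"),
               0.003)
  expect_error(expand_annual(c(1, 2), grid = 800), "does not cover")
})

test_that("the synthetic forcing generator is seeded and structurally sound", {
  a <- synthesize_forcings(years = 2, seed = 7, dt = 0.5)
  b <- synthesize_forcings(years = 2, seed = 7, dt = 0.5)
  expect_identical(a$steps, b$steps)
  expect_identical(a$annual, b$annual)
  c <- synthesize_forcings(years = 2, seed = 8, dt = 0.5)
  expect_false(identical(a$steps$temperature_C, c$steps$temperature_C))
  expect_error(synthesize_forcings(years = 0, seed = 1), "years")
  expect_error(synthesize_forcings(years = 2, seed = 1, temp_amplitude = -1),
               "amplitude")
})

test_that("noise-free forcing is exactly periodic and means match the configuration", {
  fc <- synthesize_forcings(years = 3, seed = 1, dt = 0.5,
                            temp_mean = 18, warming_slope = 0, anomaly_sd = 0,
                            food_year_sd = 0)
  per <- 365 / 0.5
  x <- fc$steps$temperature_C
  expect_equal(x[1:per], x[per + 1:per], tolerance = 1e-12)
  expect_equal(mean(x), 18, tolerance = 1e-6) # exact cosine over whole years
  # stochastic mean stays near the configured value
  fc2 <- synthesize_forcings(years = 6, seed = 3, dt = 0.5, temp_mean = 18,
                             warming_slope = 0, anomaly_sd = 0.5)
  expect_equal(mean(fc2$steps$temperature_C), 18, tolerance = 0.05)
  # autumn food peak, winter trough
  prof <- fc$steps$food_index[1:per]
  doy <- fc$steps$t_days[1:per] %% 365
  expect_gt(mean(prof[doy > 244 & doy < 334]),  # Sep-Nov
            mean(prof[doy < 60]))               # Jan-Feb
})

test_that("generated forcings satisfy the series invariants across random configs", {
  set.seed(99)
  for (i in 1:60) {
    fc <- synthesize_forcings(
      years = sample(1:3, 1), seed = sample(1e6, 1), dt = 1,
      temp_mean = runif(1, 10, 25), temp_amplitude = runif(1, 0.5, 10),
      warming_slope = runif(1, -0.05, 0.1), anomaly_sd = runif(1, 0, 2),
      food_year_sd = runif(1, 0, 0.5), zf_annual = runif(1, 0, 0.01)
    )
    expect_true(all(is.finite(fc$steps$temperature_C)))
    expect_true(all(fc$steps$food_index >= 0))
    expect_true(all(fc$steps$Z_F >= 0))
    expect_equal(nrow(fc$steps), fc$years * 365)
  }
})

test_that("scenarios shift only their targeted variable and are invertible", {
  fc <- synthesize_forcings(years = 2, seed = 5, dt = 0.5)
  warm <- apply_scenario(fc, scenario(temperature_offset = 2.7,
                                      label = "SSP2-4.5"))
  expect_equal(warm$steps$temperature_C, fc$steps$temperature_C + 2.7)
  expect_identical(warm$steps$food_index, fc$steps$food_index)
  expect_identical(warm$steps$Z_F, fc$steps$Z_F)
  back <- apply_scenario(warm, scenario(temperature_offset = -2.7))
  expect_equal(back$steps$temperature_C, fc$steps$temperature_C,
               tolerance = 1e-12)
  # fishing multiplier by a power of two restores bit-exactly
  fish <- apply_scenario(fc, scenario(fishing_multiplier = 2))
  expect_identical(
    apply_scenario(fish, scenario(fishing_multiplier = 0.5))$steps$Z_F,
    fc$steps$Z_F)
  # the preset battery encodes the projected warming offsets and +/-10% effort
  pre <- scenario_presets()
  expect_equal(pre[["SSP1-1.9"]]$temperature_offset, 1.4)
  expect_equal(pre[["SSP5-8.5"]]$temperature_offset, 4.4)
  expect_equal(pre[["ZF+10%"]]$fishing_multiplier, 1.1)
})

test_that("forcings round-trip through the two-file CSV layout", {
  fc <- synthesize_forcings(years = 2, seed = 11, dt = 0.5)
  sp <- tempfile(fileext = ".csv"); ap <- tempfile(fileext = ".csv")
  on.exit(unlink(c(sp, ap)))
  write_forcings(fc, sp, ap)
  back <- read_forcings(sp, ap)
  expect_equal(back$steps$temperature_C, fc$steps$temperature_C)
  expect_equal(back$steps$Z_F, fc$steps$Z_F)
  expect_equal(back$annual$Z_F, fc$annual$Z_F)
  expect_equal(back$dt, fc$dt)
})

test_that("the functional response saturates and respects its half-saturation", {
  expect_equal(functional_response(0.22, K_food = 0.22), 0.5)
  expect_equal(functional_response(0), 0)
  expect_lt(functional_response(1e6), 1)
  expect_gt(functional_response(0.9), functional_response(0.3))
})
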