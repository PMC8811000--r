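test_that("maximum rise height matches hand-evaluated capillary statics", {
  expect_equal(max_height(wi_oil, wi_tis$vessels), 0.1008, tolerance = 1e-3)
  expect_equal(max_height(wi_water, wi_tis$latewood), 0.95952, tolerance = 1e-4)
  # wetting limit: capillary drive vanishes as theta -> 90
  nearly_neutral <- fluid("x", 997, 0.001, 0.073, 90 - 1e-9)
  expect_lt(max_height(nearly_neutral, wi_tis$latewood), 1e-9)
  non_wetting <- fluid("x", 997, 0.001, 0.073, 95)
  expect_error(max_height(non_wetting, wi_tis$latewood), class = "wi_invalid_parameter")
})

test_that("tube-bundle permeability follows the straight-tube closed form", {
  expect_equal(tube_bundle_permeability(0.15, 40e-6, 1), 3e-11)
  expect_equal(tube_bundle_permeability(0.2, 10e-6, 1), 2.5e-12)
  # exactly linear in 1/tortuosity
  expect_equal(tube_bundle_permeability(0.15, 40e-6, 2),
               tube_bundle_permeability(0.15, 40e-6, 1) / 2)
  expect_error(tube_bundle_permeability(0, 40e-6), class = "wi_invalid_parameter")
  expect_error(tube_bundle_permeability(0.15, 40e-6, 0.5), class = "wi_invalid_parameter")
})

test_that("closed-form rise times reproduce hand-evaluated references", {
  expect_equal(analytic_time(0, wi_oil, wi_tis$vessels), 0)
  expect_equal(analytic_time(0.05, wi_oil, wi_tis$vessels),
               T_OIL_VESSELS_5CM, tolerance = 5e-3)
  expect_equal(analytic_time(0.1, wi_water, wi_tis$latewood),
               T_WATER_LATEWOOD_10CM, tolerance = 5e-3)
  expect_equal(analytic_time(0.1, wi_water, wi_tis$fibers),
               T_WATER_FIBERS_10CM, tolerance = 5e-3)
  expect_error(analytic_time(1, wi_water, wi_tis$latewood), class = "wi_domain_error")
  # strictly increasing in h
  h <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(diff(analytic_time(h, wi_water, wi_tis$latewood)) > 0))
})

test_that("height inversion is the inverse function of the closed form", {
  expect_equal(height_at_time(0, wi_water, wi_tis$latewood), 0)
  # capped at the sample length once the closed-form time is exceeded
  expect_equal(height_at_time(T_OIL_VESSELS_10CM * 1.01, wi_oil, wi_tis$vessels),
               0.1)
  hmax <- max_height(wi_water, wi_tis$latewood)
  withr::with_seed(7, {
    h <- runif(100, 0.001, 0.9) * hmax
    t <- analytic_time(h, wi_water, wi_tis$latewood, gravity = 9.81)
    h2 <- height_at_time(t, wi_water, wi_tis$latewood, sample_geometry(length = 1))
    expect_equal(h2, h, tolerance = 1e-8)
  })
})

test_that("numeric integration agrees with the closed form on all preset scenarios", {
  cases <- list(
    list(wi_oil, wi_tis$vessels, 20000),
    list(wi_oil, wi_tis$latewood, 2.5e5),
    list(wi_water, wi_tis$latewood, 5000),
    list(wi_water, wi_tis$fibers, 10000)
  )
  for (cs in cases) {
    cv <- integrate_1d(cs[[1]], cs[[2]], t_end = cs[[3]],
                       settings = numerical_settings(dt_max = cs[[3]] / 2e4))
    pre <- cv[cv$time_s > 0 & !cv$capped & cv$height_m < 0.0999, ]
    ha <- height_at_time(pre$time_s, cs[[1]], cs[[2]])
    expect_lt(max(abs(pre$height_m - ha) / ha), 1e-3)
    # monotone non-decreasing front
    expect_true(all(diff(cv$height_m) >= 0))
    # h_eq is porosity times height at every sample
    expect_equal(cv$h_eq_m, cs[[2]]$porosity * cv$height_m)
  }
})

test_that("integration stops at the sample length at the closed-form cap time", {
  cv <- integrate_1d(wi_water, wi_tis$fibers, t_end = 2e4)
  expect_true(any(cv$capped))
  expect_equal(max(cv$height_m), 0.1)
  expect_equal(max(cv$time_s), T_WATER_FIBERS_10CM, tolerance = 1e-2)
  cv <- integrate_1d(wi_water, wi_tis$latewood, t_end = 2e4)
  expect_equal(max(cv$time_s), T_WATER_LATEWOOD_10CM, tolerance = 1e-2)
  # t_end = 0 degenerates to the single origin sample
  cv0 <- integrate_1d(wi_water, wi_tis$latewood, t_end = 0)
  expect_equal(nrow(cv0), 1L)
  expect_equal(cv0$height_m, 0)
})

test_that("gravity-free limit reproduces the square-root law after startup", {
  cv <- integrate_1d(wi_water, wi_tis$latewood, t_end = 100,
                     settings = numerical_settings(gravity = 0, dt_max = 1))
  a <- 4 * 0.073 * cos(50 * pi / 180) * 1e-15 / (10e-6 * 0.01 * 0.001)
  sel <- cv$time_s > 2
  expect_lt(max(abs(cv$height_m[sel] - sqrt(a * cv$time_s[sel])) /
                  sqrt(a * cv$time_s[sel])), 5e-3)
})

test_that("water rises in latewood faster than oil", {
  t_water <- analytic_time(0.1, wi_water, wi_tis$latewood)
  t_oil <- analytic_time(0.1, wi_oil, wi_tis$latewood)
  expect_lt(t_water, t_oil)
})

test_that("equivalent-height conversion is an elementwise porosity scaling", {
  cv <- integrate_1d(wi_water, wi_tis$latewood, t_end = 1000)
  out <- to_equivalent_height(cv, wi_tis$vessels)
  expect_equal(out$h_eq_m, 0.15 * cv$height_m)
  expect_equal(out$time_s, cv$time_s)
  unit <- to_equivalent_height(cv, tissue("all-pore", 1e-15, 1, 10e-6))
  expect_equal(unit$h_eq_m, unit$height_m)
})

test_that("curves write to delimited text with the documented columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  cv <- integrate_1d(wi_water, wi_tis$latewood, t_end = 500)
  write_imbibition_curve(cv, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(back, c("time_s", "height_m", "h_eq_m"))
  expect_equal(back$height_m, cv$height_m, tolerance = 1e-9)
})
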