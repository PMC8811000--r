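test_that("network construction discretises the sample as specified", {
  st <- build_network(wi_water, wi_tis$latewood, wi_tis$cross_section)
  expect_equal(st$n_elements, 100L)
  expect_equal(st$element_height, 0.001)
  expect_equal(st$h_lw, 0)
  expect_equal(st$y, rep(0, 100))
  expect_length(st$pressures, 0)

  st2 <- build_network(wi_water, wi_tis$latewood, wi_tis$cross_section,
                       settings = numerical_settings(n_elements = 2))
  expect_equal(st2$element_height, 0.05)

  expect_error(
    build_network(wi_water, wi_tis$latewood, wi_tis$cross_section,
                  geometry = sample_geometry(ring_width = -0.004)),
    class = "wi_invalid_parameter")
})

test_that("the meniscus boundary carries the latewood capillary suction exactly", {
  st <- build_network(wi_water, wi_tis$latewood, wi_tis$cross_section,
                      settings = numerical_settings(n_elements = 4))
  st$h_lw <- 0.03 # one wetted node, no lateral fronts
  sol <- solve_pressures(st, wi_water, wi_tis$latewood, wi_tis$cross_section)
  pc_lw <- 2 * 0.073 * cos(50 * pi / 180) / 10e-6
  expect_identical(sol$front_pressure, -pc_lw)
  expect_equal(sol$m, 1L)
  expect_true(all(sol$sinks == 0))
  expect_error(solve_pressures(build_network(wi_water, wi_tis$latewood,
                                             wi_tis$cross_section),
                               wi_water, wi_tis$latewood, wi_tis$cross_section),
               class = "wi_precondition")
})

test_that("nodal pressures match a hand-assembled two-node Kirchhoff system", {
  st <- build_network(wi_water, wi_tis$latewood, wi_tis$cross_section,
                      settings = numerical_settings(n_elements = 4))
  st$h_lw <- 0.055 # two wetted nodes, front segment delta = 5 mm
  st$y[1] <- 1e-4  # one active lateral front on the bottom element
  sol <- solve_pressures(st, wi_water, wi_tis$latewood, wi_tis$cross_section)

  # independent brute-force assembly of the same 2x2 linear system
  rho <- 997; grav <- 9.81; mu <- 1e-3; S <- 8e-4; W <- 4e-3
  dz <- 0.025; delta <- 0.005
  pc_lw <- 2 * 0.073 * cos(50 * pi / 180) / 10e-6
  pc_cs <- 2 * 0.073 * cos(50 * pi / 180) / 20e-6
  gl <- 1e-15 * S / (mu * dz)
  gf <- 1e-15 * S / (mu * delta)
  c1 <- 1e-18 / (mu * 1e-4) * (S * dz / W)
  A <- matrix(c(-(2 * gl + c1), gl,
                gl, -(gl + gf)), 2, 2, byrow = TRUE)
  b <- c(c1 * pc_cs,
         gl * rho * grav * dz - gf * rho * grav * delta + gf * pc_lw)
  P_hand <- solve(A, b)

  expect_equal(sol$pressures, P_hand, tolerance = 1e-12)
  expect_equal(sol$q_front, gf * (P_hand[2] + pc_lw - rho * grav * delta))
  expect_equal(sol$sinks[1], c1 * (P_hand[1] + pc_cs))
  # Kirchhoff: base inflow equals front uptake plus lateral sinks
  expect_lt(sol$residual, 1e-10)
  expect_equal(sol$q_base, sol$q_front + sum(sol$sinks))
})

test_that("front advances by flux over porosity; lateral by the frozen-pressure form", {
  st <- build_network(wi_water, wi_tis$latewood, wi_tis$cross_section,
                      settings = numerical_settings(n_elements = 4))
  st$h_lw <- 0.055
  st$y[1:2] <- c(1e-4, 2e-4) # element 2 has y > 0 so no activation occurs
  sol <- solve_pressures(st, wi_water, wi_tis$latewood, wi_tis$cross_section)
  dt <- 5
  out <- advance_fronts(st, sol, wi_tis$latewood, wi_tis$cross_section, dt)
  S <- 8e-4
  expect_equal(out$h_lw, st$h_lw + sol$q_front / (S * 0.01) * dt)
  expect_equal(out$y[1], sqrt(st$y[1]^2 + 2 * sol$lateral_k[1] * dt / 0.5))
  expect_equal(out$time, st$time + dt)

  # zero flux everywhere leaves the state unchanged
  null_sol <- sol
  null_sol$q_front <- 0
  null_sol$sinks[] <- 0
  null_sol$lateral_k[] <- 0
  frozen <- advance_fronts(st, null_sol, wi_tis$latewood, wi_tis$cross_section, dt)
  expect_equal(frozen$h_lw, st$h_lw)
  expect_equal(frozen$y, st$y)

  # a step violating the front CFL bound is rejected
  expect_error(advance_fronts(st, sol, wi_tis$latewood, wi_tis$cross_section, 1e9),
               class = "wi_step_rejected")
  expect_error(advance_fronts(st, sol, wi_tis$latewood, wi_tis$cross_section, 0),
               class = "wi_invalid_parameter")
})

test_that("a single lateral front at constant pressure follows the square-root law", {
  # brute-force oracle for the lateral update: dy/dt = K drive/(mu eps y)
  # integrates to y^2 = y0^2 + 2 K drive t / (mu eps)
  st <- build_network(wi_water, wi_tis$latewood, wi_tis$cross_section,
                      settings = numerical_settings(n_elements = 4))
  st$h_lw <- 0.055
  st$y[1] <- 1e-6
  drive <- 3000 # held constant
  k_lat <- 1e-18 * drive / 1e-3
  sol <- list(q_front = 0, sinks = rep(0, 4), lateral_k = c(k_lat, 0, 0, 0),
              pressures = numeric(0), capped = FALSE)
  t_tot <- 0
  for (i in 1:200) {
    st <- advance_fronts(st, sol, wi_tis$latewood, wi_tis$cross_section, 5)
    t_tot <- t_tot + 5
  }
  slope_expected <- 2 * 1e-18 * drive / (0.5 * 1e-3)
  expect_equal((st$y[1]^2 - 1e-12) / t_tot, slope_expected, tolerance = 1e-2)
})

test_that("volume is conserved and the decoupled limit reduces to the 1D model", {
  res <- run_2d(wi_water, wi_tis$latewood, wi_tis$cross_section, t_end = 3600)
  cons <- res$conservation
  ok <- cons$stored_m3 > 0
  expect_lt(max(abs(cons$inflow_m3[ok] - cons$stored_m3[ok]) / cons$stored_m3[ok]),
            5e-3)
  # coupling slows the rise relative to the pure 1D latewood solution
  h1d <- height_at_time(3600, wi_water, wi_tis$latewood)
  expect_lt(tail(res$curve$h_lw_m, 1), h1d)

  # zero lateral permeability: 2D trajectory collapses onto the 1D solution
  cs0 <- tissue("cross_section", 0, 0.5, 20e-6)
  r0 <- run_2d(wi_water, wi_tis$latewood, cs0, t_end = 3000)
  sel <- r0$curve$time_s > 50
  h1d <- height_at_time(r0$curve$time_s[sel], wi_water, wi_tis$latewood)
  expect_lt(max(abs(r0$curve$h_lw_m[sel] - h1d) / h1d), 5e-3)
  expect_equal(r0$curve$h_eq_m, 0.01 * r0$curve$h_lw_m)
})

test_that("front positions are monotone and lateral fronts stay within the ring", {
  res <- run_2d(wi_water, wi_tis$latewood, wi_tis$cross_section, t_end = 3600)
  expect_true(all(diff(res$curve$h_lw_m) >= 0))
  expect_true(all(diff(res$curve$h_eq_m) >= 0))
  st <- res$state
  expect_true(all(st$y >= 0 & st$y <= st$W))
  centers <- (seq_len(st$n_elements) - 0.5) * st$element_height
  expect_true(all(st$y[centers >= st$h_lw] == 0))
})

test_that("doubling the discretisation changes the trajectory by less than 1%", {
  r100 <- run_2d(wi_water, wi_tis$latewood, wi_tis$cross_section, t_end = 2400)
  r200 <- run_2d(wi_water, wi_tis$latewood, wi_tis$cross_section,
                 settings = numerical_settings(n_elements = 200), t_end = 2400)
  h100 <- tail(r100$curve$h_lw_m, 1)
  h200 <- tail(r200$curve$h_lw_m, 1)
  expect_lt(abs(h100 - h200) / h200, 1e-2)
})

test_that("moisture fields are sharp-front indicator grids", {
  res <- run_2d(wi_water, wi_tis$latewood, wi_tis$cross_section, t_end = 3600,
                snapshot_times = c(1200, 3000), n_lateral = 20)
  expect_length(res$fields, 2)
  f <- res$fields[[2]]
  expect_true(all(f$saturation %in% c(0, 1)))
  st_y <- res$state # front positions only grow, so saturation behind front only
  by_h <- split(f, f$height_index)
  for (grp in by_h) {
    s <- grp$saturation[order(grp$lateral_index)]
    expect_true(all(diff(s) <= 0)) # 1s then 0s: a sharp front
  }
  dir <- withr::local_tempdir()
  paths <- write_moisture_fields(res, dir)
  expect_true(all(file.exists(paths)))
  grid <- as.matrix(utils::read.csv(paths[[1]], header = FALSE))
  expect_equal(dim(grid), c(100L, 20L))
})
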