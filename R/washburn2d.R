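# Dual-scale 2D imbibition model for water in spruce: a latewood column rising
# by Washburn dynamics, discretised into n longitudinal elements, feeds slow
# lateral Darcy invasion of the surrounding earlywood (rays + connected
# tracheids, the "cross-section" tissue) at every wetted height. Each time
# step solves a Kirchhoff flux-conservation system (equality of pressure and
# conservation of fluxes at every node) for the nodal liquid pressures, then
# advances the longitudinal and lateral fronts.
#
# Conventions (shared with the 1D model): permeabilities and porosities are
# sample-section effective values, so fluxes use the full cross-section S and
# front speeds divide by the porosity. Lateral fronts carry the cross-section
# tissue's capillary suction and no gravity term (the lateral direction is
# horizontal). The earlywood liquid stored in element i is
# S * dz * eps_cs * (y_i / W): y_i/W is the laterally wetted fraction of the
# ring at that height.

#' Build the initial 2D network state
#'
#' @param fluid A [fluid()] object (used for validation only at build time).
#' @param latewood [tissue()] of the fast longitudinal pathway.
#' @param cross_section [tissue()] of the slow lateral pathway (zero
#'   permeability is allowed and decouples the model into the 1D limit).
#' @param geometry A [sample_geometry()]; the sample length is divided into
#'   `settings$n_elements` elements and the ring width bounds lateral fronts.
#' @param settings A [numerical_settings()].
#' @return A `network_state` list with fields `element_height`, `n_elements`,
#'   `h_lw` (latewood meniscus height, m), `y` (per-element lateral penetration
#'   depths, m), `pressures` (last nodal solve, Pa), `time` (s), plus cached
#'   geometry (`S`, `W`, `ell`) and bookkeeping (`cum_inflow`, `capped`).
#' @export
build_network <- function(fluid, latewood, cross_section,
                          geometry = sample_geometry(),
                          settings = numerical_settings()) {
  assert_valid_fluid(fluid)
  assert_valid_tissue(latewood)
  assert_valid_tissue(cross_section, allow_zero_permeability = TRUE)
  assert_valid_geometry(geometry)
  n <- settings$n_elements
  structure(
    list(
      element_height = geometry$length / n,
      n_elements = n,
      h_lw = 0,
      y = rep(0, n),
      pressures = numeric(0),
      time = 0,
      S = cross_section_area(geometry),
      W = geometry$ring_width,
      ell = geometry$length,
      front_cfl = settings$front_cfl,
      cum_inflow = 0,
      capped = FALSE
    ),
    class = "network_state"
  )
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf(
    "<network_state>  t = %.4g s, h_lw = %.4g m (%d x %.4g m elements), %d lateral fronts active\n",
    x$time, x$h_lw, x$n_elements, x$element_height, sum(x$y > 0 & x$y < x$W)))
  invisible(x)
}

# activation depth for a newly wetted element's lateral front; avoids the 1/y
# singularity, same role as the closed-form startup step in 1D
Y_MIN <- 1e-6

#' Solve the nodal pressure system (Kirchhoff)
#'
#' Assembles and solves the linear flux-conservation system for the wetted
#' latewood nodes: base node at gauge pressure 0; Darcy conductance
#' `K_lw S/(mu dz)` between adjacent wetted nodes acting on
#' `(P_i - P_j - rho g dz)`; at the longitudinal front a suction boundary
#' `P = -2 sigma cos(theta)/R_lw` referenced through the last segment of
#' length `h_lw mod dz` (floored at `dz/10`); and, for each wetted element
#' with an active lateral front, a lateral sink
#' `Q_i = (K_cs/mu) (P_i + 2 sigma cos(theta)/R_cs) / y_i * (S dz / W)`.
#' Elements whose nodal pressure cannot sustain lateral suction
#' (`P_i <= -2 sigma cos(theta)/R_cs`) are deactivated for the step, so
#' lateral fronts never recede; the active set is found by fixed-point
#' iteration on the linear solve.
#'
#' @param state A `network_state` with `h_lw > 0`.
#' @param fluid,latewood,cross_section Model parameters.
#' @param gravity Gravitational acceleration (m s\eqn{^{-2}}).
#' @return A `wi_pressure_solution` list: `pressures` (wetted nodes, Pa),
#'   `front_pressure`, `front_delta`, `m` (number of wetted nodes), fluxes
#'   `q_base`, `q_front` (m\eqn{^3} s\eqn{^{-1}}), per-element `sinks` and
#'   `lateral_k` (the frozen-pressure lateral coefficient
#'   `K_cs * drive / mu`, m\eqn{^2} s\eqn{^{-1}}), and the flux-conservation
#'   `residual`.
#' @export
solve_pressures <- function(state, fluid, latewood, cross_section, gravity = 9.81) {
  h <- state$h_lw
  if (h <= 0) abort("solve_pressures requires h_lw > 0", class = "wi_precondition")
  dz <- state$element_height
  n <- state$n_elements
  S <- state$S
  W <- state$W
  mu <- fluid$viscosity
  rho <- fluid$density
  K_lw <- latewood$permeability
  K_cs <- cross_section$permeability
  if (K_lw <= 0 || S <= 0) {
    abort("all longitudinal conductances vanish", class = "wi_singular_system")
  }
  pc_lw <- capillary_pressure(fluid, latewood$equivalent_radius)
  pc_cs <- capillary_pressure(fluid, cross_section$equivalent_radius)

  capped <- state$capped || h >= state$ell * (1 - 1e-12)
  m <- if (capped) n else min(n, as.integer(floor(h / dz + 1e-9)))
  g_long <- K_lw * S / (mu * dz)
  delta <- p_front <- g_front <- NA_real_
  if (!capped) {
    delta <- max(h - m * dz, dz / 10)
    g_front <- K_lw * S / (mu * delta)
    p_front <- -pc_lw
  }

  centers <- (seq_len(n) - 0.5) * dz
  candidates <- which(state$y > 0 & state$y < W & centers < h)
  if (K_cs <= 0) candidates <- integer(0)
  c_sink <- K_cs / (mu * state$y[candidates]) * (S * dz / W)
  node_of <- pmin(candidates, max(m, 1L))

  active <- rep(TRUE, length(candidates))
  P <- numeric(0)
  repeat {
    if (m >= 1L) {
      csum <- numeric(m)
      for (j in which(active)) csum[node_of[j]] <- csum[node_of[j]] + c_sink[j]
      A <- matrix(0, m, m)
      b <- numeric(m)
      for (i in seq_len(m)) {
        g_hi <- if (i < m) g_long else if (!capped) g_front else 0
        d_hi <- if (i < m) dz else if (!capped) delta else 0
        A[i, i] <- -(g_long + g_hi + csum[i])
        if (i > 1L) A[i, i - 1L] <- g_long
        if (i < m) A[i, i + 1L] <- g_hi
        b[i] <- g_long * rho * gravity * dz - g_hi * rho * gravity * d_hi + csum[i] * pc_cs
      }
      if (!capped) b[m] <- b[m] - g_front * p_front
      P <- solve(A, b)
    }
    node_pressure <- function(i) if (i >= 1L && length(P)) P[i] else 0
    drives <- vapply(node_of, function(i) node_pressure(i) + pc_cs, numeric(1))
    newly_off <- active & drives <= 0
    if (!any(newly_off)) break
    active <- active & !newly_off
  }

  sinks <- numeric(n)
  lateral_k <- numeric(n)
  if (length(candidates)) {
    on <- which(active)
    sinks[candidates[on]] <- c_sink[on] * drives[on]
    lateral_k[candidates[on]] <- K_cs * drives[on] / mu
  }
  q_front <- if (capped) 0 else {
    p_last <- if (m >= 1L) P[m] else 0
    d_grav <- if (m >= 1L) delta else max(h, dz / 10) # m = 0: base feeds the front directly
    if (m < 1L) g_front <- K_lw * S / (mu * max(h, dz / 10))
    g_front * (p_last - p_front - rho * gravity * d_grav)
  }
  q_base <- if (m >= 1L) g_long * (0 - P[1] - rho * gravity * dz) else q_front + sum(sinks)
  flux_scale <- max(abs(q_base), abs(q_front), abs(sinks), 1e-300)
  residual <- abs(q_base - q_front - sum(sinks)) / flux_scale

  structure(
    list(pressures = P, front_pressure = p_front, front_delta = delta, m = m,
         q_base = q_base, q_front = q_front, sinks = sinks,
         lateral_k = lateral_k, residual = residual, capped = capped),
    class = "wi_pressure_solution"
  )
}

#' Advance the longitudinal and lateral fronts by one step
#'
#' The latewood meniscus advances by the longitudinal superficial flux divided
#' by the latewood porosity. Each active lateral front advances by the exact
#' frozen-pressure closed form `y_new = sqrt(y^2 + 2 K_cs drive dt /(mu eps_cs))`
#' (equivalent to flux/porosity * dt for small steps, but free of the 1/y
#' stiffness just after activation), clamped at the ring width. A step whose
#' front advance would exceed `front_cfl` times the element height (laterally,
#' times the ring width) raises a `wi_step_rejected` condition; callers halve
#' `dt` and retry. Elements newly below the meniscus activate their lateral
#' front at `y = 1e-6` m. The volume ledger (`cum_inflow`) accumulates the
#' front uptake plus the time-integrated lateral uptake and activation seeds.
#'
#' @param state A `network_state`.
#' @param solution A `wi_pressure_solution` from [solve_pressures()] (or an
#'   averaged pair of them).
#' @param latewood,cross_section Tissues supplying the porosities.
#' @param dt Time step (s), > 0.
#' @return The advanced `network_state`.
#' @export
advance_fronts <- function(state, solution, latewood, cross_section, dt) {
  assert_scalar_number(dt, "dt")
  if (dt <= 0) abort_invalid("dt: must be > 0")
  S <- state$S
  dz <- state$element_height
  W <- state$W
  eps_lw <- latewood$porosity
  eps_cs <- cross_section$porosity

  dh <- if (state$capped) 0 else solution$q_front / (S * eps_lw) * dt
  if (dh > state$front_cfl * dz * (1 + 1e-9)) {
    abort("longitudinal front would cross more than front_cfl * dz",
          class = "wi_step_rejected")
  }

  y_old <- state$y
  act <- which(y_old > 0 & y_old < W & solution$lateral_k > 0)
  y_new <- y_old
  if (length(act)) {
    y_new[act] <- sqrt(y_old[act]^2 + 2 * solution$lateral_k[act] * dt / eps_cs)
    if (any(y_new[act] - y_old[act] > state$front_cfl * W * (1 + 1e-9))) {
      abort("a lateral front would cross more than front_cfl * W",
            class = "wi_step_rejected")
    }
    y_new[act] <- pmin(y_new[act], W)
  }
  dV <- solution$q_front * dt * (!state$capped) +
    sum(S * dz * eps_cs / W * (y_new - y_old))

  h_new <- state$h_lw + dh
  capped <- state$capped
  if (!capped && h_new >= state$ell * (1 - 1e-12)) {
    dV <- dV - S * eps_lw * max(0, h_new - state$ell) # overshoot is not stored
    h_new <- min(h_new, state$ell)
    capped <- TRUE
  }

  if (cross_section$permeability > 0) {
    centers <- (seq_len(state$n_elements) - 0.5) * dz
    newly <- which(y_new == 0 & centers < h_new)
    if (length(newly)) {
      y_new[newly] <- Y_MIN
      dV <- dV + length(newly) * S * dz * eps_cs * Y_MIN / W
    }
  }

  state$h_lw <- h_new
  state$y <- y_new
  state$pressures <- solution$pressures
  state$time <- state$time + dt
  state$cum_inflow <- state$cum_inflow + dV
  state$capped <- capped
  state
}

stored_volume <- function(state, latewood, cross_section) {
  state$S * (latewood$porosity * state$h_lw +
               cross_section$porosity / state$W * sum(state$y) * state$element_height)
}

equivalent_height_2d <- function(state, latewood, cross_section) {
  latewood$porosity * state$h_lw +
    cross_section$porosity / state$W * sum(state$y) * state$element_height
}

average_solutions <- function(s0, s1) {
  s0$q_front <- (s0$q_front + s1$q_front) / 2
  s0$sinks <- (s0$sinks + s1$sinks) / 2
  s0$lateral_k <- (s0$lateral_k + s1$lateral_k) / 2
  s0
}

#' Run the dual-scale 2D imbibition model
#'
#' Time-loops [solve_pressures()] and [advance_fronts()] with a two-stage
#' (Heun) front update and adaptive steps limited by `dt_max` and the CFL
#' fractions. The run starts from the gravity-free closed form up to half an
#' element height (removing the 1/h singularity), and ends at `t_end`, at full
#' saturation, or — with `stop_at_cap = TRUE` — as soon as the latewood front
#' reaches the sample length. The recorded equivalent height generalises the
#' 1D conversion: `h_eq = eps_lw h_lw + (eps_cs/W) sum(y_i) dz`.
#'
#' @inheritParams build_network
#' @param t_end End time (s), > 0.
#' @param snapshot_times Optional increasing times (s) at which to capture
#'   moisture-field snapshots.
#' @param stop_at_cap Stop as soon as the latewood front reaches the top.
#' @param n_lateral Number of lateral bins in moisture-field snapshots.
#' @return A `washburn2d_result` list: `curve` (tibble `time_s`, `h_lw_m`,
#'   `h_eq_m`, `capped`), `fields` (list of moisture-field tibbles),
#'   `conservation` (tibble `time_s`, `stored_m3`, `inflow_m3`), and the final
#'   `state`.
#' @export
#' @examples
#' \donttest{
#' fl <- builtin_fluids()$water
#' ts <- builtin_tissues()
#' res <- run_2d(fl, ts$latewood, ts$cross_section, t_end = 3600)
#' glance(res)
#' }
run_2d <- function(fluid, latewood, cross_section, geometry = sample_geometry(),
                   settings = numerical_settings(), t_end,
                   snapshot_times = NULL, stop_at_cap = FALSE, n_lateral = 40L) {
  assert_scalar_number(t_end, "t_end")
  if (t_end <= 0) abort_invalid("t_end: must be > 0")
  state <- build_network(fluid, latewood, cross_section, geometry, settings)
  g <- settings$gravity
  dz <- state$element_height
  S <- state$S
  eps_lw <- latewood$porosity

  # closed-form gravity-free startup to half an element height
  pc_lw <- capillary_pressure(fluid, latewood$equivalent_radius)
  a_early <- 2 * pc_lw * latewood$permeability / (fluid$viscosity * eps_lw)
  h0 <- min(dz / 2, sqrt(a_early * t_end))
  state$h_lw <- h0
  state$time <- h0^2 / a_early
  state$cum_inflow <- S * eps_lw * h0

  dt_max <- settings$dt_max %||% (t_end / 2000)
  snaps <- sort(snapshot_times)
  fields <- list()

  nbuf <- 4096L
  rec_t <- numeric(nbuf); rec_h <- numeric(nbuf); rec_heq <- numeric(nbuf)
  rec_sto <- numeric(nbuf); rec_in <- numeric(nbuf)
  nrec <- 0L
  record <- function(st) {
    nrec <<- nrec + 1L
    if (nrec > nbuf) {
      nbuf <<- nbuf * 2L
      length(rec_t) <<- nbuf; length(rec_h) <<- nbuf; length(rec_heq) <<- nbuf
      length(rec_sto) <<- nbuf; length(rec_in) <<- nbuf
    }
    rec_t[nrec] <<- st$time
    rec_h[nrec] <<- st$h_lw
    rec_heq[nrec] <<- equivalent_height_2d(st, latewood, cross_section)
    rec_sto[nrec] <<- stored_volume(st, latewood, cross_section)
    rec_in[nrec] <<- st$cum_inflow
  }
  record(state)

  while (state$time < t_end) {
    if (stop_at_cap && state$capped) break
    lateral_active <- any(state$y > 0 & state$y < state$W) &&
      cross_section$permeability > 0
    if (state$capped && !lateral_active) break

    sol0 <- solve_pressures(state, fluid, latewood, cross_section, g)

    v_h <- if (state$capped) 0 else sol0$q_front / (S * eps_lw)
    dt <- min(dt_max, t_end - state$time)
    if (v_h > 0) {
      # allow a slight overshoot of the cap so the crossing completes in one step
      dt <- min(dt, 0.95 * state$front_cfl * dz / v_h,
                1.05 * (state$ell - state$h_lw) / v_h)
    }
    act <- which(state$y > 0 & state$y < state$W & sol0$lateral_k > 0)
    if (length(act)) {
      ymax <- state$y[act] + state$front_cfl * state$W
      dt_lat <- (ymax^2 - state$y[act]^2) * cross_section$porosity /
        (2 * sol0$lateral_k[act])
      dt <- min(dt, 0.95 * min(dt_lat))
    }
    if (length(snaps)) {
      dt <- min(dt, max(snaps[1] - state$time, dt * 1e-6))
    }

    for (try in 1:40) {
      new_state <- tryCatch({
        s1 <- advance_fronts(state, sol0, latewood, cross_section, dt)
        sol1 <- if (s1$h_lw > 0) solve_pressures(s1, fluid, latewood, cross_section, g) else sol0
        advance_fronts(state, average_solutions(sol0, sol1), latewood, cross_section, dt)
      }, wi_step_rejected = function(e) NULL)
      if (!is.null(new_state)) break
      dt <- dt / 2
    }
    if (is.null(new_state)) {
      abort("time step repeatedly rejected; fronts cannot advance stably",
            class = "wi_step_rejected")
    }
    state <- new_state
    record(state)

    while (length(snaps) && state$time >= snaps[1] * (1 - 1e-12)) {
      fields[[length(fields) + 1L]] <- moisture_field(state, n_lateral)
      snaps <- snaps[-1]
    }
  }

  idx <- seq_len(nrec)
  curve <- tibble::new_tibble(
    list(time_s = rec_t[idx], h_lw_m = rec_h[idx], h_eq_m = rec_heq[idx],
         capped = rec_h[idx] >= state$ell * (1 - 1e-12)),
    class = "washburn2d_curve")
  conservation <- tibble::tibble(time_s = rec_t[idx], stored_m3 = rec_sto[idx],
                                 inflow_m3 = rec_in[idx])
  structure(
    list(curve = curve, fields = fields, conservation = conservation,
         state = state, latewood = latewood, cross_section = cross_section,
         fluid = fluid, t_end = t_end),
    class = "washburn2d_result"
  )
}

#' Moisture-field snapshot
#'
#' Sharp-front saturation field over the earlywood part of one growth ring:
#' rows are height elements (bottom to top), columns lateral bins across the
#' ring width; saturation is 1 behind the lateral front `y_i`, 0 ahead.
#'
#' @param state A `network_state`.
#' @param n_lateral Number of lateral bins.
#' @return Tibble with columns `height_index`, `z_m`, `lateral_index`, `x_m`,
#'   `saturation` and attributes `time` and `h_lw`.
#' @export
moisture_field <- function(state, n_lateral = 40L) {
  n <- state$n_elements
  dz <- state$element_height
  xb <- (seq_len(n_lateral) - 0.5) * state$W / n_lateral
  grid <- tidyr::expand_grid(height_index = seq_len(n), lateral_index = seq_len(n_lateral))
  grid$z_m <- (grid$height_index - 0.5) * dz
  grid$x_m <- xb[grid$lateral_index]
  grid$saturation <- as.numeric(grid$x_m <= state$y[grid$height_index])
  out <- tibble::new_tibble(grid[c("height_index", "z_m", "lateral_index", "x_m",
                                   "saturation")], class = "wi_moisture_field")
  attr(out, "time") <- state$time
  attr(out, "h_lw") <- state$h_lw
  out
}

#' Write moisture-field snapshots as delimited-text grids
#'
#' One CSV per snapshot, named `field_t<seconds>.csv`: rows are height elements
#' bottom to top, columns lateral bins (no header).
#'
#' @param result A `washburn2d_result` with snapshots.
#' @param dir Output directory (created if needed).
#' @return Written paths, invisibly.
#' @export
write_moisture_fields <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::map_chr(result$fields, function(f) {
    wide <- tidyr::pivot_wider(f[c("height_index", "lateral_index", "saturation")],
                               names_from = "lateral_index", values_from = "saturation")
    mat <- as.matrix(wide[order(wide$height_index), -1, drop = FALSE])
    path <- file.path(dir, sprintf("field_t%d.csv", round(attr(f, "time"))))
    write.table(mat, path, sep = ",", row.names = FALSE, col.names = FALSE)
    path
  })
  invisible(paths)
}

#' @export
print.washburn2d_result <- function(x, ...) {
  st <- x$state
  cat(sprintf(
    "<washburn2d_result>  t = %.4g s, h_lw = %.4g m%s, h_eq = %.4g m, %d snapshots\n",
    st$time, st$h_lw, if (st$capped) " (capped)" else "",
    equivalent_height_2d(st, x$latewood, x$cross_section), length(x$fields)))
  invisible(x)
}
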