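# Porous-medium Washburn model in 1D. The meniscus height h in the conducting
# pathway obeys
#   eps_g * dh/dt = (2 sigma cos(theta)/R_eq - rho g h) * K / (mu h)
# whose implicit closed form is
#   t = -(mu eps_g / (rho g K)) * (h + h_max log(1 - h/h_max)),
#   h_max = 2 sigma cos(theta) / (rho g R_eq).
# The equivalent height seen by a gravimetric experiment is h_eq = eps_g * h.

#' Maximum capillary rise height
#'
#' Equilibrium rise height \eqn{h_{max} = 2\sigma\cos\theta/(\rho g R_{eq})}
#' where capillary pressure balances the hydrostatic head.
#'
#' @param fluid A [fluid()] object.
#' @param tissue A [tissue()] object (its equivalent pore radius is used).
#' @param gravity Gravitational acceleration (m s\eqn{^{-2}}).
#' @return Height (m).
#' @export
#' @examples
#' max_height(builtin_fluids()$silicone_oil, builtin_tissues()$vessels)
max_height <- function(fluid, tissue, gravity = 9.81) {
  assert_valid_fluid(fluid)
  assert_valid_tissue(tissue, allow_zero_permeability = TRUE)
  if (gravity <= 0) abort_invalid("gravity: must be > 0 for a finite rise height")
  capillary_pressure(fluid, tissue$equivalent_radius) / (fluid$density * gravity)
}

#' Tube-bundle permeability
#'
#' Permeability of a perfect bundle of straight parallel tubes,
#' \eqn{K = (\varepsilon_g/\tau)\,R_{eq}^2/8}. Used as a theoretical anchor for
#' the tissue presets.
#'
#' @param porosity Active porosity (fraction of the sample cross-section).
#' @param equivalent_radius Tube radius (m).
#' @param tortuosity Tortuosity (1 for straight tubes).
#' @return Permeability (m\eqn{^2}).
#' @export
#' @examples
#' tube_bundle_permeability(0.15, 40e-6) # poplar vessels as straight tubes
tube_bundle_permeability <- function(porosity, equivalent_radius, tortuosity = 1) {
  assert_scalar_number(porosity, "porosity")
  assert_scalar_number(equivalent_radius, "equivalent_radius")
  assert_scalar_number(tortuosity, "tortuosity")
  if (porosity <= 0 || equivalent_radius <= 0) {
    abort_invalid("porosity and equivalent_radius must be > 0")
  }
  if (tortuosity < 1) abort_invalid("tortuosity: must be >= 1")
  (porosity / tortuosity) * equivalent_radius^2 / 8
}

#' Time to reach a given meniscus height (closed form)
#'
#' Evaluates the implicit Washburn solution
#' \eqn{t(h) = -\frac{\mu\varepsilon_g}{\rho g K}\left(h + h_{max}\log(1 - h/h_{max})\right)}.
#' Diverges as \eqn{h \to h_{max}}.
#'
#' @inheritParams max_height
#' @param height Meniscus height(s) (m), each in `[0, h_max)`.
#' @return Time(s) (s), same length as `height`.
#' @export
analytic_time <- function(height, fluid, tissue, gravity = 9.81) {
  assert_valid_fluid(fluid)
  assert_valid_tissue(tissue)
  if (gravity <= 0) abort_invalid("gravity: must be > 0 (use the gravity-free closed form otherwise)")
  hmax <- max_height(fluid, tissue, gravity)
  if (any(height < 0) || any(height >= hmax)) {
    abort(sprintf("height must lie in [0, h_max = %g m)", hmax), class = "wi_domain_error")
  }
  pref <- fluid$viscosity * tissue$porosity / (fluid$density * gravity * tissue$permeability)
  -pref * (height + hmax * log1p(-height / hmax))
}

# upper end of the admissible height range for root finding / interpolation
height_cap <- function(fluid, tissue, geometry, gravity) {
  hmax <- max_height(fluid, tissue, gravity)
  min(geometry$length, hmax * (1 - 1e-12))
}

#' Meniscus height at a given time (inverse of the closed form)
#'
#' Inverts [analytic_time()] by bracketed root finding, capping the result at
#' the sample length (the stop-at-sample-length rule).
#'
#' @inheritParams max_height
#' @param time Time(s) (s), each \eqn{\ge 0}.
#' @param geometry A [sample_geometry()]; supplies the length cap.
#' @return Height(s) (m).
#' @export
height_at_time <- function(time, fluid, tissue, geometry = sample_geometry(),
                           gravity = 9.81) {
  if (any(time < 0)) abort("time must be >= 0", class = "wi_domain_error")
  assert_valid_geometry(geometry)
  upper <- height_cap(fluid, tissue, geometry, gravity)
  t_cap <- analytic_time(upper, fluid, tissue, gravity)
  hmax <- max_height(fluid, tissue, gravity)
  vapply(time, function(tt) {
    if (tt <= 0) return(0)
    if (tt >= t_cap) return(upper)
    stats::uniroot(
      function(h) analytic_time(h, fluid, tissue, gravity) - tt,
      interval = c(0, upper), tol = hmax * 1e-11
    )$root
  }, numeric(1))
}

# Vectorised analytic h_eq(t) through monotone interpolation of the closed form,
# used by the fitting and synthetic-data stages (uniform h grid = uniform in
# sqrt(t) early on, where the curve is steepest).
analytic_heq_at <- function(time, fluid, tissue, geometry = sample_geometry(),
                            gravity = 9.81, n_grid = 2000L) {
  upper <- height_cap(fluid, tissue, geometry, gravity)
  hg <- seq(0, upper, length.out = n_grid)
  tg <- analytic_time(hg, fluid, tissue, gravity)
  h <- approx(tg, hg, xout = pmin(time, max(tg)), rule = 2, ties = "ordered")$y
  tissue$porosity * h
}

new_imbibition_curve <- function(df, fluid, tissue, geometry, gravity) {
  out <- tibble::new_tibble(df, class = "imbibition_curve")
  attr(out, "fluid") <- fluid
  attr(out, "tissue") <- tissue
  attr(out, "geometry") <- geometry
  attr(out, "gravity") <- gravity
  out
}

#' Numerically integrate the 1D Washburn model
#'
#' Explicit two-stage second-order (Heun) integration of the porous-medium
#' Washburn ODE with gravity. The singular start (`dh/dt -> Inf` at `h = 0`) is
#' handled by taking the first point from the gravity-free closed form
#' \eqn{h(t)^2 = \frac{4\sigma\cos\theta K}{R_{eq}\varepsilon_g\mu} t}; steps
#' then ramp up geometrically to `dt_max` so the early square-root regime is
#' resolved. Integration stops at `t_end` or when the front reaches the sample
#' length, whichever comes first (the cap time is located by interpolation and
#' flagged).
#'
#' @inheritParams height_at_time
#' @param settings A [numerical_settings()]. `dt_max = NULL` defaults to
#'   `t_end / 1e5`; each step is additionally capped so the front advances at
#'   most `length/1000`.
#' @param t_end End time (s).
#' @param n_out Approximate number of rows to keep in the output curve.
#' @return An `imbibition_curve` tibble with columns `time_s`, `height_m`,
#'   `h_eq_m`, `capped`.
#' @seealso [analytic_time()], [to_equivalent_height()]
#' @export
#' @examples
#' w <- builtin_fluids()$water
#' lw <- builtin_tissues()$latewood
#' curve <- integrate_1d(w, lw, t_end = 600)
#' tail(curve, 3)
integrate_1d <- function(fluid, tissue, geometry = sample_geometry(),
                         settings = numerical_settings(), t_end, n_out = 500L) {
  assert_valid_fluid(fluid)
  assert_valid_tissue(tissue)
  assert_valid_geometry(geometry)
  assert_scalar_number(t_end, "t_end")
  if (t_end < 0) abort_invalid("t_end: must be >= 0")
  g <- settings$gravity
  ell <- geometry$length
  eps <- tissue$porosity

  if (t_end == 0) {
    return(new_imbibition_curve(
      list(time_s = 0, height_m = 0, h_eq_m = 0, capped = FALSE),
      fluid, tissue, geometry, g))
  }

  pc <- capillary_pressure(fluid, tissue$equivalent_radius)
  c1 <- pc * tissue$permeability / (fluid$viscosity * eps)          # m^2/s
  c2 <- fluid$density * g * tissue$permeability / (fluid$viscosity * eps) # m/s
  a_early <- 2 * c1                                                 # h^2 = a_early * t
  hmax <- if (g > 0) pc / (fluid$density * g) else Inf
  f <- function(h) (c1 - c2 * h) / h

  dt_max <- settings$dt_max %||% (t_end / 1e5)
  dh_cap <- ell / 1000

  # startup: gravity-free closed form at a small fraction of dt_max
  t <- min(dt_max / 100, t_end)
  h <- sqrt(a_early * t)
  capped <- FALSE
  if (h >= ell) { # degenerate: cap crossed within the startup step
    t <- ell^2 / a_early
    h <- ell
    capped <- TRUE
  }

  nbuf <- 4096L
  tv <- numeric(nbuf); hv <- numeric(nbuf)
  tv[1] <- t; hv[1] <- h
  n <- 1L

  while (!capped && t < t_end) {
    dt <- min(dt_max, 0.005 * t, t_end - t)
    v <- f(h)
    if (v <= 0) break # at equilibrium (h -> h_max)
    dt <- min(dt, dh_cap / v)
    h_pred <- h + dt * v
    if (h_pred >= hmax) h_pred <- (h + hmax) / 2
    h_new <- h + dt * (v + f(h_pred)) / 2
    if (h_new >= hmax) h_new <- (h + hmax) / 2
    if (h_new >= ell) {
      t <- t + dt * (ell - h) / (h_new - h)
      h <- ell
      capped <- TRUE
    } else {
      t <- t + dt
      h <- h_new
    }
    n <- n + 1L
    if (n > nbuf) {
      nbuf <- nbuf * 2L
      length(tv) <- nbuf; length(hv) <- nbuf
    }
    tv[n] <- t; hv[n] <- h
  }

  keep <- unique(c(1L, seq(1L, n, length.out = min(n, n_out)), n))
  keep <- sort(as.integer(round(keep)))
  times <- c(0, tv[keep]); heights <- c(0, hv[keep])
  new_imbibition_curve(
    list(time_s = times, height_m = heights, h_eq_m = eps * heights,
         capped = capped & times >= tv[n]),
    fluid, tissue, geometry, g)
}

#' Convert a curve to equivalent height
#'
#' Recomputes the equivalent height column \eqn{h_{eq} = \varepsilon_g h}
#' elementwise for an imbibition curve, using the supplied tissue's active
#' porosity. Times are untouched.
#'
#' @param curve An `imbibition_curve` tibble from [integrate_1d()].
#' @param tissue A [tissue()] whose porosity converts true to equivalent height.
#' @return The curve with `h_eq_m` replaced.
#' @export
to_equivalent_height <- function(curve, tissue) {
  assert_valid_tissue(tissue, allow_zero_permeability = TRUE)
  if (!all(c("time_s", "height_m") %in% names(curve))) {
    abort_invalid("curve: expected columns time_s and height_m")
  }
  if (any(!is.finite(curve$height_m))) abort_invalid("curve: heights must be finite")
  dplyr::mutate(curve, h_eq_m = tissue$porosity * .data$height_m)
}

#' Write an imbibition curve as delimited text
#'
#' Columns `time_s`, `height_m`, `h_eq_m` with a header row and `.` decimal
#' separator.
#'
#' @param curve An `imbibition_curve`.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_imbibition_curve <- function(curve, path) {
  readr::write_csv(dplyr::select(tibble::as_tibble(curve),
                                 "time_s", "height_m", "h_eq_m"), path)
  invisible(path)
}
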