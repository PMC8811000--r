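#' Fluid properties
#'
#' Construct a fluid parameter set for Washburn-type imbibition models. All
#' quantities are SI except the contact angle, which is in degrees. The
#' constructor only checks types; use [validate_setup()] to obtain physical
#' violations (a wetting fluid requires `0 <= contact_angle < 90`).
#'
#' @param name Label for the fluid.
#' @param density Mass density \eqn{\rho} (kg m\eqn{^{-3}}).
#' @param viscosity Dynamic viscosity \eqn{\mu} (Pa s).
#' @param surface_tension Surface tension \eqn{\sigma} (N m\eqn{^{-1}}).
#' @param contact_angle Contact angle \eqn{\theta} (degrees).
#' @return An object of class `wi_fluid`.
#' @seealso [builtin_fluids()], [validate_setup()]
#' @export
#' @examples
#' fluid("water", 997, 0.001, 0.073, 50)
fluid <- function(name, density, viscosity, surface_tension, contact_angle) {
  if (!is.character(name) || length(name) != 1L) abort_invalid("name: must be a single string")
  assert_scalar_number(density, "density")
  assert_scalar_number(viscosity, "viscosity")
  assert_scalar_number(surface_tension, "surface_tension")
  assert_scalar_number(contact_angle, "contact_angle")
  structure(
    list(name = name, density = density, viscosity = viscosity,
         surface_tension = surface_tension, contact_angle = contact_angle),
    class = "wi_fluid"
  )
}

#' Tissue properties
#'
#' Construct a wood-tissue parameter set. Permeability and porosity are
#' effective values referred to the whole sample cross-section, so the 1D and
#' 2D models share one parameter meaning: fluxes use the full section and
#' front speeds divide by the porosity.
#'
#' @param name Label for the tissue.
#' @param permeability Superficial (Darcy) permeability \eqn{K} (m\eqn{^2}).
#' @param porosity Active porosity \eqn{\varepsilon_g}, fraction of the total
#'   sample cross-section occupied by the conducting pathway (dimensionless).
#' @param equivalent_radius Equivalent pore radius \eqn{R_{eq}} (m).
#' @param tortuosity Tortuosity \eqn{\tau} (dimensionless, 1 for straight tubes).
#' @return An object of class `wi_tissue`.
#' @seealso [builtin_tissues()], [tube_bundle_permeability()]
#' @export
tissue <- function(name, permeability, porosity, equivalent_radius, tortuosity = 1) {
  if (!is.character(name) || length(name) != 1L) abort_invalid("name: must be a single string")
  assert_scalar_number(permeability, "permeability")
  assert_scalar_number(porosity, "porosity")
  assert_scalar_number(equivalent_radius, "equivalent_radius")
  assert_scalar_number(tortuosity, "tortuosity")
  structure(
    list(name = name, permeability = permeability, porosity = porosity,
         equivalent_radius = equivalent_radius, tortuosity = tortuosity),
    class = "wi_tissue"
  )
}

#' Sample geometry
#'
#' Geometry of the prismatic wood sample used in gravimetric imbibition tests:
#' 100 mm longitudinal, 40 mm radial and 20 mm tangential by default, with a
#' 4 mm growth-ring width for the dual-scale model. The sample mouth sits
#' `immersion_depth` below the liquid level; the models ignore the associated
#' hydrostatic offset, it is kept for bookkeeping.
#'
#' @param length Longitudinal extent \eqn{\ell} (m).
#' @param width_radial Radial width (m).
#' @param width_tangential Tangential width (m).
#' @param ring_width Growth-ring width \eqn{W} available for lateral spreading (m).
#' @param immersion_depth Depth of the sample mouth below the liquid level (m).
#' @return An object of class `wi_geometry`.
#' @export
sample_geometry <- function(length = 0.1, width_radial = 0.04,
                            width_tangential = 0.02, ring_width = 0.004,
                            immersion_depth = 0.005) {
  assert_scalar_number(length, "length")
  assert_scalar_number(width_radial, "width_radial")
  assert_scalar_number(width_tangential, "width_tangential")
  assert_scalar_number(ring_width, "ring_width")
  assert_scalar_number(immersion_depth, "immersion_depth")
  structure(
    list(length = length, width_radial = width_radial,
         width_tangential = width_tangential, ring_width = ring_width,
         immersion_depth = immersion_depth),
    class = "wi_geometry"
  )
}

#' Sample cross-section area
#'
#' @param geometry A [sample_geometry()] object.
#' @return Cross-section \eqn{S} = radial width \eqn{\times} tangential width (m\eqn{^2}).
#' @export
cross_section_area <- function(geometry) {
  geometry$width_radial * geometry$width_tangential
}

#' Numerical settings
#'
#' Controls shared by the numerical solvers. `n_elements` is the longitudinal
#' discretisation of the 2D network (100 elements of 1 mm by default);
#' `front_cfl` caps the front advance per step as a fraction of an element
#' height (laterally, of the ring width). `dt_max = NULL` lets each solver pick
#' its documented default from the requested end time.
#'
#' @param gravity Gravitational acceleration (m s\eqn{^{-2}}). Zero is allowed
#'   for gravity-free limits.
#' @param dt_max Time-step cap (s), or `NULL` for the solver default.
#' @param n_elements Number of longitudinal elements (\eqn{\ge 2}).
#' @param front_cfl Maximum front advance per step, as a fraction in (0, 1].
#' @param seed Optional integer seed for stochastic modules.
#' @return An object of class `wi_settings`.
#' @export
numerical_settings <- function(gravity = 9.81, dt_max = NULL, n_elements = 100L,
                               front_cfl = 0.5, seed = NULL) {
  assert_scalar_number(gravity, "gravity")
  if (gravity < 0) abort_invalid("gravity: must be >= 0")
  if (!is.null(dt_max)) {
    assert_scalar_number(dt_max, "dt_max")
    if (dt_max <= 0) abort_invalid("dt_max: must be > 0")
  }
  assert_scalar_number(n_elements, "n_elements")
  if (n_elements < 2 || n_elements != round(n_elements)) {
    abort_invalid("n_elements: must be an integer >= 2")
  }
  assert_scalar_number(front_cfl, "front_cfl")
  if (front_cfl <= 0 || front_cfl > 1) abort_invalid("front_cfl: must be in (0, 1]")
  if (!is.null(seed)) assert_scalar_number(seed, "seed")
  structure(
    list(gravity = gravity, dt_max = dt_max, n_elements = as.integer(n_elements),
         front_cfl = front_cfl, seed = seed),
    class = "wi_settings"
  )
}

#' Built-in fluid presets
#'
#' The two working fluids of the imbibition experiments: deionised water and a
#' non-polar silicone oil, with a single representative contact angle per fluid
#' (50 degrees for water, 18 for oil, as measured along the grain on solid wood).
#'
#' @return Named list with elements `"water"` and `"silicone_oil"`.
#' @export
#' @examples
#' builtin_fluids()$water
builtin_fluids <- function() {
  list(
    water        = fluid("water", 997, 0.001, 0.073, 50),
    silicone_oil = fluid("silicone_oil", 1010, 0.02, 0.021, 18)
  )
}

#' Built-in tissue presets
#'
#' Effective parameter sets for the conducting tissues: poplar vessels, spruce
#' latewood tracheids, a generic fibre tissue, and the "cross-section" tissue
#' describing slow lateral invasion of earlywood through rays and connected
#' tracheids. Porosities are fractions of the total sample cross-section; all
#' presets use tortuosity 1.
#'
#' @return Named list with elements `"vessels"`, `"latewood"`, `"fibers"`,
#'   `"cross_section"`.
#' @export
builtin_tissues <- function() {
  list(
    vessels       = tissue("vessels", 5e-12, 0.15, 40e-6),
    latewood      = tissue("latewood", 1e-15, 0.01, 10e-6),
    fibers        = tissue("fibers", 1e-14, 0.2, 10e-6),
    cross_section = tissue("cross_section", 1e-18, 0.5, 20e-6)
  )
}

fluid_violations <- function(f) {
  v <- character()
  if (f$density <= 0) v <- c(v, "density: must be > 0")
  if (f$viscosity <= 0) v <- c(v, "viscosity: must be > 0")
  if (f$surface_tension <= 0) v <- c(v, "surface_tension: must be > 0")
  if (f$contact_angle < 0 || f$contact_angle >= 90) {
    v <- c(v, "contact_angle: must be in [0, 90) degrees for a wetting fluid")
  }
  v
}

tissue_violations <- function(tis) {
  v <- character()
  if (tis$permeability < 0) v <- c(v, "permeability: must be >= 0")
  if (tis$porosity <= 0 || tis$porosity > 1) v <- c(v, "porosity: must be in (0, 1]")
  if (tis$equivalent_radius <= 0) v <- c(v, "equivalent_radius: must be > 0")
  if (tis$tortuosity < 1) v <- c(v, "tortuosity: must be >= 1")
  v
}

geometry_violations <- function(g) {
  v <- character()
  for (f in c("length", "width_radial", "width_tangential", "ring_width")) {
    if (g[[f]] <= 0) v <- c(v, sprintf("%s: must be > 0", f))
  }
  if (g$immersion_depth < 0) v <- c(v, "immersion_depth: must be >= 0")
  v
}

#' Validate a model setup
#'
#' Checks every type invariant of a fluid/tissue/geometry triple and returns
#' the violations as messages rather than raising them, so a configuration can
#' be audited in one pass. Solvers raise `wi_invalid_parameter` errors built
#' from the same checks.
#'
#' @param fluid A [fluid()] object.
#' @param tissue A [tissue()] object.
#' @param geometry A [sample_geometry()] object.
#' @return Character vector of violation messages; empty if all invariants hold.
#' @export
#' @examples
#' validate_setup(builtin_fluids()$water, builtin_tissues()$vessels, sample_geometry())
validate_setup <- function(fluid, tissue, geometry = sample_geometry()) {
  c(fluid_violations(fluid), tissue_violations(tissue), geometry_violations(geometry))
}

assert_valid_fluid <- function(f) {
  v <- fluid_violations(f)
  if (length(v)) abort_invalid(paste(c("invalid fluid:", v), collapse = "\n  "))
  invisible(f)
}

assert_valid_tissue <- function(tis, allow_zero_permeability = FALSE) {
  v <- tissue_violations(tis)
  if (!allow_zero_permeability && tis$permeability <= 0) {
    v <- c(v, "permeability: must be > 0 for a conducting pathway")
  }
  if (length(v)) abort_invalid(paste(c("invalid tissue:", v), collapse = "\n  "))
  invisible(tis)
}

assert_valid_geometry <- function(g) {
  v <- geometry_violations(g)
  if (length(v)) abort_invalid(paste(c("invalid geometry:", v), collapse = "\n  "))
  invisible(g)
}

#' @export
print.wi_fluid <- function(x, ...) {
  cat(sprintf("<fluid: %s>  rho = %g kg/m^3, mu = %g Pa s, sigma = %g N/m, theta = %g deg\n",
              x$name, x$density, x$viscosity, x$surface_tension, x$contact_angle))
  invisible(x)
}

#' @export
print.wi_tissue <- function(x, ...) {
  cat(sprintf("<tissue: %s>  K = %g m^2, eps = %g, R_eq = %g m, tau = %g\n",
              x$name, x$permeability, x$porosity, x$equivalent_radius, x$tortuosity))
  invisible(x)
}

#' @export
print.wi_geometry <- function(x, ...) {
  cat(sprintf("<geometry>  L = %g m, R x T = %g x %g m (S = %g m^2), ring W = %g m\n",
              x$length, x$width_radial, x$width_tangential,
              cross_section_area(x), x$ring_width))
  invisible(x)
}
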