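# Internal helpers shared across modules. Condition classes are stable API:
# tests and callers dispatch on them.

abort_invalid <- function(msg) abort(msg, class = "wi_invalid_parameter")

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_invalid(sprintf("%s: must be a single finite number", name))
  }
  invisible(x)
}

# contact angles are carried in degrees everywhere user-facing; radians only here
cos_contact <- function(contact_angle) cos(contact_angle * pi / 180)

# capillary pressure jump 2*sigma*cos(theta)/R for a cylindrical pore [Pa]
capillary_pressure <- function(fluid, radius) {
  2 * fluid$surface_tension * cos_contact(fluid$contact_angle) / radius
}

compact_null <- function(x) x[!vapply(x, is.null, logical(1))]
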