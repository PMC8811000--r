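# Run configuration files: one YAML document per run with sections fluid,
# tissue, (optional) cross_section, geometry, numerics. Each of fluid / tissue /
# cross_section is either a preset name or a mapping of explicit SI fields.

config_entry <- function(x) {
  if (is.character(x)) x else compact_null(unclass(x))
}

#' Write a run configuration
#'
#' Serialises a model setup to a YAML config with sections `fluid`, `tissue`,
#' optionally `cross_section`, `geometry` and `numerics`. Fluid/tissue sections
#' may be preset names (strings) or full objects; units are SI throughout
#' (contact angle in degrees), as noted in the file header.
#'
#' @param path File to write.
#' @param fluid A [fluid()] object or a preset name from [builtin_fluids()].
#' @param tissue A [tissue()] object or a preset name from [builtin_tissues()].
#' @param cross_section Optional second tissue for the dual-scale model.
#' @param geometry Optional [sample_geometry()].
#' @param numerics Optional [numerical_settings()].
#' @return `path`, invisibly.
#' @seealso [read_imbibition_config()]
#' @export
write_imbibition_config <- function(path, fluid, tissue, cross_section = NULL,
                                    geometry = NULL, numerics = NULL) {
  doc <- compact_null(list(
    fluid = config_entry(fluid),
    tissue = config_entry(tissue),
    cross_section = if (!is.null(cross_section)) config_entry(cross_section),
    geometry = if (!is.null(geometry)) config_entry(geometry),
    numerics = if (!is.null(numerics)) config_entry(numerics)
  ))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# woodimbibe run configuration.",
    "# Units: SI (m, kg, s, Pa, N/m); contact_angle in degrees."
  ), con)
  yaml::write_yaml(doc, con, precision = 15L)
  invisible(path)
}

resolve_config_section <- function(x, presets, builder, section) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) {
    if (!x %in% names(presets)) {
      abort_invalid(sprintf("%s: unknown preset '%s' (available: %s)",
                            section, x, paste(names(presets), collapse = ", ")))
    }
    return(presets[[x]])
  }
  if (!is.list(x)) abort_invalid(sprintf("%s: must be a preset name or a mapping", section))
  do.call(builder, x)
}

#' Read a run configuration
#'
#' @param path YAML config written by [write_imbibition_config()] or by hand.
#' @return List with elements `fluid`, `tissue`, `cross_section` (may be
#'   `NULL`), `geometry` and `numerics` (defaults filled in where absent).
#' @export
read_imbibition_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$fluid) || is.null(doc$tissue)) {
    abort_invalid("config: sections 'fluid' and 'tissue' are required")
  }
  list(
    fluid = resolve_config_section(doc$fluid, builtin_fluids(), fluid, "fluid"),
    tissue = resolve_config_section(doc$tissue, builtin_tissues(), tissue, "tissue"),
    cross_section = resolve_config_section(doc$cross_section, builtin_tissues(),
                                           tissue, "cross_section"),
    geometry = if (is.null(doc$geometry)) sample_geometry() else do.call(sample_geometry, doc$geometry),
    numerics = if (is.null(doc$numerics)) numerical_settings() else do.call(numerical_settings, doc$numerics)
  )
}
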