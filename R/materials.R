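#' Load a material from the packaged registry
#'
#' Returns the element weight fractions and mass density of one of the
#' transport media: pure water at 0.998 g/cm^3 (the phantom medium), dry air
#' (0% humidity, N 75.5% / O 23.2% / Ar 1.3% by weight, 0.00120 g/cm^3),
#' the stainless capsule steel (Mn 2, Si 1, Cr 17, Ni 12, Fe 68 wt%,
#' 8.02 g/cm^3), the stranded drive cable modelled as the same steel at an
#' effective 4.81 g/cm^3, and iridium metal (22.42 g/cm^3 by default, an
#' assumption recorded in the registry and overridable per source model).
#'
#' @param name one of `"water"`, `"dry_air"`, `"steel_capsule"`,
#'   `"steel_cable"`, `"iridium"`, `"vacuum"`.
#' @return a [Material-class] object.
#' @examples
#' loadMaterial("dry_air")
#' @export
loadMaterial <- function(name) {
  reg <- materialRegistry()
  if (!name %in% names(reg)) {
    stop("unknown material '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  m <- reg[[name]]
  new("Material", name = name,
      elements = names(m$composition %||% character()),
      fractions = as.numeric(unlist(m$composition %||% numeric())),
      density = as.numeric(m$density))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Material registry
#'
#' The full packaged registry as a named list of `composition` / `density`
#' entries.
#' @return named list.
#' @export
materialRegistry <- function() {
  if (is.null(.bmc_cache$materials)) {
    .bmc_cache$materials <- yaml::read_yaml(.extdata("physics", "materials.yaml"))
  }
  .bmc_cache$materials
}

# accessors ------------------------------------------------------------

#' @describeIn loadMaterial mass density in g/cm^3.
#' @param material a [Material-class].
#' @export
materialDensity <- function(material) material@density

#' @describeIn loadMaterial named vector of element weight fractions.
#' @export
materialFractions <- function(material) {
  setNames(material@fractions, material@elements)
}

setMethod("show", "Material", function(object) {
  cat("Material:", object@name, "\n")
  cat("  density:", object@density, "g/cm^3\n")
  if (length(object@elements)) {
    cat("  composition:",
        paste(sprintf("%s %.4g", object@elements, object@fractions),
              collapse = ", "), "\n")
  }
  invisible(object)
})
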