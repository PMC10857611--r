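# S4 classes for the central objects.  Slots are not part of the public
# surface; use the accessor functions.

#' Material definition
#'
#' Element weight fractions and mass density of a transport medium.
#'
#' @slot name material name.
#' @slot elements element symbols.
#' @slot fractions weight fractions (sum to 1).
#' @slot density mass density in g/cm^3.
#' @exportClass Material
setClass("Material",
  representation(name = "character", elements = "character",
                 fractions = "numeric", density = "numeric"))

setValidity("Material", function(object) {
  if (length(object@elements) != length(object@fractions))
    return("elements and fractions differ in length")
  if (length(object@fractions) > 0) {
    if (any(object@fractions < 0 | object@fractions > 1))
      return("weight fractions must lie in [0, 1]")
    if (abs(sum(object@fractions) - 1) > 1e-6)
      return("weight fractions must sum to 1 within 1e-6")
    if (object@density <= 0) return("density must be positive")
  }
  TRUE
})

#' Photon/electron emission spectrum
#'
#' Discrete lines plus an optional binned continuum, intensities per decay
#' (per Bq s).  Entries below the 10 keV cutoff are not admitted; electron
#' spectra additionally exclude energies above 669 keV.
#'
#' @slot kind "photon" or "electron".
#' @slot lines data.frame with columns energy_keV, intensity_per_Bq.
#' @slot continuum data.frame with columns e_lo_keV, e_hi_keV,
#'   intensity_per_Bq (integrated over the bin); may have zero rows.
#' @slot cutoff lower energy cutoff in keV.
#' @slot emax upper energy bound in keV (Inf for photons).
#' @exportClass EmissionSpectrum
setClass("EmissionSpectrum",
  representation(kind = "character", lines = "data.frame",
                 continuum = "data.frame", cutoff = "numeric",
                 emax = "numeric"))

setValidity("EmissionSpectrum", function(object) {
  if (!object@kind %in% c("photon", "electron")) return("kind must be photon/electron")
  if (nrow(object@lines) && any(object@lines$energy_keV < object@cutoff))
    return("line below the energy cutoff")
  if (nrow(object@lines) && any(object@lines$energy_keV > object@emax))
    return("line above the spectrum energy bound")
  if (nrow(object@continuum)) {
    if (any(object@continuum$e_lo_keV < object@cutoff - 1e-9))
      return("continuum bin below the energy cutoff")
    if (any(object@continuum$e_hi_keV > object@emax + 1e-9))
      return("continuum bin above the spectrum energy bound")
  }
  TRUE
})

#' Source geometry model
#'
#' Parametric constructive-solid-geometry description of an HDR source:
#' active core (optionally with rounded edges), capsule with spherical tip,
#' optional air gap between core and capsule, and drive cable, placed at the
#' centre of either a water-sphere phantom or a set of concentric air shells
#' in vacuum.  All dimensions are stored in cm.
#'
#' @slot name model name, e.g. "mHDR-v2" or "mHDR-v2r".
#' @slot dims named numeric vector of dimensions in cm.
#' @slot materials named character vector mapping regions (core, gap,
#'   capsule, cable, phantom) to material names.
#' @slot activeLength active length L (cm) used in the line-source geometry
#'   function.
#' @slot phantom list describing the phantom (type "water_sphere" with
#'   radius, or "air_shells" with radii, thickness, outer).
#' @slot rounded logical; rounded core edges (sphere-cylinder union fillet)
#'   versus sharp edges.
#' @slot densityOverride named numeric vector of density overrides (g/cm^3).
#' @exportClass SourceModel
setClass("SourceModel",
  representation(name = "character", dims = "numeric",
                 materials = "character", activeLength = "numeric",
                 phantom = "list", rounded = "logical",
                 densityOverride = "numeric"))

.REQUIRED_DIMS <- c("core_length", "core_diameter", "core_edge_radius",
                    "capsule_outer_diameter", "capsule_tip_radius",
                    "tip_to_core", "capsule_total_length",
                    "cavity_length", "cavity_diameter",
                    "cable_length", "cable_diameter")

setValidity("SourceModel", function(object) {
  miss <- setdiff(.REQUIRED_DIMS, names(object@dims))
  if (length(miss)) return(paste("missing dimension:", miss[1]))
  d <- object@dims[.REQUIRED_DIMS]
  if (any(!is.finite(d) | d <= 0))
    return(paste("non-positive dimension:",
                 .REQUIRED_DIMS[!is.finite(d) | d <= 0][1]))
  if (d[["cavity_diameter"]] < d[["core_diameter"]] - 1e-12)
    return("cavity narrower than the core")
  if (d[["capsule_outer_diameter"]] <= d[["cavity_diameter"]])
    return("capsule outer diameter must exceed the cavity diameter")
  if (!object@phantom$type %in% c("water_sphere", "air_shells"))
    return("unknown phantom type")
  TRUE
})

#' Transport configuration
#'
#' @slot cutoff transport cutoff energy, keV (photons and electrons).
#' @slot electronStepCap maximum condensed-history electron step in the
#'   scoring regions, cm (the step-size control).
#' @slot rangeFraction electron step limited to this fraction of the CSDA
#'   range.
#' @slot terminalRange electrons in the phantom whose residual CSDA range is
#'   below this length (cm) deposit their remaining energy locally; the
#'   default 0.002 cm is below every tally window width.
#' @slot secondaryRange secondary electrons are transported only when the
#'   photon interaction lies within this distance of the source centre
#'   (default Inf: always); beyond it their energy is deposited locally
#'   (kerma approximation, adequate under charged-particle equilibrium).
#' @slot fluorescence emit iridium K fluorescence photons.
#' @slot rayleigh include coherent scattering.
#' @slot secondaries transport secondary electrons set in motion by photons.
#' @slot primaryOnly terminate photons at their first interaction
#'   (attenuation-law test mode).
#' @slot nBatches number of history batches for variance estimation.
#' @slot maxSegments abort guard: maximum track segments per history.
#' @exportClass TransportConfig
setClass("TransportConfig",
  representation(cutoff = "numeric", electronStepCap = "numeric",
                 rangeFraction = "numeric", terminalRange = "numeric",
                 secondaryRange = "numeric",
                 fluorescence = "logical",
                 rayleigh = "logical", secondaries = "logical",
                 primaryOnly = "logical", nBatches = "numeric",
                 maxSegments = "numeric"))

setValidity("TransportConfig", function(object) {
  if (object@cutoff < 10) return("cutoff must be >= 10 keV")
  if (object@electronStepCap <= 0) return("electron step cap must be positive")
  if (object@nBatches < 2) return("need at least 2 batches")
  TRUE
})

#' Tally bin specification
#'
#' Spherical (r, theta) binning.  Two modes: sparse windows
#' (|r - r'| < dr, |theta - theta'| < dtheta around listed centres, the
#' published aggregation scheme) and contiguous bins defined by edges.
#' Window bins at the poles are clipped to [0, 180] and therefore one-sided.
#'
#' @slot window logical: sparse-window mode.
#' @slot rEdges,thEdges contiguous-mode bin edges (cm, degrees).
#' @slot rCenters,rHalf,thCenters,thHalf window-mode centres and half-widths.
#' @slot scoreMode "dose" (energy deposits), "kerma" (analog energy
#'   transfer at photon interactions), or "kerma_tl" (track-length
#'   collision-kerma estimator).
#' @slot medium material scored by the kerma modes.
#' @slot nBatches batches for variance estimation.
#' @exportClass TallySpec
setClass("TallySpec",
  representation(window = "logical", rEdges = "numeric", thEdges = "numeric",
                 rCenters = "numeric", rHalf = "numeric",
                 thCenters = "numeric", thHalf = "numeric",
                 scoreMode = "character", medium = "character",
                 nBatches = "numeric"))

setValidity("TallySpec", function(object) {
  if (!object@scoreMode %in% c("dose", "kerma", "kerma_tl"))
    return("scoreMode must be dose/kerma/kerma_tl")
  if (object@window) {
    if (any(diff(object@rCenters) <= 0)) return("r centres must increase")
    if (any(object@rHalf <= 0) || any(object@thHalf <= 0))
      return("window half-widths must be positive")
    if (length(object@rHalf) != length(object@rCenters) ||
        length(object@thHalf) != length(object@thCenters))
      return("half-width length mismatch")
    # windows must not overlap
    if (any(object@rCenters[-1] - object@rHalf[-1] <
            head(object@rCenters, -1) + head(object@rHalf, -1) - 1e-12))
      return("overlapping r windows")
    if (length(object@thCenters) > 1 &&
        any(object@thCenters[-1] - object@thHalf[-1] <
            head(object@thCenters, -1) + head(object@thHalf, -1) - 1e-12))
      return("overlapping theta windows")
  } else {
    if (any(diff(object@rEdges) <= 0) || any(diff(object@thEdges) <= 0))
      return("bin edges must increase")
  }
  TRUE
})

#' Filled tally grid
#'
#' Per-bin energy accumulators (sum and per-batch sum of squares) produced by
#' a transport run, plus run bookkeeping counters.
#'
#' @slot spec the [TallySpec-class].
#' @slot sum,sumsq nr x ntheta matrices of per-bin scored energy (keV) and
#'   per-batch sums of squares.
#' @slot nHistories number of source particles run.
#' @slot sourceKind "photon" or "electron".
#' @slot counters named list: emitted/deposited/escaped energy, process
#'   counts, gap and out-of-grid energy, aborted histories.
#' @slot model source model name.
#' @exportClass TallyGrid
setClass("TallyGrid",
  representation(spec = "TallySpec", sum = "matrix", sumsq = "matrix",
                 nHistories = "numeric", sourceKind = "character",
                 counters = "list", model = "character"))

setValidity("TallyGrid", function(object) {
  if (any(object@sum < 0)) return("negative accumulator")
  if (any(object@sumsq < 0)) return("negative variance accumulator")
  TRUE
})

#' Dose-rate (or kerma-rate) table on an (r, theta) grid
#'
#' Finalized rates in Gy per Bq s (per decay), with batch standard errors.
#'
#' @slot rCenters,thCenters bin centres (cm, degrees).
#' @slot value,se matrices (r rows, theta columns) of rate and SE, Gy/(Bq s).
#' @slot mode "dose" or "kerma".
#' @slot sourceKind "photon", "electron" or "combined".
#' @slot particlesPerBq emission-rate weighting applied.
#' @slot meta run metadata (windows, histories, seed, model).
#' @exportClass DoseRateTable
setClass("DoseRateTable",
  representation(rCenters = "numeric", thCenters = "numeric",
                 value = "matrix", se = "matrix", mode = "character",
                 sourceKind = "character", particlesPerBq = "numeric",
                 meta = "list"))

setValidity("DoseRateTable", function(object) {
  if (!all(dim(object@value) == c(length(object@rCenters),
                                  length(object@thCenters))))
    return("value matrix does not match the grid")
  if (any(object@se < 0, na.rm = TRUE)) return("negative standard error")
  TRUE
})

#' Transverse-axis air-kerma series
#'
#' Air kerma rate per decay at a set of transverse distances, the input to
#' the air-kerma-strength fit.
#'
#' @slot r_cm distances from the source centre, cm.
#' @slot kerma air kerma rate, Gy/(Bq s).
#' @slot se standard errors, Gy/(Bq s).
#' @slot meta run metadata.
#' @exportClass KermaSeries
setClass("KermaSeries",
  representation(r_cm = "numeric", kerma = "numeric", se = "numeric",
                 meta = "list"))

setValidity("KermaSeries", function(object) {
  if (length(object@kerma) != length(object@r_cm) ||
      length(object@se) != length(object@r_cm)) return("length mismatch")
  TRUE
})

#' TG-43U1 dataset
#'
#' @slot L active length, cm.
#' @slot SK,SKse air kerma strength and SE, uGy m^2 / (Bq s).
#' @slot Lambda,Lambdase dose-rate constant and SE, cGy/(h U).
#' @slot gL data.frame: r_cm, gL, se.
#' @slot F data.frame: r_cm, theta_deg, F, se.
#' @slot meta provenance metadata.
#' @exportClass TG43Dataset
setClass("TG43Dataset",
  representation(L = "numeric", SK = "numeric", SKse = "numeric",
                 Lambda = "numeric", Lambdase = "numeric",
                 gL = "data.frame", F = "data.frame", meta = "list"))

setValidity("TG43Dataset", function(object) {
  if (nrow(object@gL)) {
    i1 <- which(abs(object@gL$r_cm - 1) < 1e-9)
    if (length(i1) == 1 && abs(object@gL$gL[i1] - 1) > 1e-12)
      return("gL(1 cm) must equal 1")
  }
  if (any(object@gL$se < 0, na.rm = TRUE)) return("negative SE in gL")
  TRUE
})

#' Analytic test case
#'
#' A synthetic configuration with a closed-form expected field, used to
#' validate the transport and TG-43 stages independently of each other.
#'
#' @slot name case label.
#' @slot model the [SourceModel-class] to transport through (may be NULL
#'   for direct dose-table cases).
#' @slot spectrum the [EmissionSpectrum-class].
#' @slot expected function(r_cm, theta_deg) returning the expected field.
#' @slot kind "kerma" or "dose".
#' @exportClass AnalyticCase
setClass("AnalyticCase",
  representation(name = "character", model = "ANY", spectrum = "ANY",
                 expected = "function", kind = "character"))
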