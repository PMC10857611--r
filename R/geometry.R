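# Source geometry: construction from the packaged dimension files,
# containment, ray tracing, and emission-point sampling.

.REGIONS <- c("core", "gap", "capsule", "cable", "phantom", "outside")

#' Build an HDR source model
#'
#' Constructs the constructive-solid-geometry model of an HDR 192Ir source
#' from a dimension parameter file (mm) or an explicit dimension list.  The
#' model comprises the active iridium core (cylinder with optional rounded
#' edges, modelled as a sphere-free union of two coaxial cylinders), the
#' steel capsule (outer cylinder closed by a spherical tip cap), an optional
#' dry-air gap between core and capsule cavity, and a 2 mm drive cable.  The
#' origin is the geometric centre of the active core; the capsule tip lies
#' on the +z side.
#'
#' The two packaged designs are `"mHDR-v2"` and `"mHDR-v2r"`; the revised
#' core is 0.1 mm shorter and 0.05 mm narrower inside an unchanged capsule,
#' leaving the air gap.
#'
#' @param name model name; for the packaged designs the dimension file is
#'   located automatically.
#' @param file optional YAML dimension file (units mm) overriding the
#'   packaged one.
#' @param dims optional named list/vector of dimensions in mm overriding the
#'   file entirely (must contain every required field).
#' @param phantom `"water_sphere"` (default, radius `phantomRadius`) or
#'   `"air_shells"`.
#' @param phantomRadius water-sphere radius, cm.
#' @param shellRadii,shellThickness air-shell phantom geometry, cm.
#' @param rounded rounded core edges (default) versus sharp.
#' @param materials named character vector overriding region materials.
#' @param densityOverride named numeric vector of density overrides, e.g.
#'   `c(iridium = 22.42)`.
#' @return a [SourceModel-class].
#' @examples
#' m <- buildSourceModel("mHDR-v2r")
#' sourceDims(m)[["core_length"]]   # 0.35 cm
#' @export
buildSourceModel <- function(name = c("mHDR-v2", "mHDR-v2r"), file = NULL,
                             dims = NULL, phantom = c("water_sphere", "air_shells"),
                             phantomRadius = 20,
                             shellRadii = seq(10, 120, by = 10),
                             shellThickness = 0.1,
                             rounded = TRUE, materials = NULL,
                             densityOverride = numeric()) {
  phantom <- match.arg(phantom)
  if (is.null(dims)) {
    if (is.null(file)) {
      name <- match.arg(name)
      fn <- c("mHDR-v2" = "mhdr_v2.yaml", "mHDR-v2r" = "mhdr_v2r.yaml")[[name]]
      file <- .extdata("sources", fn)
    }
    y <- yaml::read_yaml(file)
    name <- y$model %||% name
    dm <- y[.REQUIRED_DIMS]
    if (any(vapply(dm, is.null, TRUE))) {
      stop("dimension file missing field: ",
           .REQUIRED_DIMS[vapply(dm, is.null, TRUE)][1])
    }
    dims <- unlist(dm)
    matmap <- unlist(y$materials)
    L <- y$active_length_cm %||% (dims[["core_length"]] / 10)
    if (!is.null(y$phantom_radius_cm) && missing(phantomRadius))
      phantomRadius <- y$phantom_radius_cm
    hasGap <- isTRUE(y$air_gap)
  } else {
    name <- if (length(name) == 1) name else "custom"
    dims <- unlist(dims)
    miss <- setdiff(.REQUIRED_DIMS, names(dims))
    if (length(miss)) stop("missing dimension: ", miss[1])
    matmap <- c(core = "iridium", gap = "dry_air", capsule = "steel_capsule",
                cable = "steel_cable")
    L <- dims[["core_length"]] / 10
    hasGap <- dims[["cavity_diameter"]] > dims[["core_diameter"]] + 1e-9 ||
      dims[["cavity_length"]] > dims[["core_length"]] + 1e-9
  }
  req <- dims[.REQUIRED_DIMS]
  bad <- .REQUIRED_DIMS[!is.finite(req) | req <= 0]
  if (length(bad)) stop("non-positive dimension: ", bad[1])
  dims_cm <- req / 10
  matmap <- c(matmap, phantom = if (phantom == "water_sphere") "water" else "vacuum")
  if (!is.null(materials)) {
    unk <- setdiff(materials, .MATERIALS)
    if (length(unk)) stop("unknown material: ", unk[1])
    matmap[names(materials)] <- materials
  }
  ph <- if (phantom == "water_sphere") {
    list(type = "water_sphere", radius = phantomRadius)
  } else {
    if (any(diff(shellRadii) <= shellThickness))
      stop("overlapping air shells")
    list(type = "air_shells", radii = shellRadii,
         thickness = shellThickness,
         outer = max(shellRadii) + shellThickness / 2 + 1)
  }
  # optional unitless extras (not scaled): axial placement of the air gap
  if (exists("y", inherits = FALSE) && !is.null(y$gap_distal_fraction)) {
    dims_cm <- c(dims_cm, gap_distal_fraction = y$gap_distal_fraction)
  } else if ("gap_distal_fraction" %in% names(dims)) {
    dims_cm <- c(dims_cm, gap_distal_fraction = dims[["gap_distal_fraction"]])
  }
  m <- new("SourceModel", name = name, dims = dims_cm,
           materials = matmap, activeLength = L, phantom = ph,
           rounded = rounded,
           densityOverride = if (length(densityOverride)) densityOverride
                             else setNames(numeric(), character()))
  m@dims <- c(m@dims, has_gap = as.numeric(hasGap))
  validObject(m)
  m
}

#' @describeIn buildSourceModel named dimensions in cm.
#' @param model a [SourceModel-class].
#' @export
sourceDims <- function(model) model@dims

#' @describeIn buildSourceModel active length L in cm.
#' @export
activeLength <- function(model) model@activeLength

# flattened parameter list for the C++ kernel
.geomBundle <- function(model) {
  d <- model@dims
  h <- d[["core_length"]] / 2
  rcore <- d[["core_diameter"]] / 2
  redge <- min(d[["core_edge_radius"]], rcore * 0.99, h * 0.99)
  hasGap <- isTRUE(d[["has_gap"]] > 0)
  rcav <- d[["cavity_diameter"]] / 2
  # axial placement of the air gap around the core: fraction of the axial
  # slack on the distal (tip) side; origin stays at the core centre
  fd <- if ("gap_distal_fraction" %in% names(d)) d[["gap_distal_fraction"]] else 0.5
  slack <- max(d[["cavity_length"]] - d[["core_length"]], 0)
  zcav_hi <- h + fd * slack
  zcav_lo <- -h - (1 - fd) * slack
  zapex <- (if (hasGap) zcav_hi else h) + d[["tip_to_core"]]
  rtip <- d[["capsule_tip_radius"]]
  rcap <- d[["capsule_outer_diameter"]] / 2
  zback <- zapex - d[["capsule_total_length"]]
  matid <- function(region) {
    mat <- model@materials[[region]]
    match(mat, .MATERIALS) - 1L
  }
  shells <- model@phantom$type == "air_shells"
  if (shells) {
    r <- model@phantom$radii; th <- model@phantom$thickness
    zone_r <- as.numeric(rbind(r - th / 2, r + th / 2))
    zone_mat <- rep(c(5L, match("dry_air", .MATERIALS) - 1L), length(r))
    zone_r <- c(zone_r, model@phantom$outer)
    zone_mat <- c(zone_mat, 5L)
    rph <- model@phantom$outer
  } else {
    zone_r <- numeric(); zone_mat <- integer()
    rph <- model@phantom$radius
  }
  list(rcore = rcore, hcore = h, redge = redge,
       rcav = rcav, zcav_lo = zcav_lo, zcav_hi = zcav_hi,
       rcap = rcap, zback = zback, ztipc = zapex - rtip, rtip = rtip,
       rcable = d[["cable_diameter"]] / 2,
       zcab_lo = zback - d[["cable_length"]],
       has_gap = hasGap, rounded = model@rounded,
       rph = rph, shells = shells,
       zone_r = zone_r, zone_mat = zone_mat,
       mat = c(matid("core"), matid("gap"), matid("capsule"),
               matid("cable"), matid("phantom"),
               match("vacuum", .MATERIALS) - 1L))
}

#' Locate points in the source/phantom geometry
#'
#' Total function mapping every finite point to exactly one region.
#'
#' @param model a [SourceModel-class].
#' @param points numeric vector of length 3 or an n x 3 matrix (cm).
#' @return character vector of region names (`core`, `gap`, `capsule`,
#'   `cable`, `phantom`, `outside`).
#' @examples
#' m <- buildSourceModel("mHDR-v2r")
#' locateRegion(m, c(0, 0, 0))      # "core"
#' locateRegion(m, c(0, 0, 30))     # "outside"
#' @export
locateRegion <- function(model, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  stopifnot(all(is.finite(points)))
  .REGIONS[.cpp_locate(.geomBundle(model), points) + 1L]
}

#' Ray distance to the next region boundary
#'
#' Smallest positive distance along a ray to a bounding surface, and the
#' region entered just beyond it (after a 1e-9 cm nudge).  The reported
#' crossing may be an internal construction surface of the same region; the
#' next region is always consistent with [locateRegion()].
#'
#' @param model a [SourceModel-class].
#' @param p position, cm.
#' @param u unit direction vector.
#' @return list with `distance` (cm), `region` (current), `next_region`.
#' @export
distanceToBoundary <- function(model, p, u) {
  stopifnot(length(p) == 3, length(u) == 3)
  nu <- sqrt(sum(u^2))
  if (abs(nu - 1) > 1e-9) stop("direction must be a unit vector")
  r <- .cpp_distance(.geomBundle(model), as.numeric(p), as.numeric(u))
  list(distance = r$distance, region = .REGIONS[r$region + 1L],
       next_region = .REGIONS[r$next_region + 1L])
}

#' Sample emission points uniformly within the active core
#'
#' Rejection sampling in the core's bounding cylinder; every returned point
#' satisfies `locateRegion(model, p) == "core"`.
#'
#' @param model a [SourceModel-class].
#' @param n number of points.
#' @param seed integer seed (counter-based; point i is reproducible
#'   individually).
#' @return n x 3 matrix of positions in cm.
#' @export
sampleEmissionPoints <- function(model, n, seed = 1) {
  .cpp_sample_core(.geomBundle(model), as.integer(n), as.double(seed))
}

#' Analytic volume of the active core
#'
#' Closed-form volume of the core solid (union of the two fillet cylinders
#' when rounded edges are enabled).
#'
#' @param model a [SourceModel-class].
#' @return volume in cm^3.
#' @export
coreVolume <- function(model) {
  g <- .geomBundle(model)
  if (!model@rounded) return(pi * g$rcore^2 * 2 * g$hcore)
  h1 <- g$hcore - g$redge
  r2 <- g$rcore - g$redge
  # union of cyl(rcore, 2 h1) and cyl(r2, 2 hcore)
  pi * g$rcore^2 * 2 * h1 + pi * r2^2 * 2 * g$redge
}

#' Export a containment probe grid
#'
#' Regular grid of probe points with their region assignment, as a CSV for
#' geometry debugging.
#'
#' @param model a [SourceModel-class].
#' @param file output CSV path.
#' @param n points per axis.
#' @param extent half-extent of the cube probed, cm.
#' @return the data.frame, invisibly.
#' @export
exportProbeGrid <- function(model, file, n = 25, extent = 0.3) {
  s <- seq(-extent, extent, length.out = n)
  g <- expand.grid(x = s, y = s, z = s)
  g$region <- locateRegion(model, as.matrix(g))
  write.csv(g, file, row.names = FALSE)
  invisible(g)
}

setMethod("show", "SourceModel", function(object) {
  d <- object@dims
  cat("SourceModel:", object@name, "\n")
  cat(sprintf("  core %.3f cm x %.3f cm diameter%s\n",
              d[["core_length"]], d[["core_diameter"]],
              if (isTRUE(d[["has_gap"]] > 0)) " (air gap in capsule cavity)" else ""))
  cat(sprintf("  capsule OD %.3f cm, tip radius %.3f cm; cable %.2f cm\n",
              d[["capsule_outer_diameter"]], d[["capsule_tip_radius"]],
              d[["cable_length"]]))
  cat("  active length L =", object@activeLength, "cm\n")
  cat("  phantom:", object@phantom$type, "\n")
  invisible(object)
})
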