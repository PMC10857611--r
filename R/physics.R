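# Photon cross sections, electron stopping powers, and the bundle of
# resampled tables handed to the transport kernel.  The packaged tables are
# static fixtures generated once by inst/scripts/generate_physics_tables.py.

.load_xs <- function() {
  if (is.null(.bmc_cache$xs)) {
    x <- rbind(read.csv(.extdata("physics", "xs_materials_1.csv"), comment.char = "#"),
               read.csv(.extdata("physics", "xs_materials_2.csv"), comment.char = "#"))
    .bmc_cache$xs <- split(x[-1], x$material)
  }
  .bmc_cache$xs
}

.load_xs_elements <- function() {
  if (is.null(.bmc_cache$xse)) {
    x <- rbind(read.csv(.extdata("physics", "xs_elements_1.csv"), comment.char = "#"),
               read.csv(.extdata("physics", "xs_elements_2.csv"), comment.char = "#"))
    .bmc_cache$xse <- split(x[-1], x$element)
  }
  .bmc_cache$xse
}

.load_sp <- function() {
  if (is.null(.bmc_cache$sp)) {
    x <- read.csv(.extdata("physics", "stopping_powers.csv"), comment.char = "#")
    .bmc_cache$sp <- split(x[-1], x$material)
  }
  .bmc_cache$sp
}

.load_ff <- function() {
  if (is.null(.bmc_cache$ff)) {
    x <- read.csv(.extdata("physics", "form_factors.csv"), comment.char = "#")
    .bmc_cache$ff <- split(x[-1], x$element)
  }
  .bmc_cache$ff
}

.load_x0 <- function() {
  if (is.null(.bmc_cache$x0)) {
    x <- read.csv(.extdata("physics", "radiation_lengths.csv"), comment.char = "#")
    .bmc_cache$x0 <- setNames(x$x0_g_cm2, x$material)
  }
  .bmc_cache$x0
}

# log-log interpolation, exact at nodes, linear extrapolation forbidden
.loglog_interp <- function(E, Etab, vtab) {
  v <- pmax(vtab, 1e-300)
  exp(approx(log(Etab), log(v), xout = log(E), rule = 1)$y)
}

#' Photon linear attenuation coefficient
#'
#' Log-log interpolation of the packaged mass interaction coefficients,
#' multiplied by the material density.  The interpolation is exact at table
#' nodes, and the total equals the sum of the photoelectric, incoherent and
#' coherent components exactly.
#'
#' @param material material name or a [Material-class].
#' @param energy photon energy in keV; must lie within the tabulated range
#'   10--1400 keV.
#' @param process `"total"`, `"photoelectric"`, `"incoherent"`,
#'   `"coherent"`, or `"energy_transfer"` (mass energy-transfer coefficient
#'   times density).
#' @param density override density in g/cm^3 (defaults to the registry
#'   density); use `density = 1` for mass coefficients in cm^2/g.
#' @return linear coefficient(s) in 1/cm.
#' @examples
#' mu("water", 316.5)                      # 1/cm
#' mu("water", 316.5, density = 1)         # cm^2/g
#' @export
mu <- function(material, energy,
               process = c("total", "photoelectric", "incoherent",
                           "coherent", "energy_transfer"),
               density = NULL) {
  process <- match.arg(process)
  name <- if (is(material, "Material")) material@name else material
  if (any(energy < 10 - 1e-9) || any(energy > 1400 + 1e-9))
    stop("energy outside the tabulated range 10-1400 keV")
  tab <- .load_xs()[[name]]
  if (is.null(tab)) stop("no cross-section table for material '", name, "'")
  if (is.null(density)) density <- loadMaterial(name)@density
  if (process == "total") {
    # interpolate the processes and add, so total == sum of processes exactly
    tot <- .loglog_interp(energy, tab$energy_keV, tab$pe) +
      .loglog_interp(energy, tab$energy_keV, tab$incoh) +
      .loglog_interp(energy, tab$energy_keV, tab$coh)
    return(tot * density)
  }
  col <- switch(process, photoelectric = tab$pe, incoherent = tab$incoh,
                coherent = tab$coh, energy_transfer = tab$mutr)
  .loglog_interp(energy, tab$energy_keV, col) * density
}

#' Mixture-rule mass coefficient from the elemental tables
#'
#' Weight-fraction-weighted sum of the packaged elemental mass coefficients;
#' the independent route used to cross-check the packaged compound tables.
#'
#' @inheritParams mu
#' @return mass coefficient(s) in cm^2/g.
#' @export
muMixture <- function(material, energy,
                      process = c("total", "photoelectric", "incoherent",
                                  "coherent", "energy_transfer")) {
  process <- match.arg(process)
  m <- if (is(material, "Material")) material else loadMaterial(material)
  els <- .load_xs_elements()
  out <- numeric(length(energy))
  fr <- materialFractions(m)
  for (el in names(fr)) {
    tab <- els[[el]]
    col <- switch(process, photoelectric = tab$pe, incoherent = tab$incoh,
                  coherent = tab$coh, energy_transfer = tab$mutr,
                  total = tab$pe + tab$incoh + tab$coh)
    out <- out + fr[[el]] * .loglog_interp(energy, tab$energy_keV, col)
  }
  out
}

#' Electron collision stopping power and CSDA range
#'
#' Packaged Berger--Seltzer collision stopping powers (MeV cm^2/g) and CSDA
#' ranges (g/cm^2), log-log interpolated.
#'
#' @inheritParams mu
#' @param energy electron kinetic energy, keV (10--1400).
#' @return numeric vector.
#' @export
stoppingPower <- function(material, energy) {
  name <- if (is(material, "Material")) material@name else material
  tab <- .load_sp()[[name]]
  if (is.null(tab)) stop("no stopping-power table for material '", name, "'")
  .loglog_interp(energy, tab$energy_keV, tab$scol)
}

#' @rdname stoppingPower
#' @export
csdaRange <- function(material, energy) {
  name <- if (is(material, "Material")) material@name else material
  tab <- .load_sp()[[name]]
  if (is.null(tab)) stop("no stopping-power table for material '", name, "'")
  .loglog_interp(energy, tab$energy_keV, tab$csda)
}

# ---- bundle handed to the C++ kernel ---------------------------------

.ATOMIC_A <- c(H = 1.008, N = 14.007, O = 15.999, Ar = 39.948, Si = 28.085,
               Cr = 51.996, Mn = 54.938, Fe = 55.845, Ni = 58.693,
               Ir = 192.217)

# iridium K fluorescence model parameters
.IR_FLUOR <- list(edge = 76.111, p_emit = 0.787 * 0.958,
                  e = c(64.896, 63.287, 73.50), p = c(0.50, 0.29, 0.21))

.physicsBundle <- function(rayleigh = TRUE, densityOverride = numeric(),
                           nGrid = 1200L) {
  key <- paste0("bundle_", rayleigh, "_", nGrid, "_",
                paste(names(densityOverride), densityOverride, collapse = "_"))
  if (!is.null(.bmc_cache[[key]])) return(.bmc_cache[[key]])
  xs <- .load_xs(); sp <- .load_sp(); x0 <- .load_x0(); ffs <- .load_ff()
  mats <- .MATERIALS
  nm <- length(mats)
  Eg <- exp(seq(log(10), log(1400), length.out = nGrid))
  mk <- function() matrix(0.0, nGrid, nm)
  pe <- mk(); incoh <- mk(); coh <- mk(); mutr <- mk(); scol <- mk(); csda <- mk()
  rho <- numeric(nm); x0v <- rep(1e30, nm)
  reg <- materialRegistry()
  for (j in seq_along(mats)) {
    m <- mats[j]
    if (m == "vacuum") { rho[j] <- 0; next }
    t <- xs[[m]]
    pe[, j] <- .loglog_interp(Eg, t$energy_keV, t$pe)
    incoh[, j] <- .loglog_interp(Eg, t$energy_keV, t$incoh)
    if (rayleigh) coh[, j] <- .loglog_interp(Eg, t$energy_keV, t$coh)
    mutr[, j] <- .loglog_interp(Eg, t$energy_keV, t$mutr)
    s <- sp[[m]]
    scol[, j] <- .loglog_interp(Eg, s$energy_keV, s$scol)
    csda[, j] <- .loglog_interp(Eg, s$energy_keV, s$csda)
    rho[j] <- if (m %in% names(densityOverride)) densityOverride[[m]]
              else reg[[m]]$density
    x0v[j] <- x0[[m]]
  }
  # Rayleigh sampling tables: cumulative integral over x = s^2 of the
  # per-gram molecular form factor squared
  sgrid <- ffs[[1]]$s
  xg <- sgrid^2
  ray_cdf <- matrix(0.0, length(xg), nm)
  for (j in seq_along(mats)) {
    m <- mats[j]
    if (m == "vacuum") next
    comp <- reg[[m]]$composition
    F2 <- numeric(length(sgrid))
    for (el in names(comp)) {
      F2 <- F2 + comp[[el]] / .ATOMIC_A[[el]] * ffs[[el]]$F^2
    }
    ray_cdf[, j] <- cumsum(c(0, 0.5 * (F2[-1] + F2[-length(F2)]) * diff(xg)))
  }
  fl_edge <- rep(0.0, nm); fl_pemit <- rep(0.0, nm)
  fl_e <- matrix(0.0, 3, nm); fl_cp <- matrix(1.0, 3, nm)
  jir <- match("iridium", mats)
  fl_edge[jir] <- .IR_FLUOR$edge
  fl_pemit[jir] <- .IR_FLUOR$p_emit
  fl_e[, jir] <- .IR_FLUOR$e
  fl_cp[, jir] <- cumsum(.IR_FLUOR$p)
  b <- list(logE0 = log(10), inv_dlog = (nGrid - 1) / (log(1400) - log(10)),
            pe = pe, incoh = incoh, coh = coh, tot = pe + incoh + coh,
            mutr = mutr, scol = scol, csda = csda, rho = rho,
            ray_x = xg, ray_cdf = ray_cdf,
            fl_edge = fl_edge, fl_pemit = fl_pemit, fl_e = fl_e,
            fl_cp = fl_cp, x0 = x0v)
  .bmc_cache[[key]] <- b
  b
}
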