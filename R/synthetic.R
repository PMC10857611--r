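# Synthetic fixtures: analytic cases with closed-form expected fields, fake
# tally streams with known statistics, and direct synthetic dose tables that
# exercise the TG-43 stage without transport noise.

#' Point source in vacuum (analytic case)
#'
#' A monoenergetic source with a vanishingly small core and every source
#' region set to vacuum, inside the air-shell phantom: the expected kerma
#' falls off exactly as 1/r^2, the anisotropy function is exactly 1, and the
#' point-source radial dose function is 1.
#'
#' @param energy photon energy, keV (10--1400).
#' @param radii shell radii for the kerma tally, cm.
#' @return an [AnalyticCase-class].
#' @export
makePointSourceVacuum <- function(energy, radii = seq(10, 120, by = 10)) {
  if (energy < 10 || energy > 1400) stop("energy outside 10-1400 keV")
  dims <- list(core_length = 0.002, core_diameter = 0.002,
               core_edge_radius = 5e-4,
               capsule_outer_diameter = 0.02, capsule_tip_radius = 0.01,
               tip_to_core = 0.004, capsule_total_length = 0.02,
               cavity_length = 0.002, cavity_diameter = 0.002,
               cable_length = 0.004, cable_diameter = 0.002)
  m <- buildSourceModel("point-vacuum", dims = dims, phantom = "air_shells",
                        shellRadii = radii,
                        materials = c(core = "vacuum", gap = "vacuum",
                                      capsule = "vacuum", cable = "vacuum"))
  new("AnalyticCase", name = sprintf("point source %g keV in vacuum", energy),
      model = m, spectrum = monoenergeticSpectrum(energy),
      expected = function(r_cm, theta_deg = 90) 1 / r_cm^2,
      kind = "kerma")
}

#' Synthetic line-source dose table with known TG-43 functions
#'
#' Emits a [DoseRateTable-class] directly (no transport) with
#' \eqn{\dot D(r,\theta) = G_L(r,\theta) e^{-a(r-1)} (1 - b\cos^2\theta)},
#' so the TG-43 stage must recover \eqn{g_L(r) = e^{-a(r-1)}} and
#' \eqn{F(r,\theta) = 1 - b\cos^2\theta} exactly.
#'
#' @param L active length, cm.
#' @param a radial attenuation coefficient, 1/cm.
#' @param b anisotropy amplitude (|b| < 1).
#' @param r,theta grid centres.
#' @param se relative SE attached to every bin (0 for exact recovery tests).
#' @return list with `dose` (the table), `gL` and `F` (the generating
#'   closed forms as functions).
#' @export
makeAttenuatingLineSource <- function(L = 0.35, a = 0.1, b = 0.2,
                                      r = c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 5),
                                      theta = seq(2, 178, by = 4),
                                      se = 0) {
  stopifnot(L > 0, abs(b) < 1)
  if (!any(abs(r - 1) < 1e-12)) r <- sort(c(r, 1))
  if (!any(abs(theta - 90) < 1e-12)) theta <- sort(c(theta, 90))
  G <- outer(r, theta, function(ri, ti) geometryFunctionL(ri, ti, L))
  D <- G * exp(-a * (r - 1)) * rep(1 - b * cos(theta * pi / 180)^2,
                                   each = length(r))
  dose <- new("DoseRateTable", rCenters = r, thCenters = theta,
              value = D, se = abs(D) * se, mode = "dose",
              sourceKind = "synthetic", particlesPerBq = 1,
              meta = list(case = "attenuating line source",
                          L = L, a = a, b = b))
  list(dose = dose,
       gL = function(r_cm) exp(-a * (r_cm - 1)),
       F = function(r_cm, theta_deg) 1 - b * cos(theta_deg * pi / 180)^2)
}

#' Fake deposit-event stream with known statistics
#'
#' Generates i.i.d. deposit events in a thin transverse ring so that batch
#' statistics can be checked against closed forms: event counts per batch
#' are binomial/Poisson-like and energies are constant or exponential.
#'
#' @param n number of events.
#' @param seed seed (R RNG, restored on exit).
#' @param r_cm,theta_deg event location (jittered within the bin).
#' @param energy constant event energy (keV), or `"exp"` for Exp(mean 50).
#' @param nBatches batch labels to attach.
#' @return data.frame with x, y, z, energy, batch.
#' @export
makeFakeTallyStream <- function(n, seed = 1, r_cm = 1, theta_deg = 90,
                                energy = 50, nBatches = 10) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  phi <- runif(n, 0, 2 * pi)
  th <- (theta_deg + runif(n, -0.05, 0.05)) * pi / 180
  rr <- r_cm + runif(n, -0.001, 0.001)
  e <- if (identical(energy, "exp")) stats::rexp(n, 1 / 50) else rep(energy, n)
  data.frame(x = rr * sin(th) * cos(phi), y = rr * sin(th) * sin(phi),
             z = rr * cos(th), energy = e,
             batch = rep_len(seq_len(nBatches), n))
}

#' Run an analytic case through the transport pipeline
#'
#' Transports the case's spectrum through its model and finalizes the kerma
#' series on the case's shell radii, for comparison with the closed form.
#'
#' @param case an [AnalyticCase-class] from [makePointSourceVacuum()].
#' @param nHistories histories.
#' @param seed seed.
#' @param estimator kerma estimator.
#' @return a [KermaSeries-class].
#' @export
runAnalyticKerma <- function(case, nHistories = 2e5, seed = 1,
                             estimator = "track") {
  radii <- case@model@phantom$radii
  spec <- tallySpecWindow(rCenters = radii, rHalf = 0.05,
                          thCenters = 90, thHalf = 90,
                          scoreMode = if (estimator == "track") "kerma_tl"
                                      else "kerma",
                          medium = "dry_air", nBatches = 10)
  # thetaHalf = 90 spans the full sphere: isotropy makes the window choice free
  grid <- runHistories(case@model, case@spectrum, spec, nHistories, seed,
                       transportConfig(secondaries = FALSE))
  kt <- finalizeKerma(grid, particlesPerBq = 1)
  new("KermaSeries", r_cm = radii, kerma = kt@value[, 1], se = kt@se[, 1],
      meta = list(case = case@name, nHistories = nHistories))
}
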