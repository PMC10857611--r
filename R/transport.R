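# Front end to the transport kernel: configuration, history batches with
# deterministic per-history random-number substreams, and worker merging.

#' Transport configuration
#'
#' @param cutoff transport cutoff energy in keV for photons and electrons
#'   (default 10; tracking stops below it and the residual energy is
#'   deposited where the particle stopped).
#' @param electronStepCap maximum condensed-history electron step length in
#'   cm (default 0.005, the step-size control used in the scoring regions).
#' @param rangeFraction electron steps are additionally capped at this
#'   fraction of the residual CSDA range (default 0.05).
#' @param secondaryRange transport secondary electrons only when they are
#'   set in motion within this distance (cm) of the source centre; beyond it
#'   their energy is deposited at the interaction site (default Inf).
#' @param terminalRange electrons in the phantom with residual CSDA range
#'   below this length (cm) deposit their remaining energy locally (default
#'   0.002 cm, below every tally window width); inside the unscored source
#'   regions electrons whose range cannot reach the region boundary are
#'   absorbed on the spot (range rejection).
#' @param fluorescence emit iridium K-fluorescence photons (steel K X rays
#'   lie below the cutoff and are deposited locally).
#' @param rayleigh include coherent (Rayleigh) scattering, sampled from the
#'   packaged atomic form factors.
#' @param secondaries transport secondary electrons set in motion by photon
#'   interactions (otherwise their energy is deposited at the interaction
#'   site).
#' @param primaryOnly terminate photons at their first interaction,
#'   depositing all energy there; used by attenuation-law validation tests.
#' @param nBatches history batches for the variance estimate (default 20).
#' @param maxSegments per-history segment guard against pathological
#'   tracking loops.
#' @return a [TransportConfig-class].
#' @export
transportConfig <- function(cutoff = 10, electronStepCap = 0.005,
                            rangeFraction = 0.05, terminalRange = 0.002,
                            secondaryRange = Inf,
                            fluorescence = TRUE,
                            rayleigh = TRUE, secondaries = TRUE,
                            primaryOnly = FALSE, nBatches = 20,
                            maxSegments = 100000) {
  new("TransportConfig", cutoff = cutoff, electronStepCap = electronStepCap,
      rangeFraction = rangeFraction, terminalRange = terminalRange,
      secondaryRange = secondaryRange,
      fluorescence = fluorescence,
      rayleigh = rayleigh, secondaries = secondaries,
      primaryOnly = primaryOnly, nBatches = nBatches,
      maxSegments = maxSegments)
}

.cfgBundle <- function(config) {
  list(cutoff = config@cutoff, chard = config@electronStepCap,
       range_frac = config@rangeFraction,
       terminal_range = config@terminalRange,
       secondary_range = config@secondaryRange,
       fluorescence = config@fluorescence, rayleigh = config@rayleigh,
       secondaries = config@secondaries, primary_only = config@primaryOnly,
       max_segments = as.integer(config@maxSegments))
}

#' Run transport histories and accumulate a tally
#'
#' Transports `nHistories` source particles through the model geometry.
#' Every history uses its own counter-based random substream keyed by
#' `(seed, history index)`, so results are independent of how the histories
#' are split across workers: `workers` only partitions the index range (in
#' batch-aligned chunks whose partial tallies are merged in deterministic
#' order), and a fixed seed yields identical results for any worker count.
#'
#' @param model a [SourceModel-class].
#' @param spectrum an [EmissionSpectrum-class] (its kind selects photon or
#'   electron transport).
#' @param spec a [TallySpec-class].
#' @param nHistories number of source particles.
#' @param seed master seed (integer).
#' @param config a [TransportConfig-class].
#' @param workers number of batch-aligned chunks to run (sequentially).
#' @return a [TallyGrid-class].
#' @export
runHistories <- function(model, spectrum, spec, nHistories, seed = 1,
                         config = transportConfig(), workers = 1) {
  stopifnot(is(model, "SourceModel"), is(spectrum, "EmissionSpectrum"),
            is(spec, "TallySpec"), is(config, "TransportConfig"))
  nHistories <- as.numeric(nHistories)
  geom <- .geomBundle(model)
  phys <- .physicsBundle(rayleigh = config@rayleigh,
                         densityOverride = model@densityOverride)
  sb <- .spectrumBundle(spectrum)
  tb <- .tallyBundle(spec)
  tb$nbatch <- as.integer(spec@nBatches)
  cfg <- .cfgBundle(config)
  particle <- if (spectrum@kind == "photon") 0L else 1L
  nb <- spec@nBatches
  if (nHistories < 1) {
    nrb <- length(.tallyRC(spec)); nthb <- length(.tallyThC(spec))
    return(new("TallyGrid", spec = spec,
               sum = matrix(0, nrb, nthb), sumsq = matrix(0, nrb, nthb),
               nHistories = 0, sourceKind = spectrum@kind,
               counters = list(emitted = 0, deposited = 0, escaped = 0,
                               gap_energy = 0, outside_energy = 0,
                               n_pe = 0, n_compton = 0, n_rayleigh = 0,
                               aborted = 0, ledger_fail = 0),
               model = model@name))
  }
  # batch-aligned worker chunks: batch b covers [ceil(b N / nb), ...)
  bstart <- ceiling((0:nb) * nHistories / nb)
  wb <- unique(round(seq(0, nb, length.out = workers + 1)))
  if (length(wb) - 1 != workers) wb <- 0:min(workers, nb)
  chunks <- cbind(bstart[wb[-length(wb)] + 1], bstart[wb[-1] + 1])
  agg <- NULL
  for (k in seq_len(nrow(chunks))) {
    if (chunks[k, 1] >= chunks[k, 2]) next
    res <- .cpp_run(geom, phys, sb, tb, cfg, nHistories,
                    chunks[k, 1], chunks[k, 2], as.double(seed), particle)
    if (is.null(agg)) agg <- res
    else {
      # every batch lives wholly inside one chunk, so adding the per-batch
      # sums is exact (the other chunks contribute exact zeros)
      for (f in c("bsum", "gap_energy", "outside_energy", "emitted",
                  "deposited", "escaped", "n_pe", "n_compton", "n_rayleigh",
                  "aborted", "ledger_fail", "e_path", "n_histories"))
        agg[[f]] <- agg[[f]] + res[[f]]
    }
  }
  nrb <- agg$nr; nthb <- agg$nth
  if (agg$aborted > 1e-6 * nHistories)
    stop("transport aborted in more than 1e-6 of histories")
  # reduce batches in fixed order: results identical for any worker count
  B <- matrix(agg$bsum, nrb * nthb, nb)
  sums <- rowSums(B)
  sumsqs <- rowSums(B^2)
  new("TallyGrid", spec = spec,
      sum = matrix(sums, nrb, nthb, byrow = TRUE),
      sumsq = matrix(sumsqs, nrb, nthb, byrow = TRUE),
      nHistories = nHistories, sourceKind = spectrum@kind,
      counters = list(emitted = agg$emitted, deposited = agg$deposited,
                      escaped = agg$escaped, gap_energy = agg$gap_energy,
                      outside_energy = agg$outside_energy,
                      n_pe = agg$n_pe, n_compton = agg$n_compton,
                      n_rayleigh = agg$n_rayleigh, aborted = agg$aborted,
                      ledger_fail = agg$ledger_fail, e_path = agg$e_path),
      model = model@name)
}

#' @describeIn runHistories photon-source convenience wrapper.
#' @export
runPhotonHistories <- function(model, spec, nHistories, seed = 1,
                               config = transportConfig(), workers = 1,
                               spectrum = loadSpectrum("photon")) {
  runHistories(model, spectrum, spec, nHistories, seed, config, workers)
}

#' @describeIn runHistories electron-source convenience wrapper.
#' @export
runElectronHistories <- function(model, spec, nHistories, seed = 1,
                                 config = transportConfig(), workers = 1,
                                 spectrum = loadSpectrum("electron")) {
  runHistories(model, spectrum, spec, nHistories, seed, config, workers)
}

#' Klein--Nishina sampler access (diagnostics)
#'
#' Draws (scattered-energy fraction, scattering-angle cosine) pairs from the
#' free-electron Klein--Nishina sampler used by the transport kernel.
#'
#' @param energy photon energy, keV.
#' @param n number of samples.
#' @param seed seed.
#' @return matrix with columns `eps` (= E'/E) and `cos_theta`.
#' @export
sampleKleinNishina <- function(energy, n, seed = 1) {
  out <- .cpp_sample_kn(as.double(energy), as.integer(n), as.double(seed))
  colnames(out) <- c("eps", "cos_theta")
  out
}

setMethod("show", "TransportConfig", function(object) {
  cat("TransportConfig: cutoff", object@cutoff, "keV, step cap",
      object@electronStepCap, "cm\n")
  cat("  fluorescence:", object@fluorescence,
      " rayleigh:", object@rayleigh,
      " secondaries:", object@secondaries,
      " primaryOnly:", object@primaryOnly, "\n")
  invisible(object)
})
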