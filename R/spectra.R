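# 192Ir emission spectra: loading, totals, reduction and sampling.

#' Load a packaged 192Ir emission spectrum
#'
#' The photon spectrum is the discrete line listing (gamma transitions plus
#' Pt/Os K and L X rays) above the 10 keV cutoff, normalized to 2.2992
#' photons per decay.  The electron spectrum combines the binned beta-
#' continuum (0.9192 electrons per decay) with the internal-conversion lines
#' (0.1531 electrons per decay), both restricted to 10--669 keV; Auger
#' electrons (below 10 keV) are excluded.
#'
#' @param kind `"photon"` or `"electron"`.
#' @return an [EmissionSpectrum-class].
#' @examples
#' spectrumTotal(loadSpectrum("photon"))   # 2.2992
#' @export
loadSpectrum <- function(kind = c("photon", "electron")) {
  kind <- match.arg(kind)
  if (kind == "photon") {
    lines <- read.csv(.extdata("spectra", "ir192_photons.csv"), comment.char = "#")
    new("EmissionSpectrum", kind = "photon", lines = lines,
        continuum = data.frame(e_lo_keV = numeric(), e_hi_keV = numeric(),
                               intensity_per_Bq = numeric()),
        cutoff = 10, emax = Inf)
  } else {
    cont <- read.csv(.extdata("spectra", "ir192_electrons_beta.csv"), comment.char = "#")
    ic <- read.csv(.extdata("spectra", "ir192_electrons_ic.csv"), comment.char = "#")
    new("EmissionSpectrum", kind = "electron", lines = ic, continuum = cont,
        cutoff = 10, emax = 669)
  }
}

#' Total per-decay intensity of a spectrum
#'
#' Sum of the line intensities plus the integrated continuum intensities
#' (bin width times differential intensity).
#'
#' @param spectrum an [EmissionSpectrum-class].
#' @return photons or electrons per decay (per Bq s).
#' @export
spectrumTotal <- function(spectrum) {
  stopifnot(is(spectrum, "EmissionSpectrum"))
  tot <- 0
  if (nrow(spectrum@lines)) tot <- tot + sum(spectrum@lines$intensity_per_Bq)
  if (nrow(spectrum@continuum)) tot <- tot + sum(spectrum@continuum$intensity_per_Bq)
  tot
}

#' Reduce a spectrum to its strongest lines
#'
#' Keeps the `nLines` highest-intensity discrete lines (continuum dropped),
#' optionally renormalizing so that the total per-decay intensity is
#' preserved.  Intended for fast smoke runs.
#'
#' @param spectrum an [EmissionSpectrum-class].
#' @param nLines number of lines to keep.
#' @param renormalize preserve the total intensity (default `TRUE`).
#' @return an [EmissionSpectrum-class] flagged as reduced.
#' @export
makeReducedSpectrum <- function(spectrum, nLines, renormalize = TRUE) {
  stopifnot(is(spectrum, "EmissionSpectrum"))
  full <- spectrumTotal(spectrum)
  ln <- spectrum@lines
  if (nLines < 1 || nLines > nrow(ln)) stop("nLines outside 1..", nrow(ln))
  keep <- ln[order(-ln$intensity_per_Bq)[seq_len(nLines)], ]
  keep <- keep[order(keep$energy_keV), ]
  if (renormalize) keep$intensity_per_Bq <- keep$intensity_per_Bq *
      full / sum(keep$intensity_per_Bq)
  new("EmissionSpectrum", kind = spectrum@kind, lines = keep,
      continuum = spectrum@continuum[0, , drop = FALSE],
      cutoff = spectrum@cutoff, emax = spectrum@emax)
}

#' Monoenergetic spectrum
#'
#' @param energy line energy, keV.
#' @param kind particle kind.
#' @param intensity per-decay intensity of the single line.
#' @return an [EmissionSpectrum-class].
#' @export
monoenergeticSpectrum <- function(energy, kind = "photon", intensity = 1) {
  new("EmissionSpectrum", kind = kind,
      lines = data.frame(energy_keV = energy, intensity_per_Bq = intensity),
      continuum = data.frame(e_lo_keV = numeric(), e_hi_keV = numeric(),
                             intensity_per_Bq = numeric()),
      cutoff = 10, emax = if (kind == "photon") Inf else 669)
}

# sampling tables handed to the C++ kernel
.spectrumBundle <- function(spectrum) {
  elo <- ehi <- w <- numeric()
  if (nrow(spectrum@lines)) {
    elo <- spectrum@lines$energy_keV
    ehi <- spectrum@lines$energy_keV
    w <- spectrum@lines$intensity_per_Bq
  }
  if (nrow(spectrum@continuum)) {
    elo <- c(elo, spectrum@continuum$e_lo_keV)
    ehi <- c(ehi, spectrum@continuum$e_hi_keV)
    w <- c(w, spectrum@continuum$intensity_per_Bq)
  }
  if (!length(w)) stop("empty spectrum")
  list(cdf = cumsum(w) / sum(w), elo = elo, ehi = ehi)
}

#' Sample emission energies from a spectrum
#'
#' Lines are drawn proportionally to their per-decay intensity; continuum
#' energies uniformly within their bin.  Uses the package's own
#' counter-based generator (independent of R's RNG state).
#'
#' @param spectrum an [EmissionSpectrum-class].
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric vector of energies in keV.
#' @export
sampleEmission <- function(spectrum, n, seed = 1) {
  .cpp_sample_spectrum(.spectrumBundle(spectrum), as.integer(n), as.double(seed))
}

setMethod("show", "EmissionSpectrum", function(object) {
  cat("EmissionSpectrum (", object@kind, ")\n", sep = "")
  cat("  lines:", nrow(object@lines),
      " continuum bins:", nrow(object@continuum), "\n")
  cat("  total:", format(spectrumTotal(object), digits = 6), "per decay\n")
  cat("  energy range: [", object@cutoff, ",",
      if (is.finite(object@emax)) object@emax else "-", "] keV\n")
  invisible(object)
})
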