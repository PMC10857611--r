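# shared fixtures: models are cheap to build, spectra are cached reads

v2r <- buildSourceModel("mHDR-v2r")
v2 <- buildSourceModel("mHDR-v2")
ph_spec <- loadSpectrum("photon")
el_spec <- loadSpectrum("electron")

# a uniform all-water world (source regions replaced by water) for electron
# free-path tests
waterWorld <- buildSourceModel("mHDR-v2r",
                               materials = c(core = "water", gap = "water",
                                             capsule = "water",
                                             cable = "water"))

# numerical Klein-Nishina oracle: mean scattered-energy fraction at E (keV)
kn_mean_eps_oracle <- function(E, n = 20001) {
  k <- E / 510.99895
  mu <- seq(-1, 1, length.out = n)
  eps <- 1 / (1 + k * (1 - mu))
  dsig <- 0.5 * eps^2 * (eps + 1 / eps - (1 - mu^2))
  sum(dsig * eps) / sum(dsig)
}
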