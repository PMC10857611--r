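test_that("spectrum totals match the documented per-decay emission rates", {
  expect_equal(spectrumTotal(ph_spec), 2.2992, tolerance = 1e-4)
  expect_equal(spectrumTotal(el_spec), 1.0723, tolerance = 1e-4)
  # beta continuum and internal-conversion components separately
  expect_equal(sum(el_spec@continuum$intensity_per_Bq), 0.9192,
               tolerance = 1e-4)
  expect_equal(sum(el_spec@lines$intensity_per_Bq), 0.1531, tolerance = 1e-4)
})

test_that("spectra respect the 10 keV cutoff and the 669 keV electron bound", {
  expect_true(all(ph_spec@lines$energy_keV >= 10))
  expect_true(all(el_spec@lines$energy_keV >= 10))
  expect_true(all(el_spec@lines$energy_keV <= 669))
  expect_true(all(el_spec@continuum$e_lo_keV >= 10))
  expect_true(all(el_spec@continuum$e_hi_keV <= 669))
  e <- sampleEmission(el_spec, 20000, seed = 3)
  expect_true(all(e >= 10 & e <= 669))
})

test_that("emission sampling reproduces the line intensities", {
  n <- 200000
  e <- sampleEmission(ph_spec, n, seed = 5)
  tot <- spectrumTotal(ph_spec)
  for (i in which(ph_spec@lines$intensity_per_Bq > 0.02)) {
    p <- ph_spec@lines$intensity_per_Bq[i] / tot
    obs <- mean(abs(e - ph_spec@lines$energy_keV[i]) < 1e-9)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs - p), 4 * se + 1e-12)
  }
})

test_that("an empty spectrum has zero total", {
  empty <- new("EmissionSpectrum", kind = "photon",
               lines = data.frame(energy_keV = numeric(),
                                  intensity_per_Bq = numeric()),
               continuum = data.frame(e_lo_keV = numeric(),
                                      e_hi_keV = numeric(),
                                      intensity_per_Bq = numeric()),
               cutoff = 10, emax = Inf)
  expect_equal(spectrumTotal(empty), 0)
})

test_that("reduced spectra keep the strongest lines and honour renormalization", {
  r1 <- makeReducedSpectrum(ph_spec, 1)
  expect_equal(r1@lines$energy_keV, 316.506)          # most intense line
  expect_equal(spectrumTotal(r1), 2.2992, tolerance = 1e-4)
  r5 <- makeReducedSpectrum(ph_spec, 5, renormalize = FALSE)
  expect_lt(spectrumTotal(r5), 2.2992)
  # sampling frequencies follow the reduced intensities
  r2 <- makeReducedSpectrum(ph_spec, 2)
  e <- sampleEmission(r2, 50000, seed = 9)
  p316 <- r2@lines$intensity_per_Bq[r2@lines$energy_keV == 316.506] /
    spectrumTotal(r2)
  obs <- mean(abs(e - 316.506) < 1e-9)
  expect_lt(abs(obs - p316), 4 * sqrt(p316 * (1 - p316) / 50000))
  expect_error(makeReducedSpectrum(ph_spec, 0), "nLines")
})
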