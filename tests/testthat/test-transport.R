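test_that("energy is conserved history by history", {
  spec <- deskBinSpec()
  g <- runPhotonHistories(v2r, spec, 20000, seed = 31)
  cn <- g@counters
  expect_equal(cn$ledger_fail, 0)
  expect_equal(cn$aborted, 0)
  expect_equal(cn$emitted, cn$deposited + cn$escaped,
               tolerance = 1e-9)
  # scoring is conservative: bins + gap + out-of-grid = deposited
  expect_equal(sum(g@sum) + cn$gap_energy + cn$outside_energy, cn$deposited,
               tolerance = 1e-9)
  ge <- runElectronHistories(v2r, spec, 5000, seed = 32)
  expect_equal(ge@counters$ledger_fail, 0)
  expect_equal(ge@counters$emitted,
               ge@counters$deposited + ge@counters$escaped, tolerance = 1e-9)
})

test_that("a vacuum world lets every photon escape without interacting", {
  vac <- buildSourceModel("mHDR-v2r",
                          materials = c(core = "vacuum", gap = "vacuum",
                                        capsule = "vacuum", cable = "vacuum",
                                        phantom = "vacuum"))
  g <- runPhotonHistories(vac, deskBinSpec(), 2000, seed = 33)
  cn <- g@counters
  expect_equal(cn$n_pe + cn$n_compton + cn$n_rayleigh, 0)
  expect_equal(cn$escaped, cn$emitted, tolerance = 1e-12)
  expect_equal(sum(g@sum), 0)
})

test_that("first-interaction process frequencies follow the cross sections", {
  # monoenergetic photons in the all-water world, primary-only mode: the
  # history ends at the first interaction, whose process is recorded
  E <- 100
  n <- 100000
  g <- runHistories(waterWorld, monoenergeticSpectrum(E), deskBinSpec(),
                    n, seed = 34, config = transportConfig(primaryOnly = TRUE))
  cn <- g@counters
  ntot <- cn$n_pe + cn$n_compton + cn$n_rayleigh
  p <- c(mu("water", E, "photoelectric"), mu("water", E, "incoherent"),
         mu("water", E, "coherent")) / mu("water", E, "total")
  obs <- c(cn$n_pe, cn$n_compton, cn$n_rayleigh) / ntot
  for (i in 1:3) {
    se <- sqrt(p[i] * (1 - p[i]) / ntot)
    expect_lt(abs(obs[i] - p[i]), 4 * se + 1e-9)
  }
})

test_that("primary-only radial profile follows exp(-mu r)/r^2", {
  E <- 316.5
  rE <- seq(2, 12, by = 1)
  spec <- tallySpecGrid(rE, c(0, 180), nBatches = 10)
  g <- runHistories(waterWorld, monoenergeticSpectrum(E), spec, 200000,
                    seed = 35, config = transportConfig(primaryOnly = TRUE))
  dt <- finalizeDose(g, particlesPerBq = 1)
  rc <- (head(rE, -1) + rE[-1]) / 2
  # deposited-energy density ~ mu E exp(-mu r)/(4 pi r^2):
  # log(D r^2) should be linear in r with slope -mu_total
  y <- log(dt@value[, 1] * rc^2)
  fit <- lm(y ~ rc)
  muw <- mu("water", E, "total")
  expect_equal(unname(coef(fit)[2]), -muw,
               tolerance = 4 * summary(fit)$coefficients[2, 2] / muw + 0.01)
})

test_that("the Klein-Nishina sampler matches numerical moments", {
  for (E in c(316.5, 100)) {
    kn <- sampleKleinNishina(E, 200000, seed = 36)
    m_obs <- mean(kn[, "eps"])
    m_true <- kn_mean_eps_oracle(E)
    se <- sd(kn[, "eps"]) / sqrt(nrow(kn))
    expect_lt(abs(m_obs - m_true), 4 * se)
    # kinematic consistency: eps = 1/(1 + k(1 - cos theta))
    k <- E / 510.99895
    expect_equal(kn[, "eps"], 1 / (1 + k * (1 - kn[, "cos_theta"])),
                 tolerance = 1e-12)
  }
})

test_that("electron tracks integrate the stopping power (CSDA path length)", {
  # monoenergetic 300 keV electrons in the all-water world: the total path
  # length per history approaches the CSDA range
  n <- 3000
  g <- runHistories(waterWorld, monoenergeticSpectrum(300, kind = "electron"),
                    deskBinSpec(), n, seed = 37,
                    config = transportConfig(terminalRange = 0))
  path <- g@counters$e_path / n
  r_csda <- csdaRange("water", 300) / 0.998
  expect_equal(path, r_csda, tolerance = 0.02)
})

test_that("results are invariant to the worker count at fixed seed", {
  spec <- deskBinSpec()
  g1 <- runPhotonHistories(v2r, spec, 8000, seed = 38, workers = 1)
  g4 <- runPhotonHistories(v2r, spec, 8000, seed = 38, workers = 4)
  expect_identical(g1@sum, g4@sum)
  expect_identical(g1@sumsq, g4@sumsq)
  # event counts are integers and must agree exactly; energy ledgers are
  # chunk-merged floating sums (equal to within accumulation order)
  for (f in c("n_pe", "n_compton", "n_rayleigh", "aborted", "ledger_fail"))
    expect_identical(g1@counters[[f]], g4@counters[[f]])
  expect_equal(g1@counters$emitted, g4@counters$emitted, tolerance = 1e-12)
  expect_equal(g1@counters$deposited, g4@counters$deposited, tolerance = 1e-12)
})

test_that("statistical errors scale as 1/sqrt(N)", {
  spec <- tallySpecGrid(seq(1, 6, by = 0.5), seq(0, 180, by = 30),
                        nBatches = 20)
  cfgf <- transportConfig(secondaries = FALSE)
  ns <- c(30000, 60000, 120000)
  mean_log_se <- sapply(seq_along(ns), function(i) {
    g <- runPhotonHistories(v2r, spec, ns[i], seed = 39 + i, config = cfgf)
    dt <- finalizeDose(g)
    ok <- dt@value > 0 & dt@se > 0
    mean(log(dt@se[ok] / dt@value[ok]))
  })
  fit <- lm(mean_log_se ~ log(ns))
  expect_lt(abs(unname(coef(fit)[2]) + 0.5), 0.05)
})

test_that("zero-history runs produce an empty tally", {
  g <- runPhotonHistories(v2r, deskBinSpec(), 0, seed = 40)
  expect_equal(sum(g@sum), 0)
  expect_equal(g@nHistories, 0)
})
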