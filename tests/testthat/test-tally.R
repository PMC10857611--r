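test_that("the bin-volume formula reproduces limiting cases and telescopes", {
  # full sphere of radius 1
  expect_equal(binVolume(0.5, 0.5, 0, 180), 4 * pi / 3, tolerance = 1e-14)
  # contiguous theta bins telescope to the full shell volume
  r <- 1.3; dr <- 0.02
  edges <- seq(0, 180, by = 5)
  vsum <- sum(binVolume(r, dr, head(edges, -1), edges[-1]))
  vshell <- (4 * pi / 3) * ((r + dr)^3 - (r - dr)^3)
  expect_equal(vsum, vshell, tolerance = 1e-12)
  expect_error(binVolume(0.1, 0.2, 0, 10), "half-width")
  expect_error(binVolume(1, 0.1, 20, 10), "theta")
})

test_that("bin volumes agree with numerical quadrature of the spherical element", {
  midpoint <- function(r, dr, tlo, thi, n) {
    rr <- r - dr + (seq_len(n) - 0.5) / n * (2 * dr)
    tt <- (tlo + (seq_len(n) - 0.5) / n * (thi - tlo)) * pi / 180
    hr <- 2 * dr / n; ht <- (thi - tlo) * pi / 180 / n
    2 * pi * sum(outer(rr^2, sin(tt))) * hr * ht
  }
  # Richardson-extrapolated midpoint rule: O(h^4), comfortably below 1e-10
  quad_volume <- function(r, dr, tlo, thi) {
    (4 * midpoint(r, dr, tlo, thi, 800) - midpoint(r, dr, tlo, thi, 400)) / 3
  }
  cases <- list(c(1.0, 0.0025, 89.9, 90.1), c(0.5, 0.05, 0, 0.5),
                c(10, 0.025, 179.5, 180), c(2, 0.5, 30, 60))
  for (cs in cases) {
    expect_equal(binVolume(cs[1], cs[2], cs[3], cs[4]),
                 quad_volume(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-10,
                 label = paste("bin volume", paste(cs, collapse = "/")))
  }
})

test_that("window scoring follows the published aggregation rules", {
  spec <- paperBinSpec()
  rc <- spec@rCenters; thc <- spec@thCenters
  # event exactly at a window centre is scored there and only there
  ev <- data.frame(x = 1, y = 0, z = 0, energy = 10)   # (r=1, theta=90)
  g <- scoreDeposits(spec, ev)
  expect_equal(sum(g@sum), 10)
  expect_equal(g@sum[which(rc == 1), which(thc == 90)], 10)
  # event between the radial grids (1.5 and 2 cm) is unscored and counted
  ev2 <- data.frame(x = 1.7, y = 0, z = 0, energy = 5)
  g2 <- scoreDeposits(spec, ev2)
  expect_equal(sum(g2@sum), 0)
  expect_equal(g2@counters$gap_energy, 5)
  # theta = 0.3 deg lies in the one-sided 0-degree pole window
  # (half-width 0.5 deg) and not in the 1-degree window (half-width 0.1)
  ev3 <- data.frame(x = 1 * sin(0.3 * pi / 180), y = 0,
                    z = 1 * cos(0.3 * pi / 180), energy = 7)
  g3 <- scoreDeposits(spec, ev3)
  expect_equal(g3@sum[which(rc == 1), which(thc == 0)], 7)
  expect_equal(sum(g3@sum), 7)
  # between-window theta (e.g. 90.5 deg, windows at 90 +- 0.1) is unscored
  ev4 <- data.frame(x = cos(0.5 * pi / 180), y = 0,
                    z = -sin(0.5 * pi / 180), energy = 3)
  g4 <- scoreDeposits(spec, ev4)
  expect_equal(sum(g4@sum), 0)
})

test_that("finalization applies the dose formula and is linear", {
  spec <- tallySpecWindow(1, 0.05, 90, 2, nBatches = 4)
  ev <- data.frame(x = 1, y = 0, z = 0, energy = 100, batch = 1)
  g <- scoreDeposits(spec, ev)
  g@nHistories <- 1
  g@sourceKind <- "photon"
  dt <- finalizeDose(g)
  V <- binVolume(1, 0.05, 88, 92)
  expect_equal(dt@value[1, 1],
               100 * 2.2992 * 1.602176634e-13 / (V * 0.998),
               tolerance = 1e-12)
  # linearity: doubling accumulators and histories leaves the rate unchanged
  g2 <- g; g2@sum <- 2 * g@sum; g2@sumsq <- 2 * g@sumsq; g2@nHistories <- 2
  expect_equal(finalizeDose(g2)@value, dt@value, tolerance = 1e-12)
})

test_that("equal batches give zero standard error and known streams the closed form", {
  spec <- tallySpecWindow(1, 0.05, 90, 2, nBatches = 5)
  ev <- makeFakeTallyStream(500, seed = 2, energy = 40, nBatches = 5)
  g <- scoreDeposits(spec, ev)
  g@nHistories <- 500; g@sourceKind <- "photon"
  # 100 events x 40 keV per batch, exactly equal batches
  expect_equal(statisticalSE(g, 1, 90), 0, tolerance = 1e-10)
  expect_equal(finalizeDose(g)@se[1, 1], 0, tolerance = 1e-12)
})

test_that("batch SE tracks the Poisson closed form and the 1/sqrt(N) law", {
  # Poisson-thinned constant-energy stream: relative SE of the total is
  # 1/sqrt(n_events)
  n <- 10000
  set.seed(11)
  ev <- makeFakeTallyStream(n, seed = 13, energy = 25, nBatches = 20)
  keep <- runif(n) < 0.5                     # thin: ~Binomial counts per batch
  spec <- tallySpecWindow(1, 0.05, 90, 2, nBatches = 20)
  g <- scoreDeposits(spec, ev[keep, ])
  g@nHistories <- n; g@sourceKind <- "photon"
  sehat <- statisticalSE(g, 1, 90) / 100
  se_true <- sqrt(sum(keep) * 0.5) / sum(keep)  # binomial(0.5) variance
  expect_lt(abs(sehat - se_true) / se_true, 0.35)
  # SE halves (x1/2) when the event count quadruples (thinning keeps the
  # per-batch counts random; unthinned streams have exactly equal batches)
  ev4 <- makeFakeTallyStream(4 * n, seed = 17, energy = 25, nBatches = 20)
  keep4 <- runif(4 * n) < 0.5
  g4 <- scoreDeposits(spec, ev4[keep4, ])
  g4@nHistories <- 4 * n; g4@sourceKind <- "photon"
  ratio <- statisticalSE(g4, 1, 90) / sehat / 100
  expect_lt(abs(ratio - 0.5), 0.25)
})

test_that("fake tally streams are reproducible and tally accounting is conservative", {
  a <- makeFakeTallyStream(1000, seed = 4)
  b <- makeFakeTallyStream(1000, seed = 4)
  expect_identical(a, b)
  spec <- deskBinSpec()
  g <- scoreDeposits(spec, a)
  expect_equal(sum(g@sum) + g@counters$gap_energy, sum(a$energy),
               tolerance = 1e-9)
})
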