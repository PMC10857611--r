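test_that("the line-source geometry function has the documented limits", {
  # point-source limit
  expect_equal(geometryFunctionL(1, 30, 1e-6), 1, tolerance = 1e-6)
  expect_equal(geometryFunctionL(2, 117, 1e-6), 0.25, tolerance = 1e-6)
  # mirror symmetry
  th <- c(5, 30, 60, 85)
  expect_equal(geometryFunctionL(1.2, th, 0.36),
               geometryFunctionL(1.2, 180 - th, 0.36), tolerance = 1e-12)
  # on-axis form
  expect_equal(geometryFunctionL(1, 0, 0.35), 1 / (1 - 0.35^2 / 4),
               tolerance = 1e-12)
  expect_error(geometryFunctionL(0.1, 0, 0.35), "inside the active line")
})

test_that("the geometry function equals the numerical line integral", {
  # G_L(r, theta) = (1/L) int_0^L dl / d(l)^2 over the active line
  line_integral <- function(r, theta, L, n = 20000) {
    th <- theta * pi / 180
    x <- r * sin(th); z <- r * cos(th)
    l <- -L / 2 + (seq_len(n) - 0.5) / n * L
    mean(1 / (x^2 + (z - l)^2))
  }
  for (cs in list(c(1, 90, 0.35), c(0.5, 30, 0.36), c(2, 150, 0.35),
                  c(0.3, 90, 0.36))) {
    expect_equal(geometryFunctionL(cs[1], cs[2], cs[3]),
                 line_integral(cs[1], cs[2], cs[3]),
                 tolerance = 1e-7,
                 label = paste("G_L", paste(cs, collapse = "/")))
  }
  # high-accuracy check at one point with Richardson-style dense sampling
  expect_equal(geometryFunctionL(1, 90, 0.35),
               line_integral(1, 90, 0.35, n = 4e6), tolerance = 1e-10)
})

test_that("TG-43 functions are exactly normalized and recover closed forms", {
  syn <- makeAttenuatingLineSource(L = 0.35, a = 0.1, b = 0.2)
  gl <- radialDoseFunction(syn$dose, 0.35)
  expect_equal(gl$gL[abs(gl$r_cm - 1) < 1e-9], 1, tolerance = 0)   # exact
  expect_equal(gl$gL, syn$gL(gl$r_cm), tolerance = 1e-12)
  Ft <- anisotropyFunction(syn$dose, 0.35)
  expect_equal(Ft$F[Ft$theta_deg == 90], rep(1, length(unique(Ft$r_cm))),
               tolerance = 0)                                       # exact
  expect_equal(Ft$F, syn$F(Ft$r_cm, Ft$theta_deg), tolerance = 1e-12)
  # degenerate synthetic fields
  syn0 <- makeAttenuatingLineSource(a = 0, b = 0)
  expect_equal(radialDoseFunction(syn0$dose, 0.35)$gL,
               rep(1, nrow(radialDoseFunction(syn0$dose, 0.35))),
               tolerance = 1e-12)
  F0 <- anisotropyFunction(syn0$dose, 0.35)
  expect_equal(F0$F, rep(1, nrow(F0)), tolerance = 1e-12)
})

test_that("missing reference bins raise explicit errors", {
  syn <- makeAttenuatingLineSource()
  d <- syn$dose
  d@thCenters <- d@thCenters + 0.5     # no 90-degree column any more
  expect_error(radialDoseFunction(d, 0.35), "90 deg")
  expect_error(anisotropyFunction(d, 0.35), "90 deg")
  d2 <- syn$dose
  keep <- abs(d2@rCenters - 1) > 1e-9
  d2@rCenters <- d2@rCenters[keep]
  d2@value <- d2@value[keep, ]; d2@se <- d2@se[keep, ]
  expect_error(radialDoseFunction(d2, 0.35), "reference")
})

test_that("the air-kerma-strength fit recovers linear inputs exactly", {
  r <- seq(10, 120, by = 10)
  # exact linear input y = a - b r (in uGy m^2 / Bq s after scaling)
  a <- 2.7e-11; b <- 1e-15
  y <- a - b * r
  ks <- new("KermaSeries", r_cm = r, kerma = y / ((r / 100)^2 * 1e6),
            se = rep(0, 12), meta = list())
  fit <- airKermaStrength(ks)
  expect_equal(fit$SK, a, tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit$fit))), 1e-20)
  # constant input: intercept equals the constant
  ks2 <- new("KermaSeries", r_cm = r, kerma = a / ((r / 100)^2 * 1e6),
             se = rep(0, 12), meta = list())
  expect_equal(airKermaStrength(ks2)$SK, a, tolerance = 1e-9)
  expect_error(airKermaStrength(new("KermaSeries", r_cm = c(10, 20),
                                    kerma = c(1, 1), se = c(0, 0),
                                    meta = list())), "at least 3")
})

test_that("the fit recovers a noisy intercept within its standard error", {
  set.seed(12)
  r <- seq(10, 120, by = 10)
  a <- 2.7e-11; b <- 1e-15
  ok <- 0
  for (i in 1:20) {
    y <- a - b * r + rnorm(12, 0, 2e-14)
    ks <- new("KermaSeries", r_cm = r, kerma = y / ((r / 100)^2 * 1e6),
              se = rep(0, 12), meta = list())
    fit <- airKermaStrength(ks)
    ok <- ok + (abs(fit$SK - a) < 4 * fit$se)
  }
  expect_gte(ok, 19)    # 4-sigma coverage
})

test_that("the dose-rate constant applies the unit conversions", {
  # D and S_K chosen so Lambda is exactly 1 cGy/(h U)
  d <- new("DoseRateTable", rCenters = 1, thCenters = 90,
           value = matrix(1e-13), se = matrix(0), mode = "dose",
           sourceKind = "combined", particlesPerBq = 1, meta = list())
  expect_equal(doseRateConstant(d, 1e-11)$Lambda, 1, tolerance = 1e-12)
  expect_error(doseRateConstant(d, 0), "positive")
})

test_that("dataset comparison is zero for identical inputs and exact for known offsets", {
  syn <- makeAttenuatingLineSource(a = 0.08, b = 0.15)
  ks <- new("KermaSeries", r_cm = seq(10, 120, by = 10),
            kerma = 2.7e-11 / ((seq(10, 120, by = 10) / 100)^2 * 1e6),
            se = rep(0, 12), meta = list())
  A <- tg43Dataset(syn$dose, ks, 0.35)
  cmpAA <- compareDatasets(A, A)
  expect_equal(cmpAA$F$pct, rep(0, nrow(cmpAA$F)), tolerance = 1e-12)
  expect_equal(cmpAA$gL$pct, rep(0, nrow(cmpAA$gL)), tolerance = 1e-12)
  # a uniform +3% offset in F
  B <- A
  synB <- makeAttenuatingLineSource(a = 0.08, b = 0.15)
  d2 <- synB$dose
  th <- d2@thCenters
  scale <- 1.03 + 0 * th; scale[abs(th - 90) < 1e-9] <- 1
  d2@value <- d2@value * rep(scale, each = length(d2@rCenters))
  B <- tg43Dataset(d2, ks, 0.35)
  cmpBA <- compareDatasets(B, A)
  off <- cmpBA$F$pct[abs(cmpBA$F$theta_deg - 90) > 1e-9]
  expect_equal(off, rep(3, length(off)), tolerance = 1e-9)
})

test_that("point-source kerma in vacuum follows the inverse-square law", {
  case <- makePointSourceVacuum(316.5, radii = c(10, 20, 40))
  ks <- runAnalyticKerma(case, nHistories = 150000, seed = 41)
  ratio <- ks@kerma[2] / ks@kerma[1]
  se <- ratio * sqrt((ks@se[1] / ks@kerma[1])^2 + (ks@se[2] / ks@kerma[2])^2)
  expect_lt(abs(ratio - 0.25), 4 * se + 1e-4)
  # absolute analytic value: K = E (mu_tr/rho) / (4 pi r^2) per photon
  kexp <- 316.5 * 1.602176634e-13 *
    mu("dry_air", 316.5, "energy_transfer", density = 1) / (4 * pi * 10^2)
  expect_equal(ks@kerma[1], kexp, tolerance = 4 * ks@se[1] / ks@kerma[1] + 0.01)
})
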