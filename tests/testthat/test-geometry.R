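test_that("the two packaged designs differ only by the documented core deltas", {
  d2 <- sourceDims(v2); d2r <- sourceDims(v2r)
  expect_equal(d2[["core_length"]] - d2r[["core_length"]], 0.01)     # 0.1 mm
  expect_equal(d2[["core_diameter"]] - d2r[["core_diameter"]], 0.005)  # 0.05 mm
  same <- c("capsule_outer_diameter", "capsule_tip_radius",
            "capsule_total_length", "cavity_length", "cavity_diameter",
            "cable_length", "cable_diameter")
  expect_equal(d2[same], d2r[same])
  expect_true(d2r[["has_gap"]] > 0)
  expect_false(d2[["has_gap"]] > 0)
  expect_lt(coreVolume(v2r), coreVolume(v2))
  expect_equal(activeLength(v2), 0.36)
  expect_equal(activeLength(v2r), 0.35)
})

test_that("invalid dimensions are rejected with the field named", {
  dims <- as.list(sourceDims(v2) * 10)
  dims$has_gap <- NULL
  bad <- dims; bad$capsule_outer_diameter <- 0
  expect_error(buildSourceModel("x", dims = bad), "capsule_outer_diameter")
  bad2 <- dims; bad2$core_length <- NULL
  expect_error(buildSourceModel("x", dims = bad2), "core_length")
})

test_that("point containment matches the design geometry", {
  expect_equal(locateRegion(v2r, c(0, 0, 0)), "core")
  expect_equal(locateRegion(v2r, c(0, 0, 30)), "outside")
  expect_equal(locateRegion(v2r, c(5, 0, 0)), "phantom")
  # just outside the v2r core but inside the cavity: the air gap; in the
  # wider v2 core the same point is still iridium
  expect_equal(locateRegion(v2r, c(0.031, 0, 0)), "gap")
  expect_equal(locateRegion(v2, c(0.031, 0, 0)), "core")
  expect_equal(locateRegion(v2, c(0.034, 0, 0)), "capsule")
  # capsule wall and cable
  expect_equal(locateRegion(v2r, c(0.040, 0, 0)), "capsule")
  expect_equal(locateRegion(v2r, c(0, 0, -0.35)), "cable")
})

test_that("axial ray from the origin reaches the core boundary at the half-length", {
  d <- distanceToBoundary(v2r, c(0, 0, 0), c(0, 0, 1))
  expect_equal(d$distance, 0.175, tolerance = 1e-7)
  expect_equal(d$region, "core")
  expect_equal(d$next_region, "gap")
  d2 <- distanceToBoundary(v2, c(0, 0, 0), c(0, 0, 1))
  expect_equal(d2$distance, 0.18, tolerance = 1e-7)
  expect_equal(d2$next_region, "capsule")
  # transverse ray from 10 cm exits the phantom sphere at 20 cm
  d3 <- distanceToBoundary(v2r, c(10, 0, 0), c(1, 0, 0))
  expect_equal(d3$distance, 10, tolerance = 1e-7)
  expect_equal(d3$next_region, "outside")
})

test_that("ray marching and point containment agree on random rays", {
  set.seed(42)
  for (i in 1:200) {
    p <- runif(3, -0.4, 0.4)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    d <- distanceToBoundary(v2r, p, u)
    q <- p + (d$distance + 1e-9) * u
    expect_equal(d$next_region, locateRegion(v2r, q))
    expect_true(d$next_region != d$region)
  }
})

test_that("every point maps to exactly one region and hit-count volumes match", {
  set.seed(7)
  n <- 200000
  pts <- matrix(runif(3 * n, -0.4, 0.4), ncol = 3)  # cube around the source
  reg <- locateRegion(v2r, pts)
  expect_true(all(reg %in% c("core", "gap", "capsule", "cable", "phantom")))
  vcube <- 0.8^3
  # core volume by hit counting vs the closed form
  p_hit <- mean(reg == "core")
  se <- sqrt(p_hit * (1 - p_hit) / n)
  expect_lt(abs(p_hit - coreVolume(v2r) / vcube), 4 * se)
  # gap volume: cavity minus core
  g <- brachyMC:::.geomBundle(v2r)
  vgap <- pi * g$rcav^2 * (g$zcav_hi - g$zcav_lo) - coreVolume(v2r)
  p_gap <- mean(reg == "gap")
  expect_lt(abs(p_gap - vgap / vcube), 4 * sqrt(p_gap * (1 - p_gap) / n))
})

test_that("emission points are uniform within the core", {
  pts <- sampleEmissionPoints(v2r, 50000, seed = 21)
  expect_true(all(locateRegion(v2r, pts) == "core"))
  h <- sourceDims(v2r)[["core_length"]] / 2
  # symmetry: mean z near 0
  expect_lt(abs(mean(pts[, 3])), 3 * sd(pts[, 3]) / sqrt(nrow(pts)))
  # uniformity along z: central |z| < h/4 band holds ~1/4 of the points
  # (the rounded edges live at |z| > 3h/4 and do not touch the band)
  frac <- mean(abs(pts[, 3]) < h / 4)
  expect_lt(abs(frac - 0.25), 4 * sqrt(0.25 * 0.75 / nrow(pts)) + 0.002)
  # determinism: same seed, same points
  expect_identical(pts, sampleEmissionPoints(v2r, 50000, seed = 21))
})

test_that("probe-grid export writes a region CSV", {
  f <- tempfile(fileext = ".csv")
  g <- exportProbeGrid(v2r, f, n = 7, extent = 0.2)
  expect_true(file.exists(f))
  expect_equal(nrow(read.csv(f)), 7^3)
  expect_true("region" %in% names(read.csv(f)))
})
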