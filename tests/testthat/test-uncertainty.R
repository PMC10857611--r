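test_that("quadrature combination reproduces the published budget totals", {
  # worked example: the near-source dose column
  expect_equal(combinedDisplay(c(0.46, 0.01, 4, 1, 0.03, 0.05, 0.03, 0.14)),
               4.15)
  b <- uncertaintyBudget()
  expect_equal(totalUncertainty("D(0.10cm)", b), 4.15)
  expect_equal(totalUncertainty("D(1.0cm)", b), 1.19)
  expect_equal(totalUncertainty("K(10cm)", b), 1.14)
  # manufacturing components excluded (the MC-to-MC comparison convention)
  expect_equal(totalUncertainty("D(0.10cm)", b, excludeManufacturing = TRUE),
               1.01)
  expect_equal(totalUncertainty("D(1.0cm)", b, excludeManufacturing = TRUE),
               1.02)
  expect_equal(totalUncertainty("K(10cm)", b, excludeManufacturing = TRUE),
               1.05)
})

test_that("quadrature is permutation-invariant, monotone, and validates input", {
  x <- c(0.46, 1, 0.05, 4)
  expect_equal(combineQuadrature(x), combineQuadrature(rev(x)))
  expect_equal(combineQuadrature(1), 1)
  expect_gt(combineQuadrature(c(x, 0.2)), combineQuadrature(x))
  for (i in seq_along(x)) {
    bumped <- x; bumped[i] <- bumped[i] + 0.1
    expect_gt(combineQuadrature(bumped), combineQuadrature(x))
  }
  expect_error(combineQuadrature(numeric()), "no uncertainty components")
  expect_error(combineQuadrature(c(1, -2)), ">= 0")
})

test_that("the budget fixture is well formed", {
  b <- uncertaintyBudget()
  expect_true(all(b$type %in% c("A", "B")))
  expect_true(all(b$percent >= 0))
  expect_setequal(unique(b$quantity), c("D(0.10cm)", "D(1.0cm)", "K(10cm)"))
  # the dynamic-source-design maximum is flagged as a bound
  expect_true(all(b$is_bound[b$component == "dynamic source design"]))
  expect_error(totalUncertainty("D(42cm)", b), "unknown quantity")
})
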