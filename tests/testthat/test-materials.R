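test_that("packaged materials carry the documented compositions and densities", {
  st <- loadMaterial("steel_capsule")
  expect_equal(materialDensity(st), 8.02)
  expect_equal(materialFractions(st),
               c(Mn = 0.02, Si = 0.01, Cr = 0.17, Ni = 0.12, Fe = 0.68))
  air <- loadMaterial("dry_air")
  expect_equal(materialDensity(air), 0.00120)
  expect_equal(materialFractions(air), c(N = 0.755, O = 0.232, Ar = 0.013))
  expect_equal(materialDensity(loadMaterial("water")), 0.998)
  expect_equal(materialDensity(loadMaterial("steel_cable")), 4.81)

  for (nm in c("water", "dry_air", "steel_capsule", "steel_cable", "iridium"))
    expect_equal(sum(materialFractions(loadMaterial(nm))), 1, tolerance = 1e-6)
})

test_that("unknown materials are rejected", {
  expect_error(loadMaterial("unobtainium"), "unknown material")
})
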