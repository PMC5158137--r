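test_that("a curve that never reaches contact is pure baseline", {
  spec <- CurveSpec(contactPoint = 1800, zRange = c(0, 1800),
                    deflectionNoiseSd = 0, baselineSlope = 0.001)
  fc <- generateForceCurve(spec)
  expect_equal(fc@d, 0.001 * (fc@z - fc@z[1]), tolerance = 1e-12)
})

test_that("noiseless curves satisfy the implicit contact equation", {
  fc <- noiselessCurve(1000)
  past <- fc@z > 600
  delta <- (fc@z[past] - 600) - fc@d[past]
  lhs <- fc@k * fc@d[past]
  rhs <- sneddonForce(delta, 1000, 0.5, fc@Rs)
  expect_equal(lhs, rhs, tolerance = 1e-6)
  ## deflection monotone non-decreasing past contact
  expect_true(all(diff(fc@d[past]) >= 0))
  ## pre-contact region carries no force
  expect_true(all(fc@d[fc@z <= 600] == 0))
})

test_that("the generated force passes the shallow-indentation anchor", {
  ## E = 1000 Pa, nu = 0.5, Rs = 2250 nm, k = 0.08 N/m: at delta = 10 nm
  ## the force is ~2.67 pN, within 1% of the Hertz closed form
  fc <- noiselessCurve(1000, zStep = 0.5)
  past <- fc@z > 600
  delta <- (fc@z[past] - 600) - fc@d[past]
  i <- which.min(abs(delta - 10))
  Fi <- fc@k * fc@d[past][i]
  expect_equal(Fi, hertzForce(delta[i], 1000, 0.5, 2250),
               tolerance = 0.01)
  expect_equal(Fi, 2.67e-3, tolerance = 0.02)
})

test_that("curve generation is deterministic and noise is seed-controlled", {
  s1 <- CurveSpec(deflectionNoiseSd = 1, seed = 5L)
  expect_identical(generateForceCurve(s1)@d, generateForceCurve(s1)@d)
  s2 <- CurveSpec(deflectionNoiseSd = 1, seed = 6L)
  expect_false(identical(generateForceCurve(s1)@d,
                         generateForceCurve(s2)@d))
})

test_that("excessive indentation ranges are rejected", {
  expect_error(generateForceCurve(
    CurveSpec(contactPoint = 100, zRange = c(0, 3000))),
    "bead radius")
  expect_error(CurveSpec(poissonRatio = 0.7), "poissonRatio")
  expect_error(CurveSpec(youngsModulus = -5), "youngsModulus")
})
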