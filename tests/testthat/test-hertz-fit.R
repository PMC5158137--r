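test_that("force-indentation conversion is plain arithmetic", {
  ## flat baseline, then a sample with 20 nm corrected deflection at
  ## z - z0 = 100 nm under k = 0.08 N/m -> F = 1.6 nN, delta = 80 nm
  z <- seq(0, 1000, by = 10)
  d <- numeric(length(z))
  d[z == 600] <- 20
  fc <- ForceCurve(z, d, k = 0.08, Rs = 2250, id = "arith")
  ic <- toForceIndentation(fc, z0 = 500)
  i <- which(z == 600)
  expect_equal(ic@force[i], 1.6, tolerance = 1e-9)
  expect_equal(ic@delta[i], 80, tolerance = 1e-9)
  ## zero deflection everywhere: F = 0, delta = z - z0
  fc0 <- ForceCurve(z, numeric(length(z)), k = 0.08, Rs = 2250)
  ic0 <- toForceIndentation(fc0, z0 = 500)
  expect_true(all(ic0@force == 0))
  expect_equal(ic0@delta, z - 500, tolerance = 1e-12)
  expect_identical(ic0@preContact, z < 500)
})

test_that("baseline estimation demands enough pre-contact samples", {
  fc <- ForceCurve(seq(0, 90, 10), rep(0, 10), k = 0.1, Rs = 2250)
  expect_error(toForceIndentation(fc, 50, baselineFraction = 0.3),
               "baseline underdetermined")
  expect_error(toForceIndentation(fc, 2000), "z range")
})

test_that("conversion with the true contact point reproduces the model", {
  fc <- noiselessCurve(800)
  ic <- toForceIndentation(fc, z0 = 600)
  post <- !ic@preContact & ic@delta > 1
  expect_equal(ic@force[post],
               sneddonForce(ic@delta[post], 800, 0.5, fc@Rs),
               tolerance = 1e-6)
})

test_that("noiseless round trips recover modulus and contact point", {
  for (E in c(200, 5000)) {
    fc <- noiselessCurve(E)
    for (dep in c(200, 600)) {
      f <- fitHertz(fc, dep)
      expect_lt(abs(f@E - E) / E, 0.001)
      expect_lt(abs(f@z0 - 600), 1)
      expect_identical(f@status, "ok")
      expect_gte(f@nPoints, 10L)
    }
  }
})

test_that("fitted modulus scales linearly with the observed forces", {
  fc <- noiselessCurve(500)
  f1 <- fitHertz(fc, 400)
  ## tripling the spring constant triples every force at unchanged
  ## deflection/indentation, so the fitted E must scale by exactly 3
  fc2 <- ForceCurve(fc@z, fc@d, k = fc@k * 3, Rs = fc@Rs, id = "x3")
  f2 <- fitHertz(fc2, 400)
  expect_equal(f2@E / f1@E, 3, tolerance = 1e-6)
  expect_equal(f2@z0, f1@z0, tolerance = 1e-3)
})

test_that("results are invariant to expressing z in micrometres", {
  fc <- noiselessCurve(1000)
  um <- ForceCurve(fc@z / 1000, fc@d / 1000, k = fc@k, Rs = fc@Rs,
                   nu = fc@nu, zUnit = "um")
  a <- fitHertz(fc, 400); b <- fitHertz(um, 400)
  expect_equal(b@E, a@E, tolerance = 1e-9)
  expect_equal(b@z0, a@z0, tolerance = 1e-6)
})

test_that("batch fitting is per-curve robust and model-consistent", {
  fc <- noiselessCurve(500)
  curves <- lapply(1:8, function(i) {
    ForceCurve(fc@z, fc@d, k = fc@k, Rs = fc@Rs,
               id = sprintf("c%02d", i))
  })
  tab <- batchFit(curves)
  expect_identical(nrow(tab), 24L)
  for (dep in c(200, 400, 600))
    expect_identical(length(unique(tab$E_Pa[tab$depth_nm == dep])), 1L)
  ## three depths agree within 1% on model-consistent data
  e <- tapply(tab$E_Pa, tab$depth_nm, unique)
  expect_lt(diff(range(e)) / min(e), 0.01)
  expect_error(batchFit(list()), "empty")
  ## a contactless curve fails its row without aborting the batch
  flat <- ForceCurve(fc@z, numeric(length(fc@z)), k = fc@k, Rs = fc@Rs,
                     id = "flat")
  tab2 <- batchFit(c(curves[1], list(flat)), depths = 400)
  expect_identical(tab2$status[1], "ok")
  expect_match(tab2$status[2], "error")
})

test_that("per-cell aggregation takes the median modulus per depth", {
  specs <- lapply(c(1L, 2L, 3L), function(s)
    CurveSpec(youngsModulus = 500, deflectionNoiseSd = 1, seed = s))
  curves <- mapply(function(sp, i) generateForceCurve(sp, id = paste0("c", i)),
                   specs, 1:3)
  tab <- batchFit(curves, depths = 400,
                  cellIds = c("cellA", "cellA", "cellA"))
  cells <- attr(tab, "cells")
  expect_equal(cells$E_Pa[1], median(tab$E_Pa), tolerance = 1e-12)
})
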