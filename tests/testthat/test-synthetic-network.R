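test_that("identical specs give bit-identical images and ground truth", {
  spec <- NetworkSpec(nFilaments = 12L, seed = 42L)
  a <- generateFilamentImage(spec)
  b <- generateFilamentImage(spec)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(a$truth@angles, b$truth@angles)
  expect_identical(a$truth@crossingCount, b$truth@crossingCount)
})

test_that("an empty network renders pure background with zero-length truth", {
  out <- generateFilamentImage(NetworkSpec(nFilaments = 0L, seed = 3L))
  expect_identical(out$truth@centerlineLength, 0L)
  expect_identical(out$truth@crossingCount, 0L)
  ## background + noise only: nothing above background + 5 sd
  expect_lt(max(pixels(out$image)), 0.05 + 5 * 0.02)
})

test_that("single-angle populations have axial resultant length exactly 1", {
  out <- generateFilamentImage(NetworkSpec(
    nFilaments = 20L, orientationMode = "single_angle", meanAngle = 30,
    seed = 8L))
  expect_equal(out$truth@resultantLength, 1, tolerance = 1e-12)
})

test_that("two orthogonal filaments through the centre cross exactly once", {
  fil <- data.frame(row = c(128, 128), col = c(128, 128),
                    angle = c(0, 90))
  tr <- networkTruth(fil, c(256L, 256L))
  expect_identical(tr@crossingCount, 1L)
})

test_that("ground-truth resultant length equals direct enumeration", {
  for (seed in 1:5) {
    spec <- NetworkSpec(nFilaments = 9L, orientationMode = "uniform_axial",
                        seed = seed)
    out <- generateFilamentImage(spec)
    oracle <- Mod(mean(exp(2i * out$truth@angles * pi / 180)))
    expect_equal(out$truth@resultantLength, oracle, tolerance = 1e-14)
    nmax <- 9L * 8L / 2L
    expect_lte(out$truth@crossingCount, nmax)
    expect_true(out$truth@resultantLength >= 0 &&
                out$truth@resultantLength <= 1)
  }
})

test_that("rendering noise does not alter the ground truth", {
  spec <- NetworkSpec(nFilaments = 8L, seed = 4L)
  fil <- sampleFilaments(spec)
  tr <- networkTruth(fil, spec@imageSize)
  ## render under several noise realisations; truth is recomputed from
  ## the same line geometry and must be unchanged
  for (s in c(11L, 12L)) {
    spec2 <- NetworkSpec(nFilaments = 8L, seed = 4L, noiseSd = 0.1)
    img <- renderNetwork(fil, spec2)
    tr2 <- networkTruth(fil, spec2@imageSize)
    expect_identical(tr2@centerlineLength, tr@centerlineLength)
    expect_identical(tr2@crossingCount, tr@crossingCount)
    expect_identical(tr2@resultantLength, tr@resultantLength)
  }
})

test_that("invalid network specs name the offending field", {
  expect_error(NetworkSpec(imageSize = c(32L, 32L)), "imageSize")
  expect_error(NetworkSpec(dispersion = -1), "dispersion")
  expect_error(NetworkSpec(filamentWidth = 0), "filamentWidth")
  expect_error(NetworkSpec(orientationMode = "bogus"), "orientationMode")
})

test_that("rotating filaments shifts angles mod 180 and keeps the truth", {
  spec <- NetworkSpec(nFilaments = 7L, seed = 6L)
  fil <- sampleFilaments(spec)
  rot <- rotateFilaments(fil, 40, spec@imageSize)
  expect_equal(rot$angle, (fil$angle + 40) %% 180, tolerance = 1e-12)
  ## resultant length is rotation invariant
  t0 <- networkTruth(fil, spec@imageSize)
  t1 <- networkTruth(rot, spec@imageSize)
  expect_equal(t1@resultantLength, t0@resultantLength, tolerance = 1e-12)
})
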