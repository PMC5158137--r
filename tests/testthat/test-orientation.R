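test_that("axis-aligned lines get their exact axial angle", {
  ## 1-px lines: only the matching element survives the opening
  horiz <- renderLine(0, width = 1)
  fh <- orientationMap(horiz)
  expect_true(all(fh@angle[horiz & fh@response > 0] == 0))
  vert <- renderLine(90, width = 1)
  fv <- orientationMap(vert)
  expect_true(all(fv@angle[vert & fv@response > 0] == 90))
  ## wider bands admit the neighbouring 10-degree elements too; the
  ## smallest-angle tie-break then keeps horizontal lines at exactly 0
  fh3 <- orientationMap(renderLine(0, width = 3))
  expect_true(all(fh3@angle[fh3@valid] == 0))
})

test_that("a 45-degree line resolves to 40/50 with the smallest-angle tie-break", {
  mask <- renderLine(45)
  f <- orientationMap(mask)
  got <- f@angle[mask & f@response > 0]
  expect_true(all(got %in% c(40, 50)))
  ## brute-force oracle: wherever the opened 40- and 50-deg responses tie,
  ## the recorded angle must be 40
  idx <- which(mask & f@response > 0, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    r40 <- bruteLineResponse(mask, r, c, 40)
    r50 <- bruteLineResponse(mask, r, c, 50)
    if (r40 && r50) expect_identical(f@angle[r, c], 40)
  }
})

test_that("images smaller than the element are rejected", {
  expect_error(orientationMap(matrix(TRUE, 8, 8)), "smaller than")
})

test_that("alignment follows the doubled-angle resultant length", {
  ## all 30 degrees -> S = 1
  ang <- matrix(30, 20, 20); valid <- matrix(TRUE, 20, 20)
  f <- new("OrientationField", angle = ang, response = ang * 0 + 1,
           valid = valid, angleSet = seq(0, 170, 10))
  S <- alignmentValues(alignmentMap(f, windowDiameter = 7))
  expect_equal(max(abs(S - 1)), 0, tolerance = 1e-12)
  ## equal mix of 0 and 90: doubled vectors antipodal -> S = 0
  ang2 <- matrix(rep(c(0, 90), 200), 20, 20)
  f2 <- new("OrientationField", angle = ang2, response = ang2 * 0 + 1,
            valid = valid, angleSet = seq(0, 170, 10))
  S2 <- alignmentValues(alignmentMap(f2, windowDiameter = 21))
  ## interior windows hold a balanced mix
  expect_lt(max(abs(S2[10:11, 10:11])), 0.05)
  ## equal mix of 0 and 45 -> |(1 + i)/2| = sqrt(2)/2
  ang3 <- matrix(rep(c(0, 45), 200), 20, 20)
  f3 <- new("OrientationField", angle = ang3, response = ang3 * 0 + 1,
            valid = valid, angleSet = c(seq(0, 170, 10), 45))
  S3 <- alignmentValues(alignmentMap(f3, windowDiameter = 21))
  expect_equal(S3[10, 10], sqrt(2) / 2, tolerance = 0.02)
})

test_that("alignment map equals direct enumeration on a hand-set field", {
  set.seed(7)
  ang <- matrix(sample(seq(0, 170, 10), 64, replace = TRUE), 8, 8)
  valid <- matrix(stats::runif(64) < 0.8, 8, 8)
  f <- new("OrientationField", angle = ang, response = valid * 1,
           valid = valid, angleSet = seq(0, 170, 10))
  for (dm in c(3, 5, 7)) {
    S <- alignmentValues(alignmentMap(f, windowDiameter = dm))
    for (r in 1:8) for (c in 1:8) {
      o <- bruteAlignment(ang, valid, r, c, dm)
      if (is.na(o)) expect_true(is.na(S[r, c])) else
        expect_equal(S[r, c], o, tolerance = 1e-12)
    }
  }
})

test_that("per-cell alignment averages MT pixels and flags empty cells", {
  S <- matrix(1, 10, 10)
  map <- new("AlignmentMap", S = S, windowDiameter = 5)
  expect_identical(cellAlignment(map, matrix(TRUE, 10, 10)), 1)
  S2 <- matrix(c(1, 0), 10, 10)
  map2 <- new("AlignmentMap", S = S2, windowDiameter = 5)
  expect_equal(cellAlignment(map2, matrix(TRUE, 10, 10)), 0.5)
  expect_error(cellAlignment(map, matrix(FALSE, 10, 10)), "no MT pixels")
})

test_that("a single-angle network scores near-perfect alignment", {
  spec <- NetworkSpec(imageSize = c(160L, 160L), nFilaments = 10L,
                      orientationMode = "single_angle", meanAngle = 30,
                      filamentWidth = 3, blurSigma = 0,
                      backgroundLevel = 0, noiseSd = 0, seed = 5L)
  out <- generateFilamentImage(spec)
  mask <- binarize(out$image, 0.5)
  expect_gte(analyzeOrientation(mask)$alignment, 0.95)
})

test_that("alignment decreases monotonically with orientation dispersion", {
  disp <- c(0.5, 1, 2, 4, 8, 32)
  truthR <- numeric(); cellS <- numeric()
  for (i in seq_along(disp)) {
    spec <- NetworkSpec(imageSize = c(160L, 160L), nFilaments = 15L,
                        orientationMode = "wrapped_dispersion",
                        meanAngle = 45, dispersion = disp[i],
                        filamentWidth = 3, blurSigma = 0,
                        backgroundLevel = 0, noiseSd = 0, seed = 21L)
    out <- generateFilamentImage(spec)
    truthR[i] <- out$truth@resultantLength
    cellS[i] <- analyzeOrientation(binarize(out$image, 0.5),
                                   windowDiameter = 31)$alignment
  }
  expect_gt(cor(truthR, cellS, method = "spearman"), 0.9)
  expect_true(all(cellS >= 0 & cellS <= 1))
})
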