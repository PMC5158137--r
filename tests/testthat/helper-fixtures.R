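## shared fixtures built in code

## render one straight filament through the frame centre, no blur/noise
renderLine <- function(angle, size = 96L, width = 3, blurSigma = 0) {
  spec <- NetworkSpec(imageSize = c(size, size), nFilaments = 1L,
                      filamentWidth = width, blurSigma = blurSigma,
                      backgroundLevel = 0, noiseSd = 0)
  fil <- data.frame(row = (size + 1) / 2, col = (size + 1) / 2,
                    angle = angle)
  binarize(renderNetwork(fil, spec), 0.5)
}

## brute-force rotating-filter response: element fully inside the mask
bruteLineResponse <- function(mask, r, c, angle, len = 11) {
  off <- cytomech:::lineOffsets(len, angle)
  rr <- r + off[, 1]; cc <- c + off[, 2]
  if (any(rr < 1 | rr > nrow(mask) | cc < 1 | cc > ncol(mask)))
    return(FALSE)
  all(mask[cbind(rr, cc)])
}

## brute-force windowed angle-doubled resultant length at one pixel
bruteAlignment <- function(angles, valid, r, c, diameter) {
  rad <- (diameter - 1) / 2
  num <- 0 + 0i; n <- 0
  for (dr in -rad:rad) for (dc in -rad:rad) {
    if (dr^2 + dc^2 > rad^2) next
    rr <- r + dr; cc <- c + dc
    if (rr < 1 || rr > nrow(angles) || cc < 1 || cc > ncol(angles)) next
    if (!valid[rr, cc]) next
    num <- num + exp(2i * angles[rr, cc] * pi / 180)
    n <- n + 1
  }
  if (n == 0) NA_real_ else Mod(num / n)
}

## noiseless default curve spec at a given modulus
noiselessCurve <- function(E, ...) {
  generateForceCurve(CurveSpec(youngsModulus = E, deflectionNoiseSd = 0,
                               ...))
}
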