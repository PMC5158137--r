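## Internal binary-morphology helpers. All masks are logical matrices in
## row-major image convention (row 1 = top). Offsets are integer matrices
## with columns (dr, dc). Pixels outside the frame are background.

## symmetric round: rnd(-x) == -rnd(x), ties away from zero
rnd <- function(x) sign(x) * floor(abs(x) + 0.5)

## shift a matrix by (dr, dc); out[r, c] = m[r - dr, c - dc], fill outside
shiftMat <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## digitized line of `len` pixels at axial angle `angle` (degrees, [0,180)),
## centred on the origin; returns offsets (dr, dc). Angle 0 is horizontal
## (along columns), angles increase counter-clockwise in standard x/y view,
## i.e. row offsets are -sin(theta).
lineOffsets <- function(len, angle) {
  stopifnot(len >= 1, len %% 2 == 1)
  h <- (len - 1) / 2
  th <- angle * pi / 180
  c0 <- cos(th); s0 <- sin(th)
  t <- -h:h
  if (abs(c0) >= abs(s0)) {
    dc <- t
    dr <- -rnd(t * s0 / c0)
  } else {
    dr <- -t
    dc <- rnd(t * c0 / s0)
  }
  cbind(dr = dr, dc = dc)
}

## disk of offsets with radius (diameter - 1) / 2
diskOffsets <- function(diameter) {
  r <- (diameter - 1) / 2
  g <- expand.grid(dr = -floor(r):floor(r), dc = -floor(r):floor(r))
  g <- g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, ]
  as.matrix(g)
}

## binary erosion / dilation / opening with an explicit offset set
binErode <- function(mask, off) {
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out & shiftMat(mask, -off[i, 1], -off[i, 2], fill = FALSE)
  out
}

binDilate <- function(mask, off) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out | shiftMat(mask, off[i, 1], off[i, 2], fill = FALSE)
  out
}

binOpen <- function(mask, off) binDilate(binErode(mask, off), off)

## windowed sum: out[p] = sum over offsets of x[p + off] (zero outside)
windowSum <- function(x, off) {
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(off)))
    out <- out + shiftMat(x, -off[i, 1], -off[i, 2], fill = 0)
  out
}

## number of 8-connected TRUE neighbours at each pixel
neighborCount <- function(mask) {
  m <- mask * 1
  s <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- s + shiftMat(m, dr, dc, fill = 0)
  }
  s
}

## label 8-connected components of a sparse logical mask by BFS over the
## TRUE pixel list; returns the number of components
countComponents8 <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(0L)
  h <- nrow(mask)
  key <- new.env(hash = TRUE, parent = emptyenv())
  for (i in idx) assign(as.character(i), TRUE, envir = key)
  ncomp <- 0L
  for (i in idx) {
    if (!isTRUE(get0(as.character(i), envir = key))) next
    ncomp <- ncomp + 1L
    queue <- i
    assign(as.character(i), FALSE, envir = key)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- (p - 1) %% h + 1; cc <- (p - 1) %/% h + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1 || rr > h || c2 < 1 || c2 > ncol(mask)) next
        q <- (c2 - 1) * h + rr
        if (isTRUE(get0(as.character(q), envir = key))) {
          assign(as.character(q), FALSE, envir = key)
          queue <- c(queue, q)
        }
      }
    }
  }
  ncomp
}

## Guo-Hall two-subiteration parallel thinning to a 1-px skeleton.
## Deletion conditions evaluated on the whole frame at once; iterated to a
## fixed point, hence idempotent by construction.
guoHallThin <- function(mask) {
  img <- mask
  storage.mode(img) <- "logical"
  repeat {
    changed <- FALSE
    for (step in 0:1) {
      ## clockwise neighbour labelling, p2 = north (row above):
      ## pK[r, c] must read img at the neighbour position, so shift by
      ## the negated neighbour offset
      p2 <- shiftMat(img,  1,  0); p3 <- shiftMat(img,  1, -1)
      p4 <- shiftMat(img,  0, -1); p5 <- shiftMat(img, -1, -1)
      p6 <- shiftMat(img, -1,  0); p7 <- shiftMat(img, -1,  1)
      p8 <- shiftMat(img,  0,  1); p9 <- shiftMat(img,  1,  1)
      C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
           (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      m <- if (step == 0) (p6 | p7 | !p9) & p8 else (p2 | p3 | !p5) & p4
      del <- img & (C == 1) & (N >= 2) & (N <= 3) & !m
      if (any(del)) {
        img <- img & !del
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}
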