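# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately avoid the code paths they check.

# Largest inscribed circle of one pore by exhaustive search: for every pore
# pixel (candidate center), the minimum distance to any non-pore pixel
# center inside a sufficiently padded bounding box; the diameter is twice
# the best (minus the half-pixel boundary convention).
bruteForcePoDm <- function(poreMask, pixelSize) {
  pix <- which(poreMask, arr.ind = TRUE)
  pad <- max(dim(poreMask)) + 2L
  xr <- range(pix[, 1]); yr <- range(pix[, 2])
  ex <- max(xr[2] - xr[1], yr[2] - yr[1]) + 2L
  xs <- max(1L, xr[1] - ex):min(nrow(poreMask), xr[2] + ex)
  ys <- max(1L, yr[1] - ex):min(ncol(poreMask), yr[2] + ex)
  sub <- poreMask[xs, ys, drop = FALSE]
  obst <- which(!sub, arr.ind = TRUE)
  cand <- which(sub, arr.ind = TRUE)
  best <- 0
  for (i in seq_len(nrow(cand))) {
    d2 <- (obst[, 1] - cand[i, 1])^2 + (obst[, 2] - cand[i, 2])^2
    best <- max(best, sqrt(min(d2)))
  }
  2 * (best - 0.5) * pixelSize
}

# binary closing with an exact Euclidean disk by direct neighborhood
# enumeration (small grids only)
bruteForceClosing <- function(mask, rPx) {
  offs <- expand.grid(dx = -ceiling(rPx):ceiling(rPx),
                      dy = -ceiling(rPx):ceiling(rPx))
  offs <- offs[offs$dx^2 + offs$dy^2 <= rPx^2, ]
  nr <- nrow(mask); nc <- ncol(mask)
  shiftAny <- function(m) {
    out <- matrix(FALSE, nr, nc)
    for (k in seq_len(nrow(offs))) {
      sx <- offs$dx[k]; sy <- offs$dy[k]
      xs <- max(1, 1 + sx):min(nr, nr + sx)
      ys <- max(1, 1 + sy):min(nc, nc + sy)
      out[xs, ys] <- out[xs, ys] | m[xs - sx, ys - sy]
    }
    out
  }
  dil <- shiftAny(mask != 0)
  # erosion: complement of dilation of the complement
  !shiftAny(!dil)
}

# exhaustive between-class-variance maximization over all candidate
# thresholds (midpoints between sorted unique values)
bruteForceOtsu <- function(x) {
  v <- sort(unique(as.vector(x)))
  cand <- (v[-1] + v[-length(v)]) / 2
  n <- length(x)
  best <- -Inf; bestT <- NA_real_
  for (t in cand) {
    w1 <- sum(x <= t) / n
    w2 <- 1 - w1
    if (w1 == 0 || w2 == 0) next
    bc <- w1 * w2 * (mean(x[x > t]) - mean(x[x <= t]))^2
    if (bc > best) { best <- bc; bestT <- t }
  }
  bestT
}

# concentric-annulus SectionMasks fixture built directly from geometry
annulusMasks <- function(rOutMm, rInMm, pixelSize, dimPx = NULL,
                         holes = NULL) {
  if (is.null(dimPx)) dimPx <- 2L * ceiling(rOutMm / pixelSize + 4) + 1L
  c0 <- (dimPx - 1) / 2
  xs <- (seq_len(dimPx) - 1) - c0
  X <- matrix(xs, dimPx, dimPx)
  Y <- matrix(xs, dimPx, dimPx, byrow = TRUE)
  R <- sqrt(X^2 + Y^2) * pixelSize
  total <- R <= rOutMm
  marrow <- R < rInMm
  cortical <- total & !marrow
  poreLab <- matrix(0L, dimPx, dimPx)
  tissue <- cortical
  if (!is.null(holes)) {
    for (k in seq_len(nrow(holes))) {
      hit <- ((X - (holes$cx_px[k] - c0))^2 + (Y - (holes$cy_px[k] - c0))^2) <=
        holes$r_px[k]^2
      poreLab[hit & cortical] <- k
    }
    tissue <- cortical & poreLab == 0L
  }
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  peri <- cbind(c0 + rOutMm / pixelSize * cos(th),
                c0 + rOutMm / pixelSize * sin(th))
  endo <- cbind(c0 + rInMm / pixelSize * cos(th),
                c0 + rInMm / pixelSize * sin(th))
  new("SectionMasks", tissue = tissue, total = total, cortical = cortical,
      poreLabels = poreLab, periostealContour = peri,
      endostealContour = endo, pixelSize = pixelSize)
}

# small fast section spec for property sweeps
smallSectionSpec <- function(seed, ...) {
  sectionSpec(semiAxes = c(1.5, 1.3), endoOffset = 0.55,
              maxPoreDiam = 0.28, pixelSize = 0.02, marginMm = 0.2,
              nVertices = 720, seed = seed, ...)
}
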