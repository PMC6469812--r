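# Internal raster utilities shared by the generator, segmentation and
# morphometry stages. Conventions: matrices are indexed [x, y] with 0-based
# pixel centers at integer coordinates; physical position = index * pixelSize;
# foreground connectivity is 8, background 4.

#' 8-connected labeling of a binary mask
#'
#' Labels foreground components under 8-connectivity (diagonals connect).
#' Built on 4-connected labeling followed by a union-find merge of labels
#' that touch diagonally.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix; 0 = background, components numbered from 1 in
#'   raster order of their first pixel.
#' @export
label8 <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbor pairs: (i,j)-(i+1,j+1) and (i+1,j)-(i,j+1)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nl), find, integer(1))
  # renumber components in raster order of first occurrence
  remap <- integer(nl)
  idx <- which(lab > 0L)
  rts <- root[lab[idx]]
  u <- unique(rts)
  remap[u] <- seq_along(u)
  out <- lab
  out[idx] <- remap[rts]
  out
}

# distance-transform based binary morphology with an exact Euclidean disk
# structuring element {offset : |offset| <= r}; O(N) in the image size.
diskDilate <- function(mask, rPx) {
  m <- mask != 0
  d <- EBImage::distmap(matrix(as.numeric(!m), nrow(m), ncol(m)))
  m | (d <= rPx)
}

diskErode <- function(mask, rPx) {
  m <- mask != 0
  d <- EBImage::distmap(matrix(as.numeric(m), nrow(m), ncol(m)))
  m & (d > rPx)
}

diskClose <- function(mask, rPx) diskErode(diskDilate(mask, rPx), rPx)

# number of pixels whose k-neighborhood (4-connected) is all foreground
fillSinglePixelHoles <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-nr, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -nc, drop = FALSE])
  # a single-pixel interior hole: background with all 4 neighbors foreground
  # (border pixels fail because the padded neighbor is FALSE)
  hole <- !m & up & dn & lf & rt
  # must also be an isolated background pixel diagonally? A 1-px 4-connected
  # background component can still touch another background pixel diagonally;
  # such a pixel is its own interior component of exactly one pixel and is
  # filled -- matching the single-pixel-pore filling rule.
  m | hole
}

# boundary pixels of a mask: foreground with at least one 4-neighbor outside
# the mask (or on the image border)
boundaryPixels <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-nr, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -nc, drop = FALSE])
  m & !(up & dn & lf & rt)
}

# n x 2 matrix of 0-based (x, y) coordinates of TRUE pixels
whichXY <- function(mask) {
  idx <- which(mask != 0)
  if (!length(idx)) return(matrix(numeric(0), 0, 2))
  cbind(x = (idx - 1L) %% nrow(mask), y = (idx - 1L) %/% nrow(mask))
}

#' Rasterize a simple closed polygon
#'
#' Even-odd scanline fill of a polygon given in 0-based pixel coordinates.
#' A pixel belongs to the interior when its center lies strictly inside the
#' polygon (even-odd rule); centers exactly on an edge follow the usual
#' half-open scanline convention, so adjacent polygons never overlap.
#'
#' @param poly n x 2 matrix of (x, y) vertices, 0-based pixel coordinates;
#'   the polygon closes implicitly.
#' @param dim integer c(nx, ny) of the target raster.
#' @return logical matrix of dimension `dim`.
#' @export
rasterizePolygon <- function(poly, dim) {
  nx <- dim[1]; ny <- dim[2]
  out <- matrix(FALSE, nx, ny)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(poly[-1, 1], poly[1, 1]); y2 <- c(poly[-1, 2], poly[1, 2])
  keep <- y1 != y2          # horizontal edges never cross a scanline
  x1 <- x1[keep]; x2 <- x2[keep]; y1 <- y1[keep]; y2 <- y2[keep]
  if (!length(x1)) return(out)
  for (j in seq_len(ny)) {
    yc <- j - 1
    # half-open rule: edge spans [min(y), max(y)) to count shared vertices once
    cross <- (y1 <= yc & y2 > yc) | (y2 <= yc & y1 > yc)
    if (!any(cross)) next
    xi <- x1[cross] + (yc - y1[cross]) * (x2[cross] - x1[cross]) /
      (y2[cross] - y1[cross])
    xi <- sort(xi)
    # fill between successive crossing pairs
    for (k in seq(1, length(xi) - 1, by = 2)) {
      lo <- ceiling(xi[k] + 1e-9); hi <- floor(xi[k + 1] - 1e-9)
      lo <- max(lo, 0); hi <- min(hi, nx - 1)
      if (lo <= hi) out[(lo:hi) + 1L, j] <- TRUE
    }
  }
  out
}

# minimum Euclidean distance from each point in `a` to the point set `b`
# (both n x 2), computed in blocks to bound memory
minDistToSet <- function(a, b, block = 2048L) {
  na <- nrow(a)
  out <- numeric(na)
  bx <- b[, 1]; by <- b[, 2]
  for (s in seq(1, na, by = block)) {
    e <- min(s + block - 1L, na)
    dx <- outer(a[s:e, 1], bx, "-")
    dy <- outer(a[s:e, 2], by, "-")
    m2 <- dx * dx + dy * dy
    j <- max.col(-m2, ties.method = "first")
    out[s:e] <- sqrt(m2[cbind(seq_len(e - s + 1L), j)])
  }
  out
}

# angular membership: TRUE where the angle (degrees, atan2 convention) lies
# within width/2 of center, circularly
inSector <- function(angleDeg, centerDeg, widthDeg) {
  d <- (angleDeg - centerDeg + 180) %% 360 - 180
  abs(d) <= widthDeg / 2 + 1e-12
}

asLogicalMask <- function(x, what = "mask") {
  if (is.matrix(x)) return(x != 0)
  stop(sprintf("%s must be a matrix", what))
}
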