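# Internal array helpers shared by the phantom and solver code.

# Shift a 3-D array by whole voxels, filling vacated cells with `fill`.
shiftArray <- function(a, shift, fill = 0L) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    s <- shift[ax]
    if (abs(s) >= d[ax]) return(out)  # everything shifted out
    if (s >= 0) {
      src[[ax]] <- seq_len(d[ax] - s)
      dst[[ax]] <- seq_len(d[ax] - s) + s
    } else {
      src[[ax]] <- seq_len(d[ax] + s) - s
      dst[[ax]] <- seq_len(d[ax] + s)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 6-neighbour binary erosion; voxels outside the grid count as background.
erode6 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    sh <- c(0L, 0L, 0L); sh[ax] <- s
    out <- out & shiftArray(mask, sh, fill = FALSE)
  }
  out
}

# 6-neighbour binary dilation.
dilate6 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    sh <- c(0L, 0L, 0L); sh[ax] <- s
    out <- out | shiftArray(mask, sh, fill = FALSE)
  }
  out
}

dilateN <- function(mask, n) {
  for (i in seq_len(n)) mask <- dilate6(mask)
  mask
}

# Euclidean-ball dilation by radius n voxels: union of the mask shifted by
# every integer offset inside the ball.  Iterated 6-neighbour dilation gives
# an L1 (diamond) ball, which understates offset shells; the blanket needs a
# proper Euclidean offset.
dilateEuclidean <- function(mask, n) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(mask)
  lo <- pmax(apply(idx, 2, min) - n, 1L)
  hi <- pmin(apply(idx, 2, max) + n, d)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out <- sub
  for (dx in -n:n) for (dy in -n:n) for (dz in -n:n) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dx * dx + dy * dy + dz * dz > n * n) next
    out <- out | shiftArray(sub, c(dx, dy, dz), fill = FALSE)
  }
  full <- mask
  full[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- out
  full
}

# Voxel-centre coordinate grids (mm) for a given dim/voxel size.
coordGrids <- function(d, vs) {
  list(x = array(rep((seq_len(d[1]) - 0.5) * vs[1], times = d[2] * d[3]), d),
       y = array(rep(rep((seq_len(d[2]) - 0.5) * vs[2], each = d[1]), times = d[3]), d),
       z = array(rep((seq_len(d[3]) - 0.5) * vs[3], each = d[1] * d[2]), d))
}

# Ellipsoid membership: centre and semi-axes in mm.
inEllipsoid <- function(g, centre, semi) {
  ((g$x - centre[1]) / semi[1])^2 + ((g$y - centre[2]) / semi[2])^2 +
    ((g$z - centre[3]) / semi[3])^2 <= 1
}

linearIndexToXYZ <- function(idx, d) {
  idx0 <- idx - 1L
  x <- idx0 %% d[1]
  y <- (idx0 %/% d[1]) %% d[2]
  z <- idx0 %/% (d[1] * d[2])
  as.integer(c(x, y, z) + 1L)
}
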