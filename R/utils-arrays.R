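# Internal array helpers shared by the synthetic generator, the entropy map
# and the texture-matrix builders. Everything here is plain vectorized base R
# on 3D arrays; no voxel-by-voxel loops.

# Shift a 3D array by integer offsets, padding with `fill`.
shift_array <- function(a, dx, dy, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  xs <- sx - dx; ys <- sy - dy; zs <- sz - dz
  okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]; okz <- zs >= 1 & zs <= d[3]
  out[sx[okx], sy[oky], sz[okz]] <- a[xs[okx], ys[oky], zs[okz], drop = FALSE]
  out
}

# The 26 neighbour offsets, and the 13 unique direction representatives
# (one per +/- pair) used for co-occurrence and run-length matrices.
offsets26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

offsets13 <- function() {
  o <- offsets26()
  keep <- o[, 3] > 0 | (o[, 3] == 0 & (o[, 2] > 0 | (o[, 2] == 0 & o[, 1] > 0)))
  o[keep, , drop = FALSE]
}

# Column-wise cumulative sums of a matrix without per-column loops: global
# cumsum minus per-column offsets.
col_cumsum <- function(m) {
  n1 <- nrow(m)
  cs <- cumsum(as.numeric(m))
  off <- c(0, cs[seq(n1, length(cs), by = n1)][-ncol(m)])
  matrix(cs - rep(off, each = n1), n1)
}

box_axis1 <- function(a, r) {
  d <- dim(a)
  cs <- rbind(0, col_cumsum(matrix(a, d[1])))
  hi <- pmin(seq_len(d[1]) + r, d[1]) + 1L
  lo <- pmax(seq_len(d[1]) - r, 1L)
  out <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  dim(out) <- d
  out
}

# Separable moving-window (box) sum with per-axis window [-r[a], r[a]], via
# zero-padded cumulative sums. O(N) per axis.
box_sum3 <- function(a, r) {
  r <- rep_len(r, 3)
  if (r[1] > 0) a <- box_axis1(a, r[1])
  if (r[2] > 0) a <- aperm(box_axis1(aperm(a, c(2, 1, 3)), r[2]), c(2, 1, 3))
  if (r[3] > 0) a <- aperm(box_axis1(aperm(a, c(3, 2, 1)), r[3]), c(3, 2, 1))
  a
}

# 1D convolution along each axis with symmetric (reflect) padding.
sep_filter3 <- function(a, kx, ky = kx, kz = kx) {
  conv_axis <- function(a, k, axis) {
    if (length(k) == 1L) return(a * k)
    d <- dim(a)
    r <- (length(k) - 1L) / 2L
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    b <- aperm(a, perm)
    db <- dim(b)
    n <- db[1]
    idx <- c(rev(seq_len(min(r, n))), seq_len(n), rev(n + 1 - seq_len(min(r, n))))
    while (length(idx) < n + 2 * r) idx <- c(idx[1], idx, idx[length(idx)])
    m <- matrix(b[idx, , ], nrow = n + 2 * r)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * m[seq_len(n) + (j - 1L), , drop = FALSE]
    }
    dim(out) <- db
    aperm(out, order(perm))
  }
  a <- conv_axis(a, kx, 1L)
  a <- conv_axis(a, ky, 2L)
  conv_axis(a, kz, 3L)
}

gauss_kernel1 <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  if (sigma <= 0) return(1)
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian smoothing with per-axis sigma in voxel units.
gauss_smooth3 <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3)
  sep_filter3(a,
              gauss_kernel1(sigma_vox[1]),
              gauss_kernel1(sigma_vox[2]),
              gauss_kernel1(sigma_vox[3]))
}

# Binary morphology with the 6-connected cross structuring element.
dilate3 <- function(m) {
  out <- m
  for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
    out <- out | shift_array(m, o[1], o[2], o[3], fill = FALSE)
  }
  out
}

erode3 <- function(m) {
  out <- m
  for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
    out <- out & shift_array(m, o[1], o[2], o[3], fill = FALSE)
  }
  out
}

# Voxels of m adjacent (6-connectivity) to the complement: the inner boundary.
boundary3 <- function(m) m & !erode3(m)

# Connected components of `labels > 0` where neighbours must share the same
# label value; 26-connectivity. Returns an integer component-id array
# (0 = background). Adjacency is built vectorized over the 13 undirected
# offsets; component resolution is delegated to igraph.
label_components26 <- function(labels) {
  d <- dim(labels)
  fg <- which(labels > 0)
  node <- array(0L, d)
  node[fg] <- seq_along(fg)
  offs <- offsets13()
  from <- integer(0); to <- integer(0)
  for (i in seq_len(nrow(offs))) {
    nb_lab <- shift_array(labels, offs[i, 1], offs[i, 2], offs[i, 3], fill = -1L)
    nb_node <- shift_array(node, offs[i, 1], offs[i, 2], offs[i, 3], fill = 0L)
    ok <- labels > 0L & nb_lab == labels
    from <- c(from, node[ok]); to <- c(to, nb_node[ok])
  }
  g <- igraph::make_graph(edges = as.numeric(rbind(from, to)),
                          n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  comp <- array(0L, d)
  comp[fg] <- as.integer(memb)
  comp
}
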