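# Independent brute-force oracles used to check the vectorized
# implementations. Everything here is written as plain loops / direct
# formulas, deliberately sharing no code with the package internals.

oracle_entropy <- function(values, mask, window, n_bins, eps) {
  d <- dim(values)
  idx <- which(mask)
  rng <- range(values[idx])
  w <- (rng[2] - rng[1]) / n_bins
  out <- numeric(length(idx))
  for (q in seq_along(idx)) {
    co <- arrayInd(idx[q], d)
    xs <- max(1, co[1] - window):min(d[1], co[1] + window)
    ys <- max(1, co[2] - window):min(d[2], co[2] + window)
    zs <- max(1, co[3] - window):min(d[3], co[3] + window)
    nb <- c()
    for (x in xs) for (y in ys) for (z in zs) {
      if (mask[x, y, z]) nb <- c(nb, values[x, y, z])
    }
    if (length(nb) < 2) { out[q] <- 0; next }
    b <- if (w > 0) pmin(n_bins, floor((nb - rng[1]) / w) + 1) else rep(1, length(nb))
    p <- tabulate(b, n_bins) / length(nb)
    out[q] <- -sum(p * log2(p + eps))
  }
  out
}

oracle_ch <- function(x, cl) {
  x <- as.matrix(x)
  ks <- sort(unique(cl))
  n <- nrow(x)
  g <- colMeans(x)
  W <- 0; B <- 0
  for (k in ks) {
    xi <- x[cl == k, , drop = FALSE]
    c_k <- colMeans(xi)
    for (r in seq_len(nrow(xi))) W <- W + sum((xi[r, ] - c_k)^2)
    B <- B + nrow(xi) * sum((c_k - g)^2)
  }
  (B / (length(ks) - 1)) / (W / (n - length(ks)))
}

# Symmetric normalized GLCM for one offset, by explicit voxel-pair loops.
oracle_glcm <- function(lev, offset, ng) {
  d <- dim(lev)
  M <- matrix(0, ng, ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- lev[x, y, z]
    if (i == 0) next
    xx <- x + offset[1]; yy <- y + offset[2]; zz <- z + offset[3]
    if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3]) next
    j <- lev[xx, yy, zz]
    if (j == 0) next
    M[i, j] <- M[i, j] + 1
    M[j, i] <- M[j, i] + 1
  }
  M / sum(M)
}

# Run-length matrix for one direction by walking every line voxel-by-voxel.
oracle_glrlm <- function(lev, dir, ng) {
  d <- dim(lev)
  seen_start <- function(x, y, z) {
    px <- x - dir[1]; py <- y - dir[2]; pz <- z - dir[3]
    if (px < 1 || px > d[1] || py < 1 || py > d[2] || pz < 1 || pz > d[3]) return(TRUE)
    lev[px, py, pz] != lev[x, y, z]
  }
  runs <- list()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (lev[x, y, z] == 0 || !seen_start(x, y, z)) next
    l <- 0; cx <- x; cy <- y; cz <- z
    while (cx >= 1 && cx <= d[1] && cy >= 1 && cy <= d[2] && cz >= 1 && cz <= d[3] &&
           lev[cx, cy, cz] == lev[x, y, z]) {
      l <- l + 1; cx <- cx + dir[1]; cy <- cy + dir[2]; cz <- cz + dir[3]
    }
    runs[[length(runs) + 1]] <- c(lev[x, y, z], l)
  }
  maxl <- max(vapply(runs, `[`, 0, 2))
  R <- matrix(0, ng, maxl)
  for (r in runs) R[r[1], r[2]] <- R[r[1], r[2]] + 1
  R
}

# Size-zone matrix by recursive flood fill (26-connectivity).
oracle_glszm <- function(lev, ng) {
  d <- dim(lev)
  visited <- array(FALSE, d)
  zones <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (lev[x, y, z] == 0 || visited[x, y, z]) next
    val <- lev[x, y, z]
    stack <- list(c(x, y, z)); visited[x, y, z] <- TRUE; size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        nx <- v[1] + offs[r, 1]; nyy <- v[2] + offs[r, 2]; nz <- v[3] + offs[r, 3]
        if (nx < 1 || nx > d[1] || nyy < 1 || nyy > d[2] || nz < 1 || nz > d[3]) next
        if (!visited[nx, nyy, nz] && lev[nx, nyy, nz] == val) {
          visited[nx, nyy, nz] <- TRUE
          stack[[length(stack) + 1]] <- c(nx, nyy, nz)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(val, size)
  }
  maxs <- max(vapply(zones, `[`, 0, 2))
  Z <- matrix(0, ng, maxs)
  for (zn in zones) Z[zn[1], zn[2]] <- Z[zn[1], zn[2]] + 1
  Z
}

# Dependence matrix by per-voxel neighbour counting.
oracle_gldm <- function(lev, ng, alpha = 0) {
  d <- dim(lev)
  deps <- c()
  levs <- c()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (lev[x, y, z] == 0) next
    cnt <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nx <- x + dx; nyy <- y + dy; nz <- z + dz
      if (nx < 1 || nx > d[1] || nyy < 1 || nyy > d[2] || nz < 1 || nz > d[3]) next
      if (lev[nx, nyy, nz] > 0 && abs(lev[nx, nyy, nz] - lev[x, y, z]) <= alpha) {
        cnt <- cnt + 1
      }
    }
    deps <- c(deps, cnt); levs <- c(levs, lev[x, y, z])
  }
  D <- matrix(0, ng, max(deps) + 1)
  for (q in seq_along(deps)) D[levs[q], deps[q] + 1] <- D[levs[q], deps[q] + 1] + 1
  D
}

# AUC by exhaustive positive-negative pair counting with half tie credit.
oracle_auc <- function(scores, outcome) {
  pos <- scores[outcome == 1]; neg <- scores[outcome == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Fisher two-sided p for a 2x2 table by enumerating all tables with the
# same margins (point-probability criterion).
oracle_fisher_2x2 <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  p_of <- function(a) {
    stats::dhyper(a, rs[1], rs[2], cs[1])
  }
  p_obs <- p_of(tab[1, 1])
  tot <- 0
  for (a in max(0, cs[1] - rs[2]):min(rs[1], cs[1])) {
    if (p_of(a) <= p_obs * (1 + 1e-7)) tot <- tot + p_of(a)
  }
  tot
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_ <- sum_a * sum_b / choose(n, 2)
  (sum_ij - exp_) / ((sum_a + sum_b) / 2 - exp_)
}

# Small deterministic phantom cohort for reuse across tests.
tiny_cohort <- function(n = 4, seed = 11, rr = c(5, 8)) {
  generate_cohort(phantom_spec(n_patients = n, seed = seed,
                               tumor_radius_range = rr))
}
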