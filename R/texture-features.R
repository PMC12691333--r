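# Texture-matrix feature families. Each builder returns a named numeric
# vector; names are the bare feature names (family prefixes are added by
# extract_region). Matrix conventions:
#   * GLCM: symmetric, distance-1, the 13 unique 3D offsets, features
#     averaged over offsets.
#   * GLRLM: 13 directions, features averaged.
#   * GLSZM: zones are 26-connected equal-level components; single matrix.
#   * GLDM: dependence = number of 26-neighbours (in mask) within `alpha`
#     of the centre level; matrix indexed by (level, dependence count).
#   * NGTDM: 26-neighbour mean differences.
# Degenerate regions (single gray level) use documented sentinel values
# (e.g. GLCM Correlation -> 1) so feature tables stay rectangular.

EPS_LOG <- 1e-12

#' First-order intensity statistics
#'
#' The standard first-order radiomics set on the masked (optionally
#' filtered) intensities. Percentiles use the midpoint-interpolation
#' convention (R `quantile` type 5); kurtosis is the Fisher-Pearson moment
#' ratio m4/m2^2 (not excess); Entropy/Uniformity are computed on an
#' `n_bins` equal-width histogram of the region. A constant region has
#' variance 0 and undefined (NaN) skewness/kurtosis.
#'
#' @param image a `volume_image` or 3D array.
#' @param mask a `tumor_mask` or logical array.
#' @param n_bins histogram bins for Entropy/Uniformity.
#' @return named numeric vector of 18 features.
#' @export
firstorder_features <- function(image, mask, n_bins = 32L) {
  v <- if (inherits(image, "volume_image")) image$values else as.array(image)
  sp <- if (inherits(image, "volume_image")) image$spacing else c(1, 1, 1)
  m <- if (inherits(mask, "tumor_mask")) mask$labels > 0 else as.array(mask) > 0
  x <- v[m]
  n <- length(x)
  stopifnot(n >= 2)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 5, names = FALSE)
  robust <- x[x >= q[1] & x <= q[5]]
  rng <- range(x)
  p <- if (rng[2] > rng[1]) {
    tabulate(pmin(n_bins, floor((x - rng[1]) / ((rng[2] - rng[1]) / n_bins)) + 1L),
             n_bins) / n
  } else 1
  p <- p[p > 0]
  c(
    Energy = sum(x^2),
    TotalEnergy = prod(sp) * sum(x^2),
    Entropy = -sum(p * log2(p + EPS_LOG)),
    Minimum = rng[1],
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = rng[2],
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = rng[2] - rng[1],
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else NaN,
    Kurtosis = if (m2 > 0) m4 / m2^2 else NaN,
    Variance = m2,
    Uniformity = sum(p^2)
  )
}

# Build one symmetric normalized GLCM for an integer offset.
glcm_matrix <- function(disc, offset) {
  lev <- disc$levels
  ng <- disc$n_levels
  nb <- shift_array(lev, -offset[1], -offset[2], -offset[3], fill = 0L)
  ok <- lev > 0L & nb > 0L
  i <- lev[ok]; j <- nb[ok]
  if (length(i) == 0L) return(matrix(0, ng, ng))
  tab <- matrix(tabulate((j - 1L) * ng + i, ng * ng), ng, ng)
  tab <- tab + t(tab)
  tab / sum(tab)
}

glcm_features_one <- function(P, ng) {
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(i * P)        # == mean of marginal; symmetric so mu_x = mu_y
  sigma2 <- sum((i - mu)^2 * P)
  sigma <- sqrt(sigma2)
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), numeric(1))
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  HX <- -sum(px[px > 0] * log2(px[px > 0] + EPS_LOG))
  HXY <- -sum(P[P > 0] * log2(P[P > 0] + EPS_LOG))
  pxy <- outer(px, px)
  ok <- P > 0 & pxy > 0
  HXY1 <- -sum(P[ok] * log2(pxy[ok] + EPS_LOG))
  HXY2 <- -sum(pxy[pxy > 0] * log2(pxy[pxy > 0] + EPS_LOG))
  da <- sum(k_diff * p_diff)
  imc2arg <- 1 - exp(-2 * (HXY2 - HXY))
  c(
    Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = if (sigma2 > 0) (sum(i * j * P) - mu^2) / sigma2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(p_diff[p_diff > 0] * log2(p_diff[p_diff > 0] + EPS_LOG)),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = if (HX > 0) (HXY - HXY1) / HX else 0,
    Imc2 = if (imc2arg > 0) sqrt(imc2arg) else 0,
    InverseVariance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    JointAverage = mu,
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    MaximumProbability = max(P),
    SumEntropy = -sum(p_sum[p_sum > 0] * log2(p_sum[p_sum > 0] + EPS_LOG)),
    SumSquares = sigma2
  )
}

#' Gray-level co-occurrence features
#'
#' @param disc a [discretize()]d volume.
#' @return named numeric vector of 22 features, averaged over the 13 unique
#'   distance-1 3D offsets.
#' @export
glcm_features <- function(disc) {
  offs <- offsets13()
  feats <- vapply(seq_len(nrow(offs)), function(r) {
    glcm_features_one(glcm_matrix(disc, offs[r, ]), disc$n_levels)
  }, numeric(22))
  rowMeans(feats)
}

# Run-length matrix for one direction: R[level, run_length].
glrlm_matrix <- function(disc, dir) {
  lev <- disc$levels
  idx <- which(lev > 0L)
  co <- arrayInd(idx, dim(lev))
  n2 <- sum(dir^2)
  s <- as.integer(co %*% dir)
  key <- co * n2 - outer(s, dir)          # constant along a line, integer
  rng <- max(abs(key)) + 1
  base <- 2 * rng + 1
  keyid <- (key[, 1] * base + key[, 2]) * base + key[, 3]
  o <- order(keyid, s)
  ks <- keyid[o]; ss <- s[o]; ll <- lev[idx][o]
  newrun <- c(TRUE, ks[-1] != ks[-length(ks)] |
                ss[-1] != ss[-length(ss)] + n2 |
                ll[-1] != ll[-length(ll)])
  runid <- cumsum(newrun)
  rl <- tabulate(runid)
  rlev <- ll[newrun]
  maxl <- max(rl)
  ng <- disc$n_levels
  matrix(tabulate((rl - 1L) * ng + rlev, ng * maxl), ng, maxl)
}

rl_features_one <- function(R, np) {
  nr <- sum(R)
  i <- row(R); l <- col(R)
  p <- R / nr
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  gsum <- rowSums(R); lsum <- colSums(R)
  c(
    ShortRunEmphasis = sum(R / l^2) / nr,
    LongRunEmphasis = sum(R * l^2) / nr,
    GrayLevelNonUniformity = sum(gsum^2) / nr,
    GrayLevelNonUniformityNormalized = sum(gsum^2) / nr^2,
    RunLengthNonUniformity = sum(lsum^2) / nr,
    RunLengthNonUniformityNormalized = sum(lsum^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    RunVariance = sum((l - mu_l)^2 * p),
    RunEntropy = -sum(p[p > 0] * log2(p[p > 0] + EPS_LOG)),
    LowGrayLevelRunEmphasis = sum(R / i^2) / nr,
    HighGrayLevelRunEmphasis = sum(R * i^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(R / (i^2 * l^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(R * i^2 / l^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(R * l^2 / i^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(R * i^2 * l^2) / nr
  )
}

#' Gray-level run-length features
#'
#' @param disc a [discretize()]d volume.
#' @return named numeric vector of 16 features, averaged over 13 directions.
#' @export
glrlm_features <- function(disc) {
  np <- sum(disc$levels > 0)
  offs <- offsets13()
  feats <- vapply(seq_len(nrow(offs)), function(r) {
    rl_features_one(glrlm_matrix(disc, offs[r, ]), np)
  }, numeric(16))
  rowMeans(feats)
}

# Size-zone matrix: Z[level, zone_size] from 26-connected components.
glszm_matrix <- function(disc) {
  comp <- label_components26(disc$levels)
  idx <- which(comp > 0)
  sizes <- tabulate(comp[idx])
  zl <- disc$levels[idx][match(seq_along(sizes), comp[idx])]
  ng <- disc$n_levels
  maxs <- max(sizes)
  matrix(tabulate((sizes - 1L) * ng + zl, ng * maxs), ng, maxs)
}

#' Gray-level size-zone features
#'
#' @param disc a [discretize()]d volume.
#' @return named numeric vector of 16 features.
#' @export
glszm_features <- function(disc) {
  Z <- glszm_matrix(disc)
  np <- sum(disc$levels > 0)
  nz <- sum(Z)
  i <- row(Z); s <- col(Z)
  p <- Z / nz
  mu_i <- sum(i * p); mu_s <- sum(s * p)
  gsum <- rowSums(Z); ssum <- colSums(Z)
  c(
    SmallAreaEmphasis = sum(Z / s^2) / nz,
    LargeAreaEmphasis = sum(Z * s^2) / nz,
    GrayLevelNonUniformity = sum(gsum^2) / nz,
    GrayLevelNonUniformityNormalized = sum(gsum^2) / nz^2,
    SizeZoneNonUniformity = sum(ssum^2) / nz,
    SizeZoneNonUniformityNormalized = sum(ssum^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    ZoneVariance = sum((s - mu_s)^2 * p),
    ZoneEntropy = -sum(p[p > 0] * log2(p[p > 0] + EPS_LOG)),
    LowGrayLevelZoneEmphasis = sum(Z / i^2) / nz,
    HighGrayLevelZoneEmphasis = sum(Z * i^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(Z / (i^2 * s^2)) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(Z * i^2 / s^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(Z * s^2 / i^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(Z * i^2 * s^2) / nz
  )
}

# Dependence matrix: D[level, dependence+1]; dependence d = number of
# in-mask 26-neighbours whose level differs from the centre by <= alpha.
gldm_matrix <- function(disc, alpha = 0) {
  lev <- disc$levels
  dep <- array(0L, dim(lev))
  offs <- offsets26()
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nb <- shift_array(lev, -o[1], -o[2], -o[3], fill = 0L)
    dep <- dep + as.integer(lev > 0L & nb > 0L & abs(nb - lev) <= alpha)
  }
  ok <- lev > 0L
  ng <- disc$n_levels
  maxd <- max(dep[ok]) + 1L
  matrix(tabulate(dep[ok] * ng + lev[ok], ng * maxd), ng, maxd)
}

#' Gray-level dependence features
#'
#' The dependence count `d` of a voxel is the number of its in-mask
#' 26-neighbours within `alpha` gray levels of it (0..26); emphasis weights
#' use `d` itself, with `d = 0` rows contributing zero to the
#' dependence-weighted sums.
#'
#' @param disc a [discretize()]d volume.
#' @param alpha gray-level tolerance for dependence.
#' @return named numeric vector of 9 features.
#' @export
gldm_features <- function(disc, alpha = 0) {
  D <- gldm_matrix(disc, alpha)
  nd <- sum(D)
  i <- row(D); dcount <- col(D) - 1L
  p <- D / nd
  gsum <- rowSums(D); dsum <- colSums(D)
  inv_d2 <- ifelse(dcount > 0, 1 / dcount^2, 0)
  c(
    SmallDependenceEmphasis = sum(D * inv_d2) / nd,
    LargeDependenceEmphasis = sum(D * dcount^2) / nd,
    GrayLevelNonUniformity = sum(gsum^2) / nd,
    DependenceNonUniformity = sum(dsum^2) / nd,
    DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0] + EPS_LOG)),
    LowGrayLevelEmphasis = sum(D / i^2) / nd,
    HighGrayLevelEmphasis = sum(D * i^2) / nd,
    LargeDependenceLowGrayLevelEmphasis = sum(D * dcount^2 / i^2) / nd,
    LargeDependenceHighGrayLevelEmphasis = sum(D * dcount^2 * i^2) / nd
  )
}

# NGTDM columns: n_i, p_i, s_i per gray level.
ngtdm_table <- function(disc) {
  lev <- disc$levels
  m <- lev > 0L
  ind <- array(as.numeric(m), dim(lev))
  nb_sum <- box_sum3(array(as.numeric(lev) * ind, dim(lev)), 1) - as.numeric(lev) * ind
  nb_cnt <- box_sum3(ind, 1) - ind
  valid <- m & nb_cnt > 0
  A <- nb_sum[valid] / nb_cnt[valid]
  li <- lev[valid]
  ng <- disc$n_levels
  s <- vapply(seq_len(ng), function(i) sum(abs(i - A)[li == i]), numeric(1))
  n <- tabulate(li, ng)
  list(n = n, p = n / sum(n), s = s, np = sum(n), ng = ng)
}

#' Neighbouring gray-tone difference features
#'
#' @param disc a [discretize()]d volume.
#' @return named numeric vector: Coarseness, Contrast, Busyness, Complexity,
#'   Strength.
#' @export
ngtdm_features <- function(disc) {
  t <- ngtdm_table(disc)
  act <- which(t$p > 0)
  ngp <- length(act)
  ps <- sum(t$p * t$s)
  i <- act; pi_ <- t$p[act]; si <- t$s[act]
  contrast <- if (ngp > 1) {
    (sum(outer(pi_, pi_) * outer(i, i, "-")^2) / (ngp * (ngp - 1))) * (sum(t$s) / t$np)
  } else 0
  denom_busy <- sum(abs(outer(i * pi_, i * pi_, "-")))
  busyness <- if (denom_busy > 0) ps / denom_busy else 0
  cmplx <- if (t$np > 0 && ngp > 1) {
    sum(abs(outer(i, i, "-")) *
          (outer(pi_ * si, pi_ * si, "+")) / outer(pi_, pi_, "+")) / t$np
  } else 0
  strength <- if (sum(si) > 0) {
    sum(outer(pi_, pi_, "+") * outer(i, i, "-")^2) / sum(si)
  } else 0
  c(
    Coarseness = if (ps > 0) 1 / ps else 1e6,
    Contrast = contrast,
    Busyness = busyness,
    Complexity = cmplx,
    Strength = strength
  )
}

#' Voxel-based shape features
#'
#' Mesh-free approximations from the binary mask: voxel-count volume,
#' exposed-face surface area, derived sphericity/compactness, maximum 3D
#' diameter over boundary voxels, and principal-axis lengths from the
#' physical-coordinate covariance eigenvalues.
#'
#' @param mask a `tumor_mask`.
#' @return named numeric vector of 14 features.
#' @export
shape_features <- function(mask) {
  stopifnot(inherits(mask, "tumor_mask"))
  m <- mask$labels > 0
  sp <- mask$spacing
  n <- sum(m)
  vol <- n * prod(sp)
  area <- 0
  for (a in 1:3) {
    o <- c(0, 0, 0)
    face <- prod(sp) / sp[a]
    for (s in c(-1, 1)) {
      o[a] <- s
      exposed <- m & !shift_array(m, o[1], o[2], o[3], fill = FALSE)
      area <- area + sum(exposed) * face
      o[a] <- 0
    }
  }
  bnd <- which(boundary3(m))
  co <- sweep(arrayInd(bnd, dim(m)), 2, sp, "*")
  if (nrow(co) > 1500) {  # deterministic thinning for very large surfaces
    co <- co[seq(1, nrow(co), length.out = 1500), , drop = FALSE]
  }
  maxd <- if (nrow(co) > 1) {
    sq <- rowSums(co^2)
    sqrt(max(outer(sq, sq, "+") - 2 * tcrossprod(co)))
  } else 0
  all_co <- sweep(arrayInd(which(m), dim(m)), 2, sp, "*")
  ev <- if (n > 3) {
    sort(pmax(eigen(stats::cov(all_co), symmetric = TRUE, only.values = TRUE)$values, 0),
         decreasing = TRUE)
  } else c(0, 0, 0)
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  sph <- (pi^(1 / 3) * (6 * vol)^(2 / 3)) / area
  c(
    VoxelCount = n,
    VoxelVolume = vol,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / vol,
    Sphericity = sph,
    Compactness1 = vol / (sqrt(pi) * area^1.5),
    Compactness2 = 36 * pi * vol^2 / area^3,
    SphericalDisproportion = area / (4 * pi * r_eq^2),
    Maximum3DDiameter = maxd,
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  )
}
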