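mini_vol <- function(vals, dims = NULL) {
  if (is.null(dims)) dims <- dim(vals)
  volume_image(array(vals, dims))
}

full_mask <- function(dims) tumor_mask(array(1L, dims))

test_that("discretization: floor arithmetic, degenerate, loop oracle", {
  v <- mini_vol(c(0, 24, 25, 49, 0, 0, 0, 0), c(2, 2, 2))
  d <- discretize(v, full_mask(c(2, 2, 2)), "width", 25)
  expect_equal(d$levels[1:4], c(1L, 1L, 2L, 2L))

  cv <- mini_vol(rep(3, 8), c(2, 2, 2))
  dc <- discretize(cv, full_mask(c(2, 2, 2)), "count", 8)
  expect_equal(dc$n_levels, 1L)
  expect_true(dc$constant)
  expect_true(all(dc$levels == 1L))

  set.seed(5)
  vals <- array(rnorm(4^3, 100, 40), c(4, 4, 4))
  dr <- discretize(mini_vol(vals), full_mask(c(4, 4, 4)), "width", 10)
  mn <- min(vals)
  brute <- vapply(as.numeric(vals),
                  function(x) min(floor((x - mn) / 10) + 1, dr$n_levels), 1)
  expect_equal(as.integer(dr$levels), as.integer(brute))
})

test_that("LoG filter: affine kill, analytic Gaussian-blob response", {
  const <- log_filter(mini_vol(rep(4, 15^3), c(15, 15, 15)), 2)
  expect_lt(max(abs(const$values[4:12, 4:12, 4:12])), 1e-9)

  # interior = deeper than the smoothing-kernel reach (3 sigma + laplacian)
  ramp <- array(0, c(21, 21, 21))
  for (x in 1:21) ramp[x, , ] <- 3 * x
  lr <- log_filter(mini_vol(ramp), 1.5)
  expect_lt(max(abs(lr$values[8:14, 8:14, 8:14])), 1e-8)

  # Gaussian blob width s, filter sigma: peak = -3 A (s^2/(s^2+sig^2))^1.5 / (s^2+sig^2)
  dims <- c(33, 33, 33); ctr <- 17; s <- 4; sig <- 2; A <- 100
  g <- expand.grid(x = 1:33, y = 1:33, z = 1:33)
  r2 <- (g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2
  blob <- array(A * exp(-r2 / (2 * s^2)), dims)
  resp <- log_filter(mini_vol(blob), sig)$values[ctr, ctr, ctr]
  t2 <- s^2 + sig^2
  analytic <- -3 * A * (s^2 / t2)^1.5 / t2
  expect_lt(abs(resp - analytic) / abs(analytic), 0.02)
})

test_that("wavelet subbands: DC kill, impulse tensor product, Haar Parseval", {
  wb <- wavelet_decompose(mini_vol(rep(2.5, 8^3), c(8, 8, 8)))
  for (b in setdiff(names(wb), "LLL")) expect_lt(max(abs(wb[[b]])), 1e-10)

  # single impulse: subband = tensor product of the per-axis taps
  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  wb <- wavelet_decompose(mini_vol(imp))
  taps <- habikit:::wavelet_taps("coif1")
  off <- ceiling(length(taps$lo) / 2)
  conv_naive <- function(x, k) {
    n <- length(x); L <- length(k)
    out <- numeric(n)
    for (i in 1:n) for (j in 1:L) {
      src <- i + j - off
      while (src < 1 || src > n) src <- ifelse(src < 1, 1 - src, 2 * n + 1 - src)
      out[i] <- out[i] + k[j] * x[src]
    }
    out
  }
  band <- "LHH"  # z low, y high, x high
  expect_band <- imp
  for (ax in 1:3) {
    k <- if (substr(band, 4 - ax, 4 - ax) == "L") taps$lo else taps$hi
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    b <- aperm(expect_band, perm)
    for (j in seq_len(15)) for (l in seq_len(15)) b[, j, l] <- conv_naive(b[, j, l], k)
    expect_band <- aperm(b, order(perm))
  }
  expect_equal(wb[[band]], expect_band, tolerance = 1e-12)

  # orthonormal decimated Haar conserves energy
  set.seed(6)
  x <- array(rnorm(8^3), c(8, 8, 8))
  wd <- wavelet_decompose(mini_vol(x), wavelet = "haar", decimated = TRUE)
  expect_equal(sum(vapply(wd, function(b) sum(b^2), 1)), sum(x^2),
               tolerance = 1e-8)
})

test_that("first-order features: percentile convention, moments, degenerate", {
  v <- mini_vol(as.numeric(1:100), c(100, 1, 1))
  f <- firstorder_features(v, full_mask(c(100, 1, 1)))
  expect_equal(unname(f["InterquartileRange"]), 50)
  expect_equal(unname(f["Median"]), 50.5)
  expect_equal(unname(f["Energy"]), sum((1:100)^2))

  fc <- firstorder_features(mini_vol(rep(9, 27), c(3, 3, 3)), full_mask(c(3, 3, 3)))
  expect_equal(unname(fc["Variance"]), 0)
  expect_true(is.nan(fc["Kurtosis"]))

  set.seed(11)
  z <- rnorm(40000)
  fz <- firstorder_features(mini_vol(z, c(40000, 1, 1)), full_mask(c(40000, 1, 1)))
  expect_lt(abs(fz["Kurtosis"] - 3), 0.15)   # non-excess convention
  expect_lt(abs(fz["Skewness"]), 0.1)
})

test_that("GLCM: degenerate level, hand-enumerated checkerboard, symmetry", {
  d1 <- discretize(mini_vol(rep(5, 27), c(3, 3, 3)), full_mask(c(3, 3, 3)), "width", 25)
  g1 <- glcm_features(d1)
  expect_equal(unname(g1["Idn"]), 1)
  expect_equal(unname(g1["Correlation"]), 1)

  # 4x4 checkerboard of levels 1/2, horizontal offset (1,0,0):
  # every horizontal pair is (1,2) or (2,1): P = [[0,.5],[.5,0]]
  cb <- array(0, c(4, 4, 1))
  for (x in 1:4) for (y in 1:4) cb[x, y, 1] <- (x + y) %% 2
  db <- discretize(mini_vol(cb * 25), full_mask(c(4, 4, 1)), "width", 25)
  M <- habikit:::glcm_matrix(db, c(1, 0, 0))
  expect_equal(M, matrix(c(0, .5, .5, 0), 2))
  fb <- habikit:::glcm_features_one(M, 2)
  # hand: mu = 1.5, sigma2 = .25, sum ij p = 2 -> corr = (2 - 2.25)/.25 = -1
  expect_equal(unname(fb["Correlation"]), -1)
  expect_equal(unname(fb["Idn"]), 1 / (1 + 1 / 2))
  # ClusterProminence: (i+j-3)^4 = 0 for both cells
  expect_equal(unname(fb["ClusterProminence"]), 0)
  expect_equal(unname(fb["Contrast"]), 1)

  # matrix equals the brute-force pair enumeration on a random volume
  set.seed(12)
  rv <- array(sample(0:75, 5^3, replace = TRUE), c(5, 5, 5))
  m <- array(runif(5^3) < 0.8, c(5, 5, 5)); m[1] <- TRUE
  dd <- discretize(mini_vol(rv), tumor_mask(m + 0L), "width", 25)
  for (off in list(c(1, 0, 0), c(0, 1, 1), c(-1, 1, 1))) {
    expect_equal(habikit:::glcm_matrix(dd, off),
                 oracle_glcm(dd$levels, off, dd$n_levels), tolerance = 1e-12)
  }
  # symmetry of the construction
  M1 <- habikit:::glcm_matrix(dd, c(1, -1, 0))
  expect_equal(M1, t(M1))
})

test_that("GLRLM: hand-enumerated runs and matrix oracle", {
  row <- mini_vol(c(1, 1, 2, 2, 2) * 30, c(5, 1, 1))
  dr <- discretize(row, full_mask(c(5, 1, 1)), "width", 25)
  R <- habikit:::glrlm_matrix(dr, c(1, 0, 0))
  expect_equal(R[1, 2], 1)   # run (level 1, length 2)
  expect_equal(R[2, 3], 1)   # run (level 2, length 3)
  expect_equal(sum(R), 2)
  f <- habikit:::rl_features_one(R, 5)
  expect_equal(unname(f["ShortRunLowGrayLevelEmphasis"]),
               (1 / (1 * 4) + 1 / (4 * 9)) / 2)

  cvol <- discretize(mini_vol(rep(7, 27), c(3, 3, 3)), full_mask(c(3, 3, 3)), "width", 25)
  Rc <- habikit:::glrlm_matrix(cvol, c(0, 0, 1))
  fc <- habikit:::rl_features_one(Rc, 27)
  expect_equal(unname(fc["GrayLevelNonUniformityNormalized"]), 1)

  set.seed(13)
  rv <- array(sample(0:60, 4^3, replace = TRUE), c(4, 4, 4))
  m <- array(runif(4^3) < 0.75, c(4, 4, 4)); m[1] <- TRUE
  dd <- discretize(mini_vol(rv), tumor_mask(m + 0L), "width", 20)
  offs <- habikit:::offsets13()
  for (r in seq_len(nrow(offs))) {
    R1 <- habikit:::glrlm_matrix(dd, offs[r, ])
    R2 <- oracle_glrlm(dd$levels, offs[r, ], dd$n_levels)
    expect_equal(unname(R1[, seq_len(ncol(R2))]), unname(R2), tolerance = 1e-12)
    expect_equal(sum(col(R1) * R1), sum(dd$levels > 0))  # conservation
  }
})

test_that("GLSZM: hand-enumerated zones, constants, flood-fill oracle", {
  # [1,1,2,2,2]: one zone of level 1 size 2, one of level 2 size 3
  dz <- discretize(mini_vol(c(1, 1, 2, 2, 2) * 30, c(5, 1, 1)),
                   full_mask(c(5, 1, 1)), "width", 25)
  f <- glszm_features(dz)
  expect_equal(unname(f["SizeZoneNonUniformityNormalized"]), (1 + 1) / 4)
  expect_equal(unname(f["SmallAreaHighGrayLevelEmphasis"]),
               (1 * 1 / 4 + 1 * 4 / 9) / 2)
  expect_equal(unname(f["LargeAreaLowGrayLevelEmphasis"]),
               (1 * 4 / 1 + 1 * 9 / 4) / 2)

  dc <- discretize(mini_vol(rep(2, 27), c(3, 3, 3)), full_mask(c(3, 3, 3)), "width", 25)
  expect_equal(unname(glszm_features(dc)["SizeZoneNonUniformityNormalized"]), 1)

  set.seed(14)
  rv <- array(sample(c(0, 30, 60), 5^3, replace = TRUE, prob = c(.2, .4, .4)), c(5, 5, 5))
  m <- array(runif(5^3) < 0.8, c(5, 5, 5)); m[2, 2, 2] <- TRUE
  dd <- discretize(mini_vol(rv), tumor_mask(m + 0L), "width", 25)
  Z1 <- habikit:::glszm_matrix(dd)
  Z2 <- oracle_glszm(dd$levels, dd$n_levels)
  expect_equal(unname(Z1[, seq_len(ncol(Z2))]), unname(Z2))
  expect_equal(sum(col(Z1) * Z1), sum(dd$levels > 0))
})

test_that("GLDM: constant-volume dependence, brute-force matrix", {
  dc <- discretize(mini_vol(rep(4, 27), c(3, 3, 3)), full_mask(c(3, 3, 3)), "width", 25)
  D <- habikit:::gldm_matrix(dc, 0)
  expect_equal(D[1, 27], 1)  # centre voxel: dependence 26 -> column 27
  expect_equal(sum(D), 27)

  set.seed(15)
  rv <- array(sample(c(10, 40), 4^3, replace = TRUE), c(4, 4, 4))
  m <- array(runif(4^3) < 0.8, c(4, 4, 4)); m[1] <- TRUE
  dd <- discretize(mini_vol(rv), tumor_mask(m + 0L), "width", 25)
  D1 <- habikit:::gldm_matrix(dd, 0)
  D2 <- oracle_gldm(dd$levels, dd$n_levels, 0)
  expect_equal(unname(D1[, seq_len(ncol(D2))]), unname(D2))
  expect_equal(sum(D1), sum(dd$levels > 0))
})

test_that("NGTDM: constant contrast, hand-computed s_i, coarseness ordering", {
  dc <- discretize(mini_vol(rep(4, 27), c(3, 3, 3)), full_mask(c(3, 3, 3)), "width", 25)
  expect_equal(unname(ngtdm_features(dc)["Contrast"]), 0)

  # 2-voxel toy: [1,2] along x; each voxel's only neighbour is the other
  dt <- discretize(mini_vol(c(0, 30), c(2, 1, 1)), full_mask(c(2, 1, 1)), "width", 25)
  t <- habikit:::ngtdm_table(dt)
  expect_equal(t$s, c(1, 1))  # |1-2| and |2-1|

  # coarseness: fine checkerboard < large blocks
  cb <- array(0, c(6, 6, 6))
  for (x in 1:6) for (y in 1:6) for (z in 1:6) cb[x, y, z] <- (x + y + z) %% 2
  blocks <- array(0, c(6, 6, 6)); blocks[4:6, , ] <- 1
  dcb <- discretize(mini_vol(cb * 30), full_mask(c(6, 6, 6)), "width", 25)
  dbl <- discretize(mini_vol(blocks * 30), full_mask(c(6, 6, 6)), "width", 25)
  expect_lt(ngtdm_features(dcb)["Coarseness"], ngtdm_features(dbl)["Coarseness"])
})

test_that("shape features: cube volume, digital-ball sphericity bound", {
  f <- shape_features(tumor_mask(array(1, c(10, 10, 10))))
  expect_equal(unname(f["VoxelVolume"]), 1000)
  expect_equal(unname(f["SurfaceArea"]), 600)

  d <- c(23, 23, 23); ctr <- 12
  g <- expand.grid(x = 1:23, y = 1:23, z = 1:23)
  ball <- array((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= 100, d)
  fb <- shape_features(tumor_mask(ball))
  expect_lt(abs(fb["Sphericity"] - 1), 0.35)   # staircase surface bias
  expect_equal(unname(fb["VoxelCount"]), sum(ball))

  set.seed(16)
  for (i in 1:5) {
    m <- array(runif(6^3) < 0.5, c(6, 6, 6)); m[1] <- TRUE
    fs <- shape_features(tumor_mask(m + 0L))
    expect_lte(unname(fs["Sphericity"]), 1.01)
  }
  expect_equal(unname(fb["Elongation"]), 1, tolerance = 0.05)
})

test_that("extract_region resolves every published model feature name", {
  man <- default_manifest()
  expect_equal(man$total_per_region, 1218)
  all_names <- c(
    paste0("original_shape_", man$shape),
    unlist(lapply(man$filters, function(f) {
      unlist(lapply(names(man$families), function(fam) {
        paste0(f, "_", fam, "_", man$families[[fam]])
      }))
    }))
  )
  expect_equal(length(all_names), 1218)
  expect_false(any(duplicated(all_names)))
  voi <- radscore_fixture("paper_voi")
  sub <- radscore_fixture("paper_sub")
  stripped <- sub("^Sub[0-9]+_", "", names(sub$coefficients))
  expect_true(all(names(voi$coefficients) %in% all_names))
  expect_true(all(stripped %in% all_names))
})

test_that("small-manifest extraction returns the declared count and prefixes", {
  coh <- tiny_cohort(n = 1, seed = 41, rr = c(5, 6))
  p <- coh$patients[[1]]
  man <- small_manifest()
  fv <- extract_region(p$image, p$mask, man)
  expect_equal(length(fv), man$total_per_region)
  expect_false(any(duplicated(names(fv))))
  fv2 <- extract_region(p$image, p$mask, man, prefix = "Sub2_")
  expect_true(all(startsWith(names(fv2), "Sub2_")))
  # shape depends on the mask only: identical across prefixes
  expect_equal(unname(fv2["Sub2_original_shape_VoxelVolume"]),
               unname(fv["original_shape_VoxelVolume"]))
})
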