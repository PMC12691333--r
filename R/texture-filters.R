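#' Gray-level discretization of a masked volume
#'
#' Maps masked intensities to integer levels `1..n_levels`, either with a
#' fixed bin width (`level = floor((I - min)/width) + 1`, the convention for
#' calibrated HU) or a fixed bin count (for filtered volumes whose scale is
#' not physically meaningful). A constant region under either rule yields a
#' single level and is flagged.
#'
#' @param image a `volume_image`, or a bare 3D numeric array.
#' @param mask a `tumor_mask` (or logical/0-1 array) on the same grid.
#' @param method `"width"` or `"count"`.
#' @param value the bin width (HU) or the bin count (>= 2).
#' @return a `discretized_volume`: `levels` (integer array, 0 outside mask),
#'   `n_levels`, `mask` (logical array), `spacing`, `constant` flag.
#' @export
discretize <- function(image, mask, method = c("width", "count"), value = 25) {
  method <- match.arg(method)
  v <- if (inherits(image, "volume_image")) image$values else as.array(image)
  spacing <- if (inherits(image, "volume_image")) image$spacing else c(1, 1, 1)
  m <- if (inherits(mask, "tumor_mask")) mask$labels > 0 else as.array(mask) > 0
  stopifnot(identical(dim(v), dim(m)), any(m))
  x <- v[m]
  rng <- range(x)
  constant <- rng[2] - rng[1] <= 0
  lev <- array(0L, dim(v))
  if (constant) {
    lev[m] <- 1L
    ng <- 1L
  } else if (method == "width") {
    stopifnot(value > 0)
    li <- floor((x - rng[1]) / value) + 1
    ng <- as.integer(floor((rng[2] - rng[1]) / value) + 1)
    lev[m] <- as.integer(pmin(li, ng))
  } else {
    stopifnot(value >= 2)
    w <- (rng[2] - rng[1]) / value
    lev[m] <- as.integer(pmin(value, floor((x - rng[1]) / w) + 1))
    ng <- as.integer(value)
  }
  structure(list(levels = lev, n_levels = ng, mask = m, spacing = spacing,
                 constant = constant),
            class = "discretized_volume")
}

#' Laplacian-of-Gaussian filter at a physical scale
#'
#' Separable Gaussian smoothing at `sigma_mm` (converted to voxel units via
#' the spacing) followed by the spacing-aware discrete Laplacian. Band-pass
#' response emphasizing blob-like structure at scale sigma.
#'
#' @param image a `volume_image`.
#' @param sigma_mm Gaussian scale in mm.
#' @return a `volume_image` of the filter response.
#' @export
log_filter <- function(image, sigma_mm) {
  stopifnot(inherits(image, "volume_image"), sigma_mm > 0)
  sp <- image$spacing
  if (sigma_mm < min(sp) / 2) {
    warning("LoG sigma ", sigma_mm, " mm is below half the voxel spacing; ",
            "response is resolution-limited")
  }
  sm <- gauss_smooth3(image$values, sigma_mm / sp)
  lap <- sep_filter3(sm, kx = c(1, -2, 1) / sp[1]^2, ky = 1, kz = 1) +
    sep_filter3(sm, kx = 1, ky = c(1, -2, 1) / sp[2]^2, kz = 1) +
    sep_filter3(sm, kx = 1, ky = 1, kz = c(1, -2, 1) / sp[3]^2)
  volume_image(lap, sp, image$origin, image$direction)
}

wavelet_taps <- function(wavelet = c("coif1", "haar")) {
  wavelet <- match.arg(wavelet)
  lo <- switch(wavelet,
    coif1 = c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
              0.852572020212255, 0.337897662457809, -0.072732619512854),
    haar = c(1, 1) / sqrt(2)
  )
  n <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1)
  list(lo = lo, hi = hi)
}

# 1D correlation with symmetric (half-sample) padding, arbitrary kernel
# length, output aligned so tap `offset` sits on the current sample.
conv1d_sym <- function(x, k, offset) {
  n <- length(x)
  L <- length(k)
  pl <- offset - 1L
  pr <- L - offset
  pad_idx <- function(i) {
    # symmetric (reflect including edge) index into 1..n
    i <- ((i - 1) %% (2 * n))
    ifelse(i < n, i + 1, 2 * n - i)
  }
  idx <- pad_idx(seq(1 - pl, n + pr))
  xp <- x[idx]
  out <- numeric(n)
  for (j in seq_len(L)) out <- out + k[j] * xp[seq_len(n) + (j - 1L)]
  out
}

apply_axis <- function(a, fun, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  b <- aperm(a, perm)
  db <- dim(b)
  m <- matrix(b, nrow = db[1])
  m <- apply(m, 2, fun)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  dim(m) <- c(nrow(m), db[2], db[3])  # first dim may shrink (decimated mode)
  aperm(m, order(perm))
}

#' One-level 3D wavelet decomposition into 8 subbands
#'
#' Separable stationary (undecimated) wavelet transform; each subband name
#' has three letters giving the low(L)/high(H)-pass filter applied along the
#' (z, y, x) axes, in that order, so e.g. `LHH` is low-pass in z and
#' high-pass in y and x. Default wavelet is Coiflet-1 with symmetric
#' boundary padding. `decimated = TRUE` (Haar only) gives the orthonormal
#' decimated transform, for which subband energies sum to the input energy.
#'
#' @param image a `volume_image` (or 3D array).
#' @param wavelet `"coif1"` (default) or `"haar"`.
#' @param decimated use the decimated orthonormal transform (requires even
#'   dimensions; Haar only).
#' @return named list of 8 arrays: `LLL`, `LLH`, `LHL`, `LHH`, `HLL`, `HLH`,
#'   `HHL`, `HHH`.
#' @export
wavelet_decompose <- function(image, wavelet = c("coif1", "haar"),
                              decimated = FALSE) {
  wavelet <- match.arg(wavelet)
  a <- if (inherits(image, "volume_image")) image$values else as.array(image)
  stopifnot(all(dim(a) >= 2))
  taps <- wavelet_taps(wavelet)
  if (decimated) {
    if (wavelet != "haar") stop("decimated mode is implemented for haar only", call. = FALSE)
    if (any(dim(a) %% 2 != 0)) stop("decimated transform requires even dimensions", call. = FALSE)
    lo1 <- function(x) (x[seq(1, length(x), 2)] + x[seq(2, length(x), 2)]) / sqrt(2)
    hi1 <- function(x) (x[seq(1, length(x), 2)] - x[seq(2, length(x), 2)]) / sqrt(2)
    filt <- list(L = lo1, H = hi1)
  } else {
    off <- ceiling(length(taps$lo) / 2)
    filt <- list(L = function(x) conv1d_sym(x, taps$lo, off),
                 H = function(x) conv1d_sym(x, taps$hi, off))
  }
  out <- list()
  for (lz in c("L", "H")) {
    az <- apply_axis(a, filt[[lz]], 3L)
    for (ly in c("L", "H")) {
      ay <- apply_axis(az, filt[[ly]], 2L)
      for (lx in c("L", "H")) {
        out[[paste0(lz, ly, lx)]] <- apply_axis(ay, filt[[lx]], 1L)
      }
    }
  }
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}
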