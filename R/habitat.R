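#' Per-voxel intensity/entropy feature map
#'
#' For every tumor voxel, computes its HU intensity and the Shannon entropy
#' (base 2) of the gray-level histogram over a cubic neighbourhood of radius
#' `window`, intersected with the mask. Histogram bins are fixed per patient
#' over the masked HU range. These two per-voxel features are the input to
#' population-level habitat clustering.
#'
#' Entropy is \eqn{H = -\sum_i p_i \log_2(p_i + \epsilon)} over the `n_bins`
#' occupancy probabilities; `eps` guards empty bins, so a constant
#' neighbourhood yields \eqn{|H| \le |\log_2(1+\epsilon)|} rather than NaN.
#'
#' @param image a `volume_image`.
#' @param mask a `tumor_mask` on the same grid.
#' @param window neighbourhood radius in voxels (>= 1).
#' @param n_bins number of gray-level bins (>= 2).
#' @param eps entropy guard added inside the logarithm.
#' @param per_slice if `TRUE`, use a 2D in-plane (x-y) neighbourhood per
#'   slice instead of the 3D cube.
#' @return tibble with one row per mask voxel: `idx` (linear array index),
#'   `intensity`, `entropy`, and `low_support` (fewer than 2 neighbourhood
#'   voxels; entropy set to 0). Grid dimensions are kept in attribute `dim`.
#' @export
entropy_map <- function(image, mask, window = 1L, n_bins = 32L, eps = 1e-12,
                        per_slice = FALSE) {
  stopifnot(window >= 1, n_bins >= 2, eps > 0)
  check_grid_match(image, mask)
  m <- mask$labels > 0
  v <- image$values
  idx <- which(m)
  rng <- range(v[idx])
  w <- (rng[2] - rng[1]) / n_bins
  bin <- array(1L, dim(v))
  if (w > 0) {
    bin[idx] <- pmin(n_bins, floor((v[idx] - rng[1]) / w) + 1L)
  }
  r <- if (per_slice) c(window, window, 0L) else rep(window, 3L)
  total <- box_sum3(array(as.numeric(m), dim(v)), r)
  H <- array(0, dim(v))
  for (b in seq_len(n_bins)) {
    ind <- array(as.numeric(m & bin == b), dim(v))
    cnt <- box_sum3(ind, r)
    p <- ifelse(total > 0, cnt / total, 0)
    H <- H - p * log2(p + eps)
  }
  low <- total[idx] < 2
  ent <- H[idx]
  ent[low] <- 0
  out <- tibble::tibble(idx = idx, intensity = v[idx], entropy = ent,
                        low_support = low)
  attr(out, "grid_dim") <- dim(v)
  attr(out, "entropy_params") <- list(window = window, n_bins = n_bins,
                                      eps = eps, per_slice = per_slice)
  out
}

#' Pool and standardize voxel features across a cohort
#'
#' Stacks per-patient (intensity, entropy) voxel features and z-standardizes
#' each column with the pooled mean and SD. The standardization parameters
#' are stored so that held-out patients can be projected with the training
#' parameters (never their own) via [standardize_voxels()].
#'
#' @param maps named list of [entropy_map()] tibbles (names = patient ids).
#' @return a `pooled_voxels` object: `$features` tibble
#'   (`patient`, `idx`, `intensity`, `entropy`, `intensity_z`, `entropy_z`),
#'   `$center`, `$scale`.
#' @export
pool_cohort_features <- function(maps) {
  stopifnot(length(maps) >= 1)
  if (is.null(names(maps))) names(maps) <- paste0("P", seq_along(maps))
  feats <- dplyr::bind_rows(maps, .id = "patient")
  for (col in c("intensity", "entropy")) {
    if (stats::sd(feats[[col]]) < 1e-12) {
      stop("zero-variance pooled feature column: ", col, call. = FALSE)
    }
  }
  center <- c(intensity = mean(feats$intensity), entropy = mean(feats$entropy))
  scale <- c(intensity = stats::sd(feats$intensity), entropy = stats::sd(feats$entropy))
  feats$intensity_z <- (feats$intensity - center["intensity"]) / scale["intensity"]
  feats$entropy_z <- (feats$entropy - center["entropy"]) / scale["entropy"]
  structure(list(features = feats, center = center, scale = scale),
            class = "pooled_voxels")
}

#' @param pooled a `pooled_voxels` object holding training parameters.
#' @rdname pool_cohort_features
#' @export
standardize_voxels <- function(pooled, maps) {
  stopifnot(inherits(pooled, "pooled_voxels"))
  if (is.null(names(maps))) names(maps) <- paste0("V", seq_along(maps))
  feats <- dplyr::bind_rows(maps, .id = "patient")
  feats$intensity_z <- (feats$intensity - pooled$center["intensity"]) / pooled$scale["intensity"]
  feats$entropy_z <- (feats$entropy - pooled$center["entropy"]) / pooled$scale["entropy"]
  feats
}

voxel_matrix <- function(x) {
  if (inherits(x, "pooled_voxels")) x <- x$features
  if (is.data.frame(x)) {
    as.matrix(x[, c("intensity_z", "entropy_z")])
  } else {
    as.matrix(x)
  }
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k)[-1]) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

dist2_to_centers <- function(x, centers) {
  # squared Euclidean distances, n x k
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, "+") - 2 * x %*% t(centers)
  pmax(d2, 0)
}

#' K-means clustering of pooled voxel features
#'
#' Lloyd's algorithm with Euclidean distance and k-means++ initialization,
#' keeping the best of `n_init` restarts by within-cluster sum of squares
#' (inertia). Deterministic under a fixed seed. An update that empties a
#' cluster re-seeds its centroid at the point farthest from its assigned
#' centroid. Inertia is asserted non-increasing across Lloyd iterations.
#'
#' @param x a `pooled_voxels` object, a feature tibble, or a numeric matrix.
#' @param k number of clusters (>= 2).
#' @param seed integer seed.
#' @param n_init restarts.
#' @param max_iter,tol Lloyd iteration controls.
#' @return a `habitat_clustering`: `centroids` (k x 2, standardized space),
#'   `cluster` (per-row assignment 1..k), `inertia`, `inertia_trace`, `k`.
#' @export
kmeans_cluster <- function(x, k, seed = 1L, n_init = 10L, max_iter = 100L,
                           tol = 1e-8) {
  xm <- voxel_matrix(x)
  stopifnot(k >= 2, nrow(xm) >= k)
  set.seed(seed)
  best <- NULL
  for (init in seq_len(n_init)) {
    centers <- kmeanspp_init(xm, k)
    trace <- numeric()
    prev <- Inf
    for (it in seq_len(max_iter)) {
      d2 <- dist2_to_centers(xm, centers)
      assign <- max.col(-d2, ties.method = "first")
      sizes <- tabulate(assign, k)
      if (any(sizes == 0L)) {
        # re-seed each emptied centroid at the point farthest from its
        # assigned centroid (never increases inertia)
        ord <- order(d2[cbind(seq_len(nrow(xm)), assign)], decreasing = TRUE)
        empties <- which(sizes == 0L)
        for (j in seq_along(empties)) {
          centers[empties[j], ] <- xm[ord[j], ]
        }
        d2 <- dist2_to_centers(xm, centers)
        assign <- max.col(-d2, ties.method = "first")
      }
      inertia <- sum(d2[cbind(seq_len(nrow(xm)), assign)])
      trace <- c(trace, inertia)
      for (j in seq_len(k)) {
        if (any(assign == j)) {
          centers[j, ] <- colMeans(xm[assign == j, , drop = FALSE])
        }
      }
      if (prev - inertia < tol * max(1, prev)) break
      prev <- inertia
    }
    d2 <- dist2_to_centers(xm, centers)
    assign <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_len(nrow(xm)), assign)])
    trace <- c(trace, inertia)
    if (any(diff(trace) > 1e-6 * max(1, trace[1]))) {
      stop("internal error: inertia increased across Lloyd iterations", call. = FALSE)
    }
    if (is.null(best) || inertia < best$inertia) {
      best <- list(centroids = centers, cluster = assign, inertia = inertia,
                   inertia_trace = trace)
    }
  }
  structure(c(best, list(k = as.integer(k), seed = as.integer(seed))),
            class = "habitat_clustering")
}

#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster dispersion,
#' \eqn{CH = [B/(k-1)] / [W/(n-k)]}, with dispersions measured as traces of
#' the scatter about cluster centroids and the grand mean. Zero
#' within-dispersion returns `Inf`.
#'
#' @param x feature matrix / tibble / `pooled_voxels`.
#' @param cluster integer assignments 1..k.
#' @return the CH value (scalar).
#' @export
calinski_harabasz <- function(x, cluster) {
  xm <- voxel_matrix(x)
  k <- length(unique(cluster))
  n <- nrow(xm)
  stopifnot(k >= 2, n >= k)
  grand <- colMeans(xm)
  W <- 0; B <- 0
  for (j in sort(unique(cluster))) {
    xj <- xm[cluster == j, , drop = FALSE]
    cj <- colMeans(xj)
    W <- W + sum(sweep(xj, 2, cj)^2)
    B <- B + nrow(xj) * sum((cj - grand)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Select the habitat count by the Calinski-Harabasz criterion
#'
#' Runs [kmeans_cluster()] for every `k` in `k_range` and returns the `k`
#' maximizing the CH index; ties break toward smaller `k`.
#'
#' @inheritParams kmeans_cluster
#' @param k_range candidate cluster counts (subset of 2..10).
#' @return list: `k_star`, `ch_by_k` (tibble `k`, `ch`, `inertia`),
#'   `clusterings` (one `habitat_clustering` per k).
#' @export
select_k <- function(x, k_range = 2:6, seed = 1L, n_init = 10L) {
  stopifnot(all(k_range >= 2), all(k_range <= 10))
  xm <- voxel_matrix(x)
  fits <- lapply(k_range, function(k) kmeans_cluster(xm, k, seed = seed + k, n_init = n_init))
  ch <- vapply(fits, function(f) calinski_harabasz(xm, f$cluster), numeric(1))
  tab <- tibble::tibble(k = as.integer(k_range), ch = ch,
                        inertia = vapply(fits, `[[`, numeric(1), "inertia"))
  k_star <- tab$k[which.max(tab$ch)]  # which.max takes the first (smallest k) on ties
  list(k_star = k_star, ch_by_k = tab,
       clusterings = stats::setNames(fits, paste0("k", k_range)))
}

#' Habitat label maps from a fitted clustering
#'
#' Writes each voxel's cluster id back into patient-space label volumes, with
#' habitat ids renumbered cohort-wide by ascending centroid mean intensity so
#' that "Sub1" (lowest attenuation) is stable across runs regardless of the
#' arbitrary k-means cluster numbering.
#'
#' @param clustering a `habitat_clustering` fitted on pooled voxels.
#' @param features the pooled feature tibble the clustering was fitted on
#'   (or a `pooled_voxels`), carrying `patient` and `idx` columns.
#' @param masks named list of `tumor_mask` objects (names = patient ids).
#' @param assignments per-row cluster ids for the rows of `features`;
#'   defaults to the clustering's own assignments (pass the `cluster` column
#'   from [assign_to_centroids()] for held-out patients).
#' @return named list of `habitat_map` objects (`$labels` 0-background /
#'   1..k integer array, `$k`, grid fields).
#' @export
label_habitats <- function(clustering, features, masks, assignments = NULL) {
  feats <- if (inherits(features, "pooled_voxels")) features$features else features
  k <- clustering$k
  ord <- order(clustering$centroids[, 1])       # ascending intensity (standardized)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  lab <- relabel[assignments %||% clustering$cluster]
  out <- lapply(names(masks), function(pid) {
    sel <- feats$patient == pid
    mk <- masks[[pid]]
    arr <- array(0L, dim(mk$labels))
    arr[feats$idx[sel]] <- lab[sel]
    if (!identical(which(arr > 0), which(mk$labels > 0))) {
      stop("habitat map does not cover the mask for patient ", pid, call. = FALSE)
    }
    structure(list(labels = arr, k = k, spacing = mk$spacing,
                   origin = mk$origin, direction = mk$direction),
              class = "habitat_map")
  })
  stats::setNames(out, names(masks))
}

#' @export
print.habitat_map <- function(x, ...) {
  cat("<habitat_map> k =", x$k, "habitats,", sum(x$labels > 0), "tumor voxels\n")
  invisible(x)
}

#' Assign held-out voxels to frozen training centroids
#'
#' @param clustering a `habitat_clustering` from the training cohort.
#' @param features standardized held-out voxel tibble from
#'   [standardize_voxels()] (training standardization, frozen centroids: no
#'   information flows from validation to the clustering).
#' @return the tibble with a `cluster` column appended.
#' @export
assign_to_centroids <- function(clustering, features) {
  xm <- voxel_matrix(features)
  d2 <- dist2_to_centers(xm, clustering$centroids)
  dplyr::mutate(features, cluster = max.col(-d2, ties.method = "first"))
}
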