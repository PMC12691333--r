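#' Feature manifests: which filters x families x features to extract
#'
#' A manifest declares the image filter bank, the per-family feature lists,
#' the shape feature list and the discretization rules. The shipped default
#' (`default_manifest()`, loaded from the versioned JSON under
#' `inst/extdata/`) totals exactly 1218 features per region: 14 shape
#' features plus 14 filtered images (original, 5 LoG scales, 8 wavelet
#' subbands) x 86 intensity/texture features.
#'
#' @param filters character vector of filter names (`"original"`,
#'   `"log.sigma.<s>.0.mm.3D"`, `"wavelet.<BBB>"`).
#' @param families named list of per-family feature-name vectors.
#' @param shape character vector of shape feature names.
#' @param disc_original,disc_filtered discretization rules,
#'   `list(method =, value =)`.
#' @return a `feature_manifest` with a computed `total_per_region`.
#' @export
feature_manifest <- function(filters, families, shape,
                             disc_original = list(method = "width", value = 25),
                             disc_filtered = list(method = "count", value = 32)) {
  total <- length(shape) + length(filters) * sum(lengths(families))
  structure(list(filters = filters, families = families, shape = shape,
                 disc_original = disc_original, disc_filtered = disc_filtered,
                 total_per_region = total),
            class = "feature_manifest")
}

#' @rdname feature_manifest
#' @export
default_manifest <- function() {
  path <- system.file("extdata", "manifest-default.json", package = "habikit")
  read_manifest(path)
}

#' @param path path to a manifest JSON file.
#' @rdname feature_manifest
#' @export
read_manifest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- feature_manifest(j$filters, as.list(j$families), j$shape,
                        j$disc_original, j$disc_filtered)
  if (!is.null(j$total_per_region) && j$total_per_region != m$total_per_region) {
    stop("manifest declares ", j$total_per_region, " features but resolves to ",
         m$total_per_region, call. = FALSE)
  }
  m
}

#' A reduced manifest for fast cohort-scale extraction
#'
#' Original image plus one LoG scale; first-order, GLCM, GLRLM and GLSZM
#' families. Used where the full 1218-feature bank is not the point of the
#' computation (e.g. repeated simulation studies).
#'
#' @export
small_manifest <- function() {
  feature_manifest(
    filters = c("original", "log.sigma.2.0.mm.3D"),
    families = list(
      firstorder = c("Mean", "Variance", "Skewness", "Kurtosis", "Entropy",
                     "InterquartileRange", "Energy", "Uniformity"),
      glcm = c("Contrast", "Correlation", "Idn", "ClusterProminence",
               "JointEntropy"),
      glrlm = c("ShortRunEmphasis", "GrayLevelVariance",
                "GrayLevelNonUniformityNormalized", "RunEntropy"),
      glszm = c("SizeZoneNonUniformityNormalized", "SmallAreaHighGrayLevelEmphasis",
                "LargeAreaLowGrayLevelEmphasis", "ZoneEntropy")
    ),
    shape = c("VoxelVolume", "SurfaceArea", "Sphericity", "Elongation")
  )
}

#' @export
print.feature_manifest <- function(x, ...) {
  cat("<feature_manifest> ", length(x$filters), " filters x ",
      sum(lengths(x$families)), " features + ", length(x$shape),
      " shape = ", x$total_per_region, " per region\n", sep = "")
  invisible(x)
}

crop_to_mask <- function(image, mask, pad = 4L) {
  m <- mask$labels > 0
  d <- dim(m)
  rngs <- lapply(1:3, function(a) {
    pr <- apply(m, a, any)
    r <- range(which(pr))
    seq(max(1L, r[1] - pad), min(d[a], r[2] + pad))
  })
  list(
    image = volume_image(image$values[rngs[[1]], rngs[[2]], rngs[[3]], drop = FALSE],
                         image$spacing, image$origin, image$direction),
    mask = tumor_mask(m[rngs[[1]], rngs[[2]], rngs[[3]], drop = FALSE],
                      mask$spacing, mask$origin, mask$direction)
  )
}

filtered_volumes <- function(image, filters) {
  out <- list()
  need_wavelet <- any(grepl("^wavelet\\.", filters))
  wv <- if (need_wavelet) wavelet_decompose(image) else NULL
  for (f in filters) {
    if (f == "original") {
      out[[f]] <- image
    } else if (grepl("^log\\.sigma\\.", f)) {
      sigma <- as.numeric(sub("^log\\.sigma\\.([0-9.]+)\\.mm\\.3D$", "\\1", f))
      out[[f]] <- log_filter(image, sigma)
    } else if (grepl("^wavelet\\.", f)) {
      band <- sub("^wavelet\\.", "", f)
      out[[f]] <- volume_image(wv[[band]], image$spacing, image$origin, image$direction)
    } else {
      stop("unknown filter in manifest: ", f, call. = FALSE)
    }
  }
  out
}

family_fun <- list(
  firstorder = function(img, mask, disc) firstorder_features(img, mask),
  glcm = function(img, mask, disc) glcm_features(disc),
  glrlm = function(img, mask, disc) glrlm_features(disc),
  glszm = function(img, mask, disc) glszm_features(disc),
  gldm = function(img, mask, disc) gldm_features(disc),
  ngtdm = function(img, mask, disc) ngtdm_features(disc)
)

#' Extract all manifest features from one region
#'
#' Applies the manifest's filter bank to the image, discretizes each
#' filtered volume (fixed bin width for the original HU image, fixed bin
#' count for filtered volumes), runs every declared feature family, and
#' returns a named vector using the `{filter}_{family}_{feature}` naming
#' convention (with an optional region prefix such as `"Sub2_"`). Shape
#' features come from the mask alone and appear once, under
#' `original_shape_*`.
#'
#' @param image a `volume_image` (HU).
#' @param mask a `tumor_mask`: the region (whole tumor or one habitat).
#' @param manifest a [feature_manifest()].
#' @param prefix optional name prefix, e.g. `"Sub1_"`.
#' @return named numeric vector of length `manifest$total_per_region`; if
#'   the region has fewer than 8 voxels the result carries attribute
#'   `low_confidence = TRUE`.
#' @export
extract_region <- function(image, mask, manifest = default_manifest(),
                           prefix = "") {
  check_grid_match(image, mask)
  cr <- crop_to_mask(image, mask)
  vols <- filtered_volumes(cr$image, manifest$filters)
  out <- numeric(0)
  if (length(manifest$shape)) {
    sf <- shape_features(cr$mask)[manifest$shape]
    names(sf) <- paste0(prefix, "original_shape_", manifest$shape)
    out <- c(out, sf)
  }
  for (f in manifest$filters) {
    img <- vols[[f]]
    rule <- if (f == "original") manifest$disc_original else manifest$disc_filtered
    disc <- discretize(img, cr$mask, method = rule$method, value = rule$value)
    for (fam in names(manifest$families)) {
      vals <- family_fun[[fam]](img, cr$mask, disc)[manifest$families[[fam]]]
      names(vals) <- paste0(prefix, f, "_", fam, "_", manifest$families[[fam]])
      out <- c(out, vals)
    }
  }
  if (length(out) != manifest$total_per_region) {
    stop("extracted ", length(out), " features; manifest declares ",
         manifest$total_per_region, call. = FALSE)
  }
  if (sum(cr$mask$labels) < 8) attr(out, "low_confidence") <- TRUE
  out
}

#' Whole-tumor plus per-habitat feature table
#'
#' Runs [extract_region()] on the whole tumor and, if habitat maps are
#' given, on each habitat subregion (prefixes `Sub1_` .. `Subk_`; a habitat
#' absent from a patient yields NA columns for that patient).
#'
#' @param patients list of lists with `image` and `mask` per patient.
#' @param habitat_maps optional named list of `habitat_map`s (from
#'   [label_habitats()]), aligned with `patients` by name.
#' @param manifest a [feature_manifest()].
#' @param ids patient identifiers (defaults to names of `habitat_maps` or
#'   `P001..`).
#' @return tibble: `patient` column plus one column per feature.
#' @export
extract_cohort_features <- function(patients, habitat_maps = NULL,
                                    manifest = default_manifest(), ids = NULL) {
  if (is.null(ids)) {
    ids <- names(habitat_maps) %||% paste0("P", sprintf("%03d", seq_along(patients)))
  }
  rows <- lapply(seq_along(patients), function(i) {
    p <- patients[[i]]
    fv <- extract_region(p$image, p$mask, manifest)
    base_names <- names(fv)
    if (!is.null(habitat_maps)) {
      hm <- habitat_maps[[ids[i]]]
      for (j in seq_len(hm$k)) {
        sel <- hm$labels == j
        sub <- if (sum(sel) >= 2) {
          mk <- tumor_mask(sel, hm$spacing, hm$origin, hm$direction)
          extract_region(p$image, mk, manifest, prefix = paste0("Sub", j, "_"))
        } else {
          stats::setNames(rep(NA_real_, manifest$total_per_region),
                          paste0("Sub", j, "_", base_names))
        }
        fv <- c(fv, sub)
      }
    }
    tibble::as_tibble(as.list(fv))
  })
  dplyr::bind_cols(tibble::tibble(patient = ids), dplyr::bind_rows(rows))
}
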