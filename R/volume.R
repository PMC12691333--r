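#' 3D scalar volumes and tumor masks
#'
#' `volume_image()` wraps a 3D numeric array (CT intensities in HU) together
#' with its geometry: voxel spacing (mm), world origin (mm) and a 3x3
#' direction matrix. `tumor_mask()` wraps a binary segmentation on the same
#' grid (1 = tumor, 0 = background).
#'
#' @param values 3D numeric array.
#' @param spacing numeric length-3, strictly positive voxel spacing in mm.
#' @param origin numeric length-3 world coordinate of voxel (1,1,1), mm.
#' @param direction 3x3 direction cosine matrix (columns = axis directions).
#' @return An object of class `volume_image` (resp. `tumor_mask`).
#' @export
volume_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("volume must be 3D; got ", length(dim(values)), " dimensions", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("volume values must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive numbers", call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin),
         direction = matrix(as.numeric(direction), 3, 3)),
    class = "volume_image"
  )
}

#' @param labels 3D array coercible to 0/1.
#' @rdname volume_image
#' @export
tumor_mask <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       direction = diag(3)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) {
    stop("mask must be 3D; got ", length(dim(labels)), " dimensions", call. = FALSE)
  }
  lab <- array(as.integer(labels != 0), dim(labels))
  if (sum(lab) == 0L) stop("mask has no foreground voxels", call. = FALSE)
  structure(
    list(labels = lab, spacing = as.numeric(spacing), origin = as.numeric(origin),
         direction = matrix(as.numeric(direction), 3, 3)),
    class = "tumor_mask"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"), " mm\n", sep = "")
  invisible(x)
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat("<tumor_mask> ", paste(dim(x$labels), collapse = " x "),
      " grid, ", sum(x$labels), " foreground voxels\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "volume_image")) dim(a$values) else dim(a$labels)
  db <- if (inherits(b, "volume_image")) dim(b$values) else dim(b$labels)
  identical(da, db) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

check_grid_match <- function(image, mask) {
  if (!same_grid(image, mask)) {
    stop("image and mask are not on the same grid (shape/spacing/origin/direction); ",
         "segmentations must stay on their native grid", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write 3D volumes (NIfTI-1 or NRRD)
#'
#' Format is chosen by extension: `.nii` / `.nii.gz` (via RNifti) or `.nrrd`
#' (raw-encoding NRRD, read and written natively). Round-tripping preserves
#' values, spacing, origin and direction within format precision.
#'
#' @param path file path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @param as_mask read as a binary `tumor_mask` instead of a `volume_image`.
#' @return `read_volume()`: a `volume_image` (or `tumor_mask`);
#'   `write_volume()`: `path`, invisibly.
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    vol <- read_nrrd(path)
  } else {
    img <- RNifti::readNifti(path)
    nd <- length(dim(img))
    if (nd != 3L) {
      stop("expected a 3D volume, got ", nd, " dimensions in ", path, call. = FALSE)
    }
    aff <- RNifti::xform(img)
    spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
    vol <- list(values = array(as.numeric(img), dim(img)),
                spacing = spacing,
                origin = as.numeric(aff[1:3, 4]),
                direction = sweep(aff[1:3, 1:3], 2, spacing, "/"))
  }
  if (as_mask) {
    tumor_mask(vol$values != 0, vol$spacing, vol$origin, vol$direction)
  } else {
    volume_image(vol$values, vol$spacing, vol$origin, vol$direction)
  }
}

#' @param x a `volume_image` or `tumor_mask`.
#' @rdname read_volume
#' @export
write_volume <- function(x, path) {
  vals <- if (inherits(x, "tumor_mask")) x$labels else x$values
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(vals, x$spacing, x$origin, x$direction, path)
  } else {
    aff <- rbind(cbind(x$direction %*% diag(x$spacing), x$origin), c(0, 0, 0, 1))
    img <- RNifti::asNifti(vals)
    img <- RNifti::`pixdim<-`(img, x$spacing)
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

# Minimal NRRD (raw encoding, little endian, double) -- enough for exact
# round-trips of analysis volumes; not a general NRRD implementation.
write_nrrd <- function(values, spacing, origin, direction, path) {
  dirs <- direction %*% diag(spacing)
  vec <- function(v) sprintf("(%.17g,%.17g,%.17g)", v[1], v[2], v[3])
  hdr <- c(
    "NRRD0004",
    "type: double",
    "dimension: 3",
    paste0("sizes: ", paste(dim(values), collapse = " ")),
    "encoding: raw",
    "endian: little",
    "space dimension: 3",
    paste0("space directions: ", paste(vapply(1:3, function(j) vec(dirs[, j]), ""), collapse = " ")),
    paste0("space origin: ", vec(origin)),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(values), con, size = 8, endian = "little")
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    hdr <- c(hdr, line)
  }
  field <- function(key) {
    m <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (length(m) == 0L) return(NULL)
    sub(paste0("^", key, ": "), "", m[1])
  }
  if (!grepl("^NRRD", hdr[1])) stop("not an NRRD file: ", path, call. = FALSE)
  if (!identical(field("dimension"), "3")) {
    stop("expected dimension 3 in ", path, ", got ", field("dimension"), call. = FALSE)
  }
  if (!identical(field("encoding"), "raw") || !identical(field("type"), "double")) {
    stop("only raw-encoded double NRRD supported: ", path, call. = FALSE)
  }
  sizes <- as.integer(strsplit(field("sizes"), " +")[[1]])
  parse_vecs <- function(s) {
    m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
    vapply(m, function(v) as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
  }
  dirs <- parse_vecs(field("space directions"))
  origin <- as.numeric(parse_vecs(field("space origin")))
  spacing <- sqrt(colSums(dirs^2))
  vals <- readBin(con, numeric(), n = prod(sizes), size = 8, endian = "little")
  list(values = array(vals, sizes), spacing = spacing, origin = origin,
       direction = sweep(dirs, 2, spacing, "/"))
}

# Vectorized trilinear interpolation at per-axis fractional (1-based) indices.
trilinear_sample <- function(vol, fx, fy, fz) {
  d <- dim(vol)
  x0 <- pmax(1L, pmin(d[1] - 1L, floor(fx))); wx <- pmin(pmax(fx - x0, 0), 1)
  y0 <- pmax(1L, pmin(d[2] - 1L, floor(fy))); wy <- pmin(pmax(fy - y0, 0), 1)
  z0 <- pmax(1L, pmin(d[3] - 1L, floor(fz))); wz <- pmin(pmax(fz - z0, 0), 1)
  if (d[1] == 1L) { x0 <- rep(1L, length(fx)); wx <- rep(0, length(fx)) }
  if (d[2] == 1L) { y0 <- rep(1L, length(fy)); wy <- rep(0, length(fy)) }
  if (d[3] == 1L) { z0 <- rep(1L, length(fz)); wz <- rep(0, length(fz)) }
  out <- array(0, c(length(fx), length(fy), length(fz)))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- pmin(x0 + cx, d[1]); iy <- pmin(y0 + cy, d[2]); iz <- pmin(z0 + cz, d[3])
    ax <- if (cx == 1) wx else 1 - wx
    ay <- if (cy == 1) wy else 1 - wy
    az <- if (cz == 1) wz else 1 - wz
    w <- outer(outer(ax, ay), az)
    out <- out + vol[ix, iy, iz, drop = FALSE] * w
  }
  out
}

#' Resample an image and mask to an isotropic grid
#'
#' The image is interpolated trilinearly and the mask by nearest neighbour
#' onto a grid with spacing `target` mm along every axis, covering the same
#' physical extent. All downstream habitat and texture analysis assumes an
#' isotropic grid; this is the operation that establishes it.
#'
#' @param image a `volume_image`.
#' @param mask a `tumor_mask` on the same grid.
#' @param target target isotropic spacing in mm (default 1).
#' @return list with elements `image` and `mask` on the new grid.
#' @export
resample_isotropic <- function(image, mask, target = 1) {
  stopifnot(target > 0)
  check_grid_match(image, mask)
  if (max(abs(image$direction - diag(3))) > 1e-6) {
    stop("resampling supports axis-aligned volumes only; reorient first", call. = FALSE)
  }
  d <- dim(image$values)
  sp <- image$spacing
  if (max(abs(sp - target)) < 1e-12) {
    return(list(image = image, mask = mask))
  }
  nd <- pmax(1L, as.integer(floor((d - 1) * sp / target)) + 1L)
  fr <- lapply(1:3, function(a) ((seq_len(nd[a]) - 1) * target) / sp[a] + 1)
  vals <- trilinear_sample(image$values, fr[[1]], fr[[2]], fr[[3]])
  nn <- lapply(1:3, function(a) pmax(1L, pmin(d[a], as.integer(round(fr[[a]])))))
  lab <- mask$labels[nn[[1]], nn[[2]], nn[[3]], drop = FALSE]
  if (sum(lab) == 0L) stop("mask is empty after resampling to ", target, " mm", call. = FALSE)
  list(
    image = volume_image(vals, rep(target, 3), image$origin, image$direction),
    mask = tumor_mask(lab, rep(target, 3), image$origin, image$direction)
  )
}

#' Tumor volume statistics
#'
#' Total tumor volume as the sum of per-voxel volumes over the segmentation:
#' on a uniform grid this is `n_voxels * prod(spacing)`.
#'
#' @param mask a `tumor_mask`.
#' @return one-row tibble: `n_voxels`, `voxel_volume` (mm^3), `total_volume` (mm^3).
#' @export
volume_stats <- function(mask) {
  stopifnot(inherits(mask, "tumor_mask"))
  n <- sum(mask$labels)
  vv <- prod(mask$spacing)
  tibble::tibble(n_voxels = n, voxel_volume = vv, total_volume = n * vv)
}
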