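#' Specify a synthetic phantom cohort
#'
#' Defines the generating conditions for a seeded cohort of ellipsoidal tumor
#' phantoms, each composed of `k_true` spatially contiguous habitat
#' subregions with distinct mean attenuation, noise level and texture
#' correlation length. A binary outcome (brain-metastasis-like event) is
#' drawn from a logistic link on the per-patient habitat volume fractions
#' plus one subregional texture summary, with optional clinical covariate
#' effects.
#'
#' @param n_patients number of phantoms.
#' @param k_true number of planted habitats (>= 1).
#' @param habitat_params tibble with one row per habitat: `mean_hu`, `sd_hu`,
#'   `corr_mm` (Gaussian-field correlation length, mm). Means must be pairwise
#'   separated by at least twice the largest `sd_hu` so habitats remain
#'   separable in feature space.
#' @param tumor_radius_range min/max ellipsoid semi-axis, mm.
#' @param spacing voxel spacing, mm (length 3).
#' @param outcome_beta named coefficients of the logistic link; names refer to
#'   habitat-fraction covariates `f1..fk` and `tex` (texture summary).
#' @param clinical_beta named coefficients on dichotomized clinical covariates
#'   (`age_ge65`, `n2_stage`, `mutation_any`, `egfr`); zero vector disables
#'   clinical signal.
#' @param prevalence_target target outcome prevalence in (0,1); the link
#'   intercept is calibrated against the generated covariates to reach it.
#' @param texture_jitter half-width of the per-patient multiplier (uniform on
#'   `1 +/- texture_jitter`) applied to the highest habitat's noise SD, so
#'   that subregional texture carries real patient-level signal; the
#'   separability guarantee is enforced at the largest multiplier.
#' @param geometry `"voronoi"` (random interior seeds; patchy habitats) or
#'   `"shells"` (concentric equal-volume shells; ring-enhancement pattern).
#' @param seed integer; the single source of randomness. Per-patient
#'   substreams are derived from it, so cohorts are bit-reproducible.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(n_patients = 20,
                         k_true = 3,
                         habitat_params = default_habitat_params(k_true),
                         tumor_radius_range = c(6, 12),
                         spacing = c(1, 1, 1),
                         outcome_beta = default_outcome_beta(k_true),
                         clinical_beta = c(age_ge65 = 0.35, n2_stage = 0.4,
                                           mutation_any = 0.35, egfr = 0.3),
                         prevalence_target = 0.35,
                         geometry = c("voronoi", "shells"),
                         texture_jitter = 0.4,
                         seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(k_true >= 1, n_patients >= 1,
            prevalence_target > 0, prevalence_target < 1,
            nrow(habitat_params) == k_true,
            texture_jitter >= 0, texture_jitter < 1)
  if (k_true > 1) {
    gaps <- abs(outer(habitat_params$mean_hu, habitat_params$mean_hu, "-"))
    min_gap <- min(gaps[upper.tri(gaps)])
    sd_max <- habitat_params$sd_hu
    sd_max[k_true] <- sd_max[k_true] * (1 + texture_jitter)
    if (min_gap < 2 * max(sd_max)) {
      stop("habitat mean HUs must be pairwise separated by >= 2x the largest sd_hu",
           call. = FALSE)
    }
  }
  structure(
    list(n_patients = as.integer(n_patients), k_true = as.integer(k_true),
         habitat_params = tibble::as_tibble(habitat_params),
         tumor_radius_range = tumor_radius_range, spacing = spacing,
         outcome_beta = outcome_beta, clinical_beta = clinical_beta,
         prevalence_target = prevalence_target, geometry = geometry,
         texture_jitter = texture_jitter, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' @rdname phantom_spec
#' @export
default_habitat_params <- function(k_true = 3) {
  # Enhancing arterial-phase lesion: hypodense necrotic core (~0 HU) through
  # strongly enhancing tissue (~160 HU), 80 HU apart with sd <= 25 so the
  # 2x-sd separability guarantee holds; noise amplitude and correlation
  # length both increase with enhancement, so local entropy separates the
  # habitats as well as mean attenuation does.
  tibble::tibble(
    mean_hu = seq(0, by = 80, length.out = k_true),
    sd_hu = rep_len(c(5, 12, 25), k_true),
    corr_mm = rep_len(c(0.1, 0.45, 0.25), k_true)
  )
}

#' @rdname phantom_spec
#' @export
default_outcome_beta <- function(k_true = 3) {
  b <- c(-4, 5, 1.5)
  names(b) <- c("f1", paste0("f", k_true), "tex")
  if (k_true == 1) b <- c(f1 = 0, tex = 1.5)
  b
}

# Deterministic 32-bit substream seed for patient i of a spec-level seed.
substream_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 1009) %% 2147483647)
}

ellipsoid_mask <- function(semi_axes, spacing) {
  nd <- as.integer(ceiling(2 * semi_axes / spacing) + 3L)
  ctr <- (nd + 1) / 2
  gx <- (seq_len(nd[1]) - ctr[1]) * spacing[1]
  gy <- (seq_len(nd[2]) - ctr[2]) * spacing[2]
  gz <- (seq_len(nd[3]) - ctr[3]) * spacing[3]
  r2 <- outer(outer((gx / semi_axes[1])^2, (gy / semi_axes[2])^2, "+"),
              (gz / semi_axes[3])^2, "+")
  r2 <= 1
}

# Partition the foreground of `inside` into k contiguous habitats.
plant_habitats <- function(inside, k, spacing, geometry, min_voxels = 8L) {
  d <- dim(inside)
  idx <- which(inside)
  coord <- arrayInd(idx, d)
  phys <- sweep(coord, 2, spacing, "*")
  lab <- array(0L, d)
  if (k == 1L) { lab[idx] <- 1L; return(lab) }
  if (geometry == "shells") {
    ctr <- colMeans(phys)
    r <- sqrt(rowSums(sweep(phys, 2, ctr)^2))
    q <- stats::quantile(r, probs = seq(0, 1, length.out = k + 1))
    sh <- pmin(k, findInterval(r, q, rightmost.closed = TRUE))
    lab[idx] <- as.integer(sh)
    return(lab)
  }
  for (try in 1:25) {
    seeds <- phys[sample.int(nrow(phys), k), , drop = FALSE]
    d2 <- vapply(seq_len(k), function(j) rowSums(sweep(phys, 2, seeds[j, ])^2),
                 numeric(nrow(phys)))
    assign <- max.col(-d2, ties.method = "first")
    if (min(tabulate(assign, k)) >= min_voxels) {
      lab[idx] <- as.integer(assign)
      return(lab)
    }
  }
  stop("could not place ", k, " habitats of >= ", min_voxels,
       " voxels; tumor too small", call. = FALSE)
}

# Unit-variance Gaussian random field with correlation length corr_mm.
grf3 <- function(d, corr_mm, spacing) {
  z <- array(stats::rnorm(prod(d)), d)
  if (corr_mm <= min(spacing) / 4) return(z)
  s <- gauss_smooth3(z, corr_mm / spacing)
  sd_s <- stats::sd(s)
  if (sd_s < 1e-12) return(array(0, d)) else s / sd_s
}

generate_phantom <- function(spec, patient_seed) {
  set.seed(patient_seed)
  sp <- spec$spacing
  rr <- spec$tumor_radius_range
  for (attempt in 1:10) {
    semi <- stats::runif(3, rr[1], rr[2])
    inside <- ellipsoid_mask(semi, sp)
    lab <- tryCatch(plant_habitats(inside, spec$k_true, sp, spec$geometry),
                    error = function(e) NULL)
    if (!is.null(lab)) break
    rr <- rr * 1.3
    message("phantom regeneration with larger radius (attempt ", attempt + 1, ")")
  }
  if (is.null(lab)) stop("failed to generate phantom", call. = FALSE)
  d <- dim(inside)
  vals <- array(-700 + 20 * stats::rnorm(prod(d)), d)  # lung-background HU
  tex_mult <- 1 + spec$texture_jitter * stats::runif(1, -1, 1)
  for (h in seq_len(spec$k_true)) {
    hp <- spec$habitat_params[h, ]
    sd_h <- hp$sd_hu * if (h == spec$k_true) tex_mult else 1
    field <- hp$mean_hu + sd_h * grf3(d, hp$corr_mm, sp)
    sel <- lab == h
    vals[sel] <- field[sel]
  }
  list(image = volume_image(vals, sp),
       mask = tumor_mask(inside, sp),
       truth_labels = lab)
}

#' Generate a synthetic phantom cohort
#'
#' Produces `spec$n_patients` phantoms with planted habitat structure, a
#' second-reader segmentation for each, a clinical covariate table, and a
#' Bernoulli outcome drawn from the calibrated logistic link. Identical
#' `spec` (including its seed) reproduces the cohort bit-identically.
#'
#' @param spec a [phantom_spec()].
#' @return a `habitat_cohort` list: `patients` (list of `image`, `mask`,
#'   `mask_reader2`, `truth_labels` per patient), `clinical` (tibble, includes
#'   the outcome), `truth` (tibble of habitat fractions, texture summary,
#'   true probability and outcome), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  seeds <- vapply(seq_len(spec$n_patients), function(i) substream_seed(spec$seed, i), 1L)
  patients <- lapply(seq_len(spec$n_patients), function(i) {
    ph <- generate_phantom(spec, seeds[i])
    ph$mask_reader2 <- simulate_second_reader(
      ph$mask, perturb = list(jitter_p = 0.15), seed = substream_seed(seeds[i], 1L))
    ph
  })
  k <- spec$k_true
  fr <- t(vapply(patients, function(p) {
    tabulate(p$truth_labels[p$truth_labels > 0], k) / sum(p$truth_labels > 0)
  }, numeric(k)))
  colnames(fr) <- paste0("f", seq_len(k))
  tex <- vapply(patients, function(p) {
    v <- p$image$values[p$truth_labels == k]
    if (length(v) > 1) stats::sd(v) else 0
  }, numeric(1))
  truth <- tibble::tibble(patient = paste0("P", sprintf("%03d", seq_len(spec$n_patients))))
  truth <- dplyr::bind_cols(truth, tibble::as_tibble(fr), tibble::tibble(tex = tex))

  clinical <- make_clinical_table(spec, truth)

  # Linear predictor on standardized link covariates + clinical flags.
  tex_z <- if (length(tex) > 1 && stats::sd(tex) > 0) {
    as.numeric(scale(tex))
  } else rep(0, length(tex))
  covs <- cbind(fr, tex = tex_z)
  b <- spec$outcome_beta
  miss <- setdiff(names(b), colnames(covs))
  if (length(miss)) stop("outcome_beta names not generated: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  eta <- as.numeric(covs[, names(b), drop = FALSE] %*% b)
  cb <- spec$clinical_beta
  if (length(cb)) {
    cmat <- as.matrix(clinical[, names(cb), drop = FALSE])
    eta <- eta + as.numeric(cmat %*% cb)
  }
  f <- function(b0) mean(stats::plogis(b0 + eta)) - spec$prevalence_target
  if (f(-30) > 0 || f(30) < 0) {
    stop("prevalence target ", spec$prevalence_target, " unattainable under the link",
         call. = FALSE)
  }
  b0 <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  prob <- stats::plogis(b0 + eta)
  set.seed(substream_seed(spec$seed, spec$n_patients + 1L))
  outcome <- stats::rbinom(length(prob), 1, prob)

  truth$prob <- prob
  truth$outcome <- outcome
  clinical$outcome <- outcome
  structure(list(patients = patients, clinical = clinical, truth = truth,
                 spec = spec, informative = names(b)),
            class = "habitat_cohort")
}

#' Simulate a second reader's segmentation
#'
#' Emulates inter-observer segmentation variability: optional one-voxel
#' dilation or erosion followed by random flipping of boundary voxels. The
#' perturbed mask is guaranteed nonempty and to overlap the input with a Dice
#' coefficient above `dice_floor`.
#'
#' @param mask a `tumor_mask`.
#' @param perturb list with any of `dilate` (logical), `erode` (logical),
#'   `jitter_p` (boundary flip probability in `[0,1]`).
#' @param dice_floor minimum acceptable Dice vs the input mask.
#' @param seed integer seed.
#' @return a perturbed `tumor_mask` on the same grid.
#' @export
simulate_second_reader <- function(mask, perturb = list(jitter_p = 0.15),
                                   dice_floor = 0.7, seed = 1L) {
  stopifnot(inherits(mask, "tumor_mask"))
  set.seed(seed)
  m0 <- mask$labels > 0
  m <- m0
  if (isTRUE(perturb$dilate)) m <- dilate3(m)
  if (isTRUE(perturb$erode)) m <- erode3(m)
  jp <- perturb$jitter_p %||% 0
  if (jp > 0) {
    bnd <- which(boundary3(m) | (dilate3(m) & !m))  # inner + outer boundary
    flip <- bnd[stats::runif(length(bnd)) < jp]
    m[flip] <- !m[flip]
  }
  if (!any(m)) stop("perturbation emptied the mask", call. = FALSE)
  dice <- 2 * sum(m & m0) / (sum(m) + sum(m0))
  if (dice < dice_floor) {
    stop(sprintf("perturbed mask Dice %.3f below floor %.2f", dice, dice_floor),
         call. = FALSE)
  }
  tumor_mask(m, mask$spacing, mask$origin, mask$direction)
}

#' Clinical covariate table for a synthetic cohort
#'
#' Draws demographics, staging, serum tumor markers and mutation flags with
#' the schema of a typical NSCLC cohort table, and appends the dichotomized
#' derived columns used by the clinical risk model: age >= 65, N2 stage,
#' any gene mutation, EGFR mutation, and marker cutoffs (CEA > 5,
#' CA125 > 35, NSE > 18, ProGRP > 70, Cyfra21-1 > 2.08, SCC > 2; all strict).
#'
#' @param spec a [phantom_spec()].
#' @param truth tibble with a `patient` column (one row per patient).
#' @return tibble, one row per patient.
#' @export
make_clinical_table <- function(spec, truth) {
  n <- nrow(truth)
  set.seed(substream_seed(spec$seed, spec$n_patients + 2L))
  rln <- function(med, sdlog) stats::rlnorm(n, log(med), sdlog)
  age <- round(stats::rnorm(n, 65.8, 9.2))
  egfr <- stats::rbinom(n, 1, 0.47)
  alk <- stats::rbinom(n, 1, 0.04)
  kras <- stats::rbinom(n, 1, 0.10)
  tp53 <- stats::rbinom(n, 1, 0.10)
  other_mut <- stats::rbinom(n, 1, 0.05)
  n_stage <- sample(c("N0", "N1", "N2", "N3"), n, replace = TRUE,
                    prob = c(0.35, 0.2, 0.3, 0.15))
  tbl <- tibble::tibble(
    patient = truth$patient,
    age = age,
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.59, 0.41)),
    smoking = stats::rbinom(n, 1, 0.47),
    tumor_type = sample(c("adenocarcinoma", "squamous"), n, replace = TRUE,
                        prob = c(0.87, 0.13)),
    tumor_location = sample(c("peripheral", "central"), n, replace = TRUE,
                            prob = c(0.86, 0.14)),
    t_stage = sample(c("T1", "T2", "T3", "T4"), n, replace = TRUE,
                     prob = c(0.2, 0.32, 0.24, 0.24)),
    n_stage = n_stage,
    m_stage = sample(c("M0", "M1"), n, replace = TRUE, prob = c(0.65, 0.35)),
    cea = rln(5.6, 1.2), ca125 = rln(20, 1.0), ca724 = rln(4.2, 1.0),
    nse = rln(12.8, 0.4), scc = rln(1.0, 0.8), progrp = rln(36, 0.5),
    cyfra211 = rln(2.7, 0.9),
    egfr = egfr, alk = alk, kras = kras, tp53 = tp53,
    mutation_any = as.integer(egfr | alk | kras | tp53 | other_mut)
  )
  dplyr::mutate(tbl,
    age_ge65 = as.integer(.data$age >= 65),
    n2_stage = as.integer(.data$n_stage == "N2"),
    cea_high = as.integer(.data$cea > 5),
    ca125_high = as.integer(.data$ca125 > 35),
    nse_high = as.integer(.data$nse > 18),
    progrp_high = as.integer(.data$progrp > 70),
    cyfra211_high = as.integer(.data$cyfra211 > 2.08),
    scc_high = as.integer(.data$scc > 2)
  )
}

#' Variable manifest of the clinical table
#'
#' @return character vector of the column names [make_clinical_table()]
#'   guarantees (outcome is appended by [generate_cohort()]).
#' @export
clinical_schema <- function() {
  c("patient", "age", "sex", "smoking", "tumor_type", "tumor_location",
    "t_stage", "n_stage", "m_stage",
    "cea", "ca125", "ca724", "nse", "scc", "progrp", "cyfra211",
    "egfr", "alk", "kras", "tp53", "mutation_any",
    "age_ge65", "n2_stage", "cea_high", "ca125_high", "nse_high",
    "progrp_high", "cyfra211_high", "scc_high")
}

#' Export a cohort to disk (NIfTI volumes + CSV tables)
#'
#' Writes per-patient image, mask and truth labels as `.nii.gz`, the clinical
#' table as CSV and the spec as JSON, in the layout [ingest_cohort()] reads.
#'
#' @param cohort a `habitat_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  ids <- cohort$clinical$patient
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    write_volume(p$image, file.path(dir, "images", paste0(ids[i], ".nii.gz")))
    write_volume(p$mask, file.path(dir, "masks", paste0(ids[i], ".nii.gz")))
    tr <- volume_image(p$truth_labels, p$image$spacing, p$image$origin, p$image$direction)
    write_volume(tr, file.path(dir, "truth", paste0(ids[i], ".nii.gz")))
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  spec_json <- cohort$spec
  spec_json$habitat_params <- as.data.frame(spec_json$habitat_params)
  jsonlite::write_json(unclass(spec_json), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
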