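#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end habitat analysis with a
#' single seed. The configuration round-trips through JSON and its hash
#' identifies a run for artifact caching/resume.
#'
#' @param spec a [phantom_spec()] describing the simulated cohort (ignored
#'   when a pre-built cohort is passed to [run_pipeline()]).
#' @param spacing target isotropic spacing, mm.
#' @param entropy_window,entropy_bins,entropy_eps per-voxel entropy-map
#'   parameters (see [entropy_map()]).
#' @param k_range candidate habitat counts for CH selection.
#' @param manifest `"default"`, `"small"`, or a path to a manifest JSON.
#' @param r_max correlation-filter cutoff.
#' @param mrmr_m features kept by the mRMR stage.
#' @param n_folds LASSO cross-validation folds.
#' @param split_ratio training fraction.
#' @param lambda LASSO lambda rule, `"min"` or `"1se"`.
#' @param seed integer; master seed for split/clustering/selection.
#' @param out_dir optional directory for stage artifacts (enables resume).
#' @return a `run_config` list.
#' @export
run_config <- function(spec = phantom_spec(), spacing = 1,
                       entropy_window = 1L, entropy_bins = 32L,
                       entropy_eps = 1e-12, k_range = 2:5,
                       manifest = "small", r_max = 0.75, mrmr_m = 30,
                       n_folds = 10, split_ratio = 0.7, lambda = "min",
                       seed = 17L, out_dir = NULL) {
  structure(
    list(spec = spec, spacing = spacing, entropy_window = entropy_window,
         entropy_bins = entropy_bins, entropy_eps = entropy_eps,
         k_range = k_range, manifest = manifest, r_max = r_max,
         mrmr_m = mrmr_m, n_folds = n_folds, split_ratio = split_ratio,
         lambda = lambda, seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

resolve_manifest <- function(manifest) {
  if (inherits(manifest, "feature_manifest")) return(manifest)
  switch(manifest,
         default = default_manifest(),
         small = small_manifest(),
         read_manifest(manifest))
}

stage_cached <- function(config, name, compute) {
  if (is.null(config$out_dir)) return(compute())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(config$out_dir,
                    paste0(config_hash(config), "-", name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  res <- compute()
  saveRDS(res, path)
  res
}

#' Run the full habitat-radiomics pipeline
#'
#' Executes, in order: simulate (or ingest) -> resample -> split -> habitat
#' clustering (training cohort only; validation voxels are assigned to the
#' frozen training centroids) -> feature extraction (whole tumor + each
#' habitat) -> feature selection and radscore construction (training only)
#' -> clinical/VOI/Sub logistic models -> evaluation (AUC/CI/operating
#' points, DeLong Sub-vs-VOI, calibration, decision curves). When
#' `config$out_dir` is set, each stage's result is cached on disk keyed by
#' the configuration hash, so an interrupted run resumes without
#' recomputation.
#'
#' @param config a [run_config()].
#' @param cohort optional pre-built cohort (a `habitat_cohort` from
#'   [generate_cohort()] or [ingest_cohort()]); by default simulated from
#'   `config$spec`.
#' @return a `habitat_report`: `config_hash`, `ch_by_k`, `k_star`,
#'   `selection` (per model), `evaluation` (model x cohort grid), `delong`,
#'   `calibration`, `decision`, `scores`, `clinical_fit`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  manifest <- resolve_manifest(config$manifest)

  cohort <- stage_cached(config, "simulate", function() {
    cohort %||% generate_cohort(config$spec)
  })
  ids <- cohort$clinical$patient

  resampled <- stage_cached(config, "resample", function() {
    lapply(cohort$patients, function(p) {
      resample_isotropic(p$image, p$mask, target = config$spacing)
    })
  })
  masks <- stats::setNames(lapply(resampled, `[[`, "mask"), ids)

  clinical <- split_cohort(cohort$clinical, ratio = config$split_ratio,
                           seed = config$seed)
  tr_ids <- clinical$patient[clinical$split == "training"]
  va_ids <- clinical$patient[clinical$split == "validation"]

  habitats <- stage_cached(config, "habitats", function() {
    maps <- stats::setNames(lapply(seq_along(resampled), function(i) {
      entropy_map(resampled[[i]]$image, resampled[[i]]$mask,
                  window = config$entropy_window, n_bins = config$entropy_bins,
                  eps = config$entropy_eps)
    }), ids)
    pooled <- pool_cohort_features(maps[tr_ids])
    sel <- select_k(pooled, k_range = config$k_range, seed = config$seed)
    fit <- sel$clusterings[[paste0("k", sel$k_star)]]
    hm_tr <- label_habitats(fit, pooled, masks[tr_ids])
    hm_va <- if (length(va_ids)) {
      va_feats <- assign_to_centroids(fit, standardize_voxels(pooled, maps[va_ids]))
      label_habitats(fit, va_feats, masks[va_ids], assignments = va_feats$cluster)
    } else list()
    list(k_star = sel$k_star, ch_by_k = sel$ch_by_k, clustering = fit,
         maps = c(hm_tr, hm_va)[ids])
  })

  features <- stage_cached(config, "extract", function() {
    extract_cohort_features(resampled, habitat_maps = habitats$maps,
                            manifest = manifest, ids = ids)
  })

  fit_one <- function(cols) {
    tab <- features[features$patient %in% tr_ids, cols, drop = FALSE]
    tab <- tab[, colSums(is.na(tab)) == 0 & vapply(tab, function(x) is.numeric(x) && all(is.finite(x)), TRUE), drop = FALSE]
    tab$outcome <- clinical$outcome[match(tr_ids, clinical$patient)]
    select_features(tab, r_max = config$r_max, mrmr_m = config$mrmr_m,
                    n_folds = config$n_folds, seed = config$seed,
                    lambda = config$lambda)
  }
  feat_names <- setdiff(names(features), "patient")
  voi_cols <- feat_names[!grepl("^Sub[0-9]+_", feat_names)]
  sub_cols <- feat_names[grepl("^Sub[0-9]+_", feat_names)]
  selection <- stage_cached(config, "select", function() {
    list(voi = fit_one(voi_cols), sub = fit_one(sub_cols))
  })

  # A habitat can be absent from an individual patient; its subregional
  # features are then imputed with the training-cohort median before scoring.
  features_imp <- features
  for (cn in setdiff(names(features_imp), "patient")) {
    col <- features_imp[[cn]]
    bad <- !is.finite(col)
    if (any(bad)) {
      med <- stats::median(col[features_imp$patient %in% tr_ids & !bad])
      col[bad] <- if (is.finite(med)) med else 0
      features_imp[[cn]] <- col
    }
  }
  score_of <- function(model, rows) {
    evaluate_radscore(model, features_imp[match(rows, features_imp$patient), , drop = FALSE])
  }
  clin_fit <- fit_clinical_model(clinical[clinical$split == "training", ])
  clin_score <- function(rows) {
    stats::predict(clin_fit$fit,
                   newdata = clinical[match(rows, clinical$patient), ],
                   type = "link")
  }
  scores <- list(
    clin = list(training = clin_score(tr_ids), validation = clin_score(va_ids)),
    voi = list(training = score_of(selection$voi$model, tr_ids),
               validation = score_of(selection$voi$model, va_ids)),
    sub = list(training = score_of(selection$sub$model, tr_ids),
               validation = score_of(selection$sub$model, va_ids))
  )
  outc <- list(training = clinical$outcome[match(tr_ids, clinical$patient)],
               validation = clinical$outcome[match(va_ids, clinical$patient)])

  grid <- dplyr::bind_rows(lapply(names(scores), function(mod) {
    dplyr::bind_rows(lapply(names(outc), function(coh) {
      if (!length(outc[[coh]]) || length(unique(outc[[coh]])) < 2) return(NULL)
      dplyr::bind_cols(tibble::tibble(model = mod, cohort = coh),
                       evaluate_model(scores[[mod]][[coh]], outc[[coh]]))
    }))
  }))
  delong <- dplyr::bind_rows(lapply(names(outc), function(coh) {
    if (length(unique(outc[[coh]])) < 2) return(NULL)
    dplyr::bind_cols(tibble::tibble(cohort = coh, comparison = "sub_vs_voi"),
                     delong_test(scores$sub[[coh]], scores$voi[[coh]], outc[[coh]]))
  }))
  sub_prob <- stats::plogis(stats::predict(
    fit_score_model(scores$sub$training, outc$training)$fit,
    newdata = data.frame(score = scores$sub$validation)))
  calib <- if (length(va_ids)) calibration_curve(sub_prob, outc$validation) else NULL
  dca <- if (length(va_ids)) decision_curve(sub_prob, outc$validation) else NULL

  structure(
    list(config_hash = config_hash(config), k_star = habitats$k_star,
         ch_by_k = habitats$ch_by_k, selection = selection,
         evaluation = grid, delong = delong, calibration = calib,
         decision = dca, scores = scores, clinical_fit = clin_fit,
         split = clinical[, c("patient", "split", "outcome")],
         version = as.character(utils::packageVersion("habikit"))),
    class = "habitat_report"
  )
}

#' @export
print.habitat_report <- function(x, ...) {
  cat("<habitat_report> k* =", x$k_star, "\n")
  print(x$evaluation[, c("model", "cohort", "auc", "ci_low", "ci_high",
                         "sensitivity", "specificity")])
  invisible(x)
}

#' @export
glance.habitat_report <- function(x, ...) {
  tibble::tibble(k_star = x$k_star,
                 n_selected_voi = length(x$selection$voi$stages$lasso),
                 n_selected_sub = length(x$selection$sub$stages$lasso),
                 auc_sub_training = x$evaluation$auc[x$evaluation$model == "sub" &
                                                       x$evaluation$cohort == "training"])
}

#' Ingest an exported cohort from disk
#'
#' Reads the directory layout written by [export_cohort()] (`images/`,
#' `masks/`, optional `truth/`, `clinical.csv`), reconciling patient ids
#' across images, masks and the clinical table; extra clinical columns are
#' passed through untouched.
#'
#' @param dir cohort directory.
#' @return a `habitat_cohort` (without generator truth unless `truth/` is
#'   present).
#' @export
ingest_cohort <- function(dir) {
  clinical <- tibble::as_tibble(utils::read.csv(file.path(dir, "clinical.csv"),
                                                stringsAsFactors = FALSE))
  ids <- clinical$patient
  img_files <- file.path(dir, "images", paste0(ids, ".nii.gz"))
  msk_files <- file.path(dir, "masks", paste0(ids, ".nii.gz"))
  missing_img <- ids[!file.exists(img_files)]
  missing_msk <- ids[!file.exists(msk_files)]
  if (length(missing_img) || length(missing_msk)) {
    stop("cohort reconciliation failed; missing image for: ",
         paste(missing_img, collapse = ", "), "; missing mask for: ",
         paste(missing_msk, collapse = ", "), call. = FALSE)
  }
  patients <- lapply(seq_along(ids), function(i) {
    p <- list(image = read_volume(img_files[i]),
              mask = read_volume(msk_files[i], as_mask = TRUE))
    tf <- file.path(dir, "truth", paste0(ids[i], ".nii.gz"))
    if (file.exists(tf)) p$truth_labels <- round(read_volume(tf)$values)
    p
  })
  structure(list(patients = patients, clinical = clinical, truth = NULL,
                 spec = NULL),
            class = "habitat_cohort")
}
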