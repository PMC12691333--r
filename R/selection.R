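feature_columns <- function(table) {
  setdiff(names(table)[vapply(table, is.numeric, TRUE)],
          c("patient", "outcome", "split"))
}

# Two-way mixed-effects, absolute-agreement, single-measure ICC (ICC(A,1))
# from the two-way ANOVA mean squares of an n-subject x k-rater matrix.
icc_a1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  if (stats::sd(as.numeric(m)) < 1e-300) return(NA_real_)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < 1e-300) return(NA_real_)
  (msr - mse) / denom
}

#' Feature stability filtering by intraclass correlation
#'
#' Computes, per feature, the two-way mixed-effects absolute-agreement
#' single-measure ICC between two readers' feature tables (and, optionally,
#' between a reader's repeated extractions), and flags features passing the
#' stability threshold on every available ICC. Zero-variance features have
#' undefined ICC and fail.
#'
#' @param reader_a,reader_b feature tibbles with identical `patient` rows
#'   and feature columns (two readers' segmentations).
#' @param reader_a_repeat optional repeat extraction by reader A, for the
#'   intra-reader ICC.
#' @param threshold stability cutoff (features pass at ICC >= threshold).
#' @return tibble: `feature`, `icc_inter`, `icc_intra` (NA when no repeat
#'   given), `pass`.
#' @export
icc_filter <- function(reader_a, reader_b, reader_a_repeat = NULL,
                       threshold = 0.70) {
  stopifnot(identical(reader_a$patient, reader_b$patient))
  feats <- intersect(feature_columns(reader_a), feature_columns(reader_b))
  inter <- vapply(feats, function(f) icc_a1(cbind(reader_a[[f]], reader_b[[f]])),
                  numeric(1))
  intra <- if (!is.null(reader_a_repeat)) {
    vapply(feats, function(f) icc_a1(cbind(reader_a[[f]], reader_a_repeat[[f]])),
           numeric(1))
  } else rep(NA_real_, length(feats))
  pass <- !is.na(inter) & inter >= threshold &
    (is.na(intra) | intra >= threshold)
  if (!is.null(reader_a_repeat)) pass <- pass & !is.na(intra)
  tibble::tibble(feature = feats, icc_inter = inter, icc_intra = intra,
                 pass = pass)
}

#' Redundancy filtering on pairwise correlation
#'
#' Greedy elimination: features are ranked by outcome relevance (absolute
#' Pearson correlation with the binary outcome; by variance when no outcome
#' is supplied), tie-broken lexicographically, and scanned in order; a
#' feature is kept only if its absolute correlation with every already-kept
#' feature is at most `r_max`. The surviving set therefore has pairwise
#' |r| <= r_max.
#'
#' @param table feature tibble (numeric feature columns; optional `outcome`).
#' @param outcome optional 0/1 vector (defaults to `table$outcome`).
#' @param r_max correlation cutoff; features correlated above it are dropped.
#' @return character vector of surviving feature names.
#' @export
correlation_filter <- function(table, outcome = table[["outcome"]], r_max = 0.75) {
  feats <- sort(feature_columns(table))
  x <- as.matrix(table[, feats, drop = FALSE])
  keepable <- feats[apply(x, 2, function(v) stats::sd(v) > 0 && all(is.finite(v)))]
  x <- x[, keepable, drop = FALSE]
  rel <- if (!is.null(outcome)) {
    abs(suppressWarnings(stats::cor(x, outcome)))[, 1]
  } else {
    apply(scale(x), 2, stats::var)
  }
  ord <- keepable[order(-rel, keepable)]
  kept <- character(0)
  for (f in ord) {
    if (length(kept) == 0 ||
        all(abs(suppressWarnings(stats::cor(x[, f], x[, kept]))) <= r_max,
            na.rm = TRUE)) {
      kept <- c(kept, f)
    }
  }
  kept
}

quantile_bin <- function(x, n_bins = 4) {
  ux <- unique(x)
  if (length(ux) <= n_bins) return(as.integer(factor(x)))  # already discrete
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, br, include.lowest = TRUE))
}

mi_disc <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  idx <- tab > 0
  sum(tab[idx] * log(tab[idx] / outer(pa, pb)[idx]))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy mutual-information-difference (MID) ranking on quantile-discretized
#' features: at each step the feature maximizing
#' \eqn{I(f; y) - \mathrm{mean}_{s \in S} I(f; s)} over the already-selected
#' set S is added. Ties break by column order after a lexicographic sort.
#'
#' @param table feature tibble.
#' @param outcome binary outcome vector (defaults to `table$outcome`).
#' @param m number of features to rank.
#' @param n_bins discretization bins for mutual information.
#' @return character vector of `m` feature names in selection order.
#' @export
mrmr_rank <- function(table, outcome = table[["outcome"]], m = 50, n_bins = 4) {
  feats <- sort(feature_columns(table))
  m <- min(m, length(feats))
  disc <- lapply(table[feats], quantile_bin, n_bins = n_bins)
  rel <- vapply(feats, function(f) mi_disc(disc[[f]], outcome), numeric(1))
  selected <- character(0)
  red_sum <- stats::setNames(numeric(length(feats)), feats)
  for (step in seq_len(m)) {
    cand <- setdiff(feats, selected)
    score <- rel[cand] - if (length(selected)) red_sum[cand] / length(selected) else 0
    pick <- cand[which.max(score)]
    selected <- c(selected, pick)
    rest <- setdiff(cand, pick)
    if (length(rest)) {
      red_sum[rest] <- red_sum[rest] +
        vapply(rest, function(f) mi_disc(disc[[f]], disc[[pick]]), numeric(1))
    }
  }
  selected
}

stratified_folds <- function(outcome, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(outcome))
  for (cl in unique(outcome)) {
    idx <- sample(which(outcome == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' L1-penalized logistic feature selection
#'
#' Fits the LASSO logistic path (glmnet) with stratified cross-validation
#' and returns the features with nonzero coefficients at the chosen lambda.
#' The penalized coefficients are used directly (no refit), matching how a
#' radiomics score is assembled from the LASSO output.
#'
#' @param table feature tibble.
#' @param outcome binary outcome vector (defaults to `table$outcome`).
#' @param n_folds cross-validation folds (10 by default; 5 available).
#' @param seed integer seed (fold assignment).
#' @param lambda `"min"` (CV-deviance optimum, default), `"1se"`, or a fixed
#'   numeric penalty (no cross-validation).
#' @return a `lasso_selection`: `features`, `coefficients` (named, nonzero),
#'   `intercept`, `lambda`, `cv` tibble (lambda, deviance, nzero).
#' @export
lasso_select <- function(table, outcome = table[["outcome"]], n_folds = 10,
                         seed = 1L, lambda = "min") {
  feats <- sort(feature_columns(table))
  x <- as.matrix(table[, feats, drop = FALSE])
  if (is.numeric(lambda)) {
    fit <- glmnet::glmnet(x, outcome, family = "binomial", standardize = TRUE)
    co <- as.matrix(stats::coef(fit, s = lambda, exact = TRUE,
                                x = x, y = outcome))[, 1]
    lam <- lambda
    cv_tab <- tibble::tibble(lambda = fit$lambda, deviance = NA_real_,
                             nzero = as.integer(fit$df))
  } else {
    lambda <- match.arg(lambda, c("min", "1se"))
    foldid <- stratified_folds(outcome, n_folds, seed)
    cv <- glmnet::cv.glmnet(x, outcome, family = "binomial", foldid = foldid,
                            standardize = TRUE, type.measure = "deviance")
    lam <- if (lambda == "min") cv$lambda.min else cv$lambda.1se
    co <- as.matrix(stats::coef(cv$glmnet.fit, s = lam))[, 1]
    cv_tab <- tibble::tibble(lambda = cv$lambda, deviance = cv$cvm,
                             nzero = as.integer(cv$nzero))
  }
  nz <- co[-1][co[-1] != 0]
  structure(
    list(features = names(nz), coefficients = nz, intercept = co[1],
         lambda = lam, lambda_rule = lambda, cv = cv_tab),
    class = "lasso_selection"
  )
}

#' Full feature-selection pipeline
#'
#' Stability (ICC, when two readers are given) -> correlation redundancy
#' filter -> mRMR ranking -> LASSO, with strictly nested surviving sets.
#'
#' @param table training feature tibble (must contain `outcome`).
#' @param reader_b optional second-reader feature table for the ICC stage.
#' @param icc_threshold,r_max,mrmr_m,n_folds,seed,lambda stage parameters.
#' @return a `selection_result`: `stages` (named list of surviving feature
#'   names after icc, correlation, mrmr, lasso), `lasso` (the
#'   `lasso_selection`), and `model` (a [radscore_model()]).
#' @export
select_features <- function(table, reader_b = NULL, icc_threshold = 0.70,
                            r_max = 0.75, mrmr_m = 50, n_folds = 10,
                            seed = 1L, lambda = "min") {
  stopifnot("outcome" %in% names(table))
  stages <- list()
  tab <- table
  if (!is.null(reader_b)) {
    rep_icc <- icc_filter(table, reader_b, threshold = icc_threshold)
    keep <- rep_icc$feature[rep_icc$pass]
    stages$icc <- keep
    tab <- tab[, c("outcome", keep)]
  } else {
    stages$icc <- feature_columns(tab)
  }
  stages$correlation <- correlation_filter(tab, r_max = r_max)
  tab <- tab[, c("outcome", stages$correlation)]
  stages$mrmr <- mrmr_rank(tab, m = mrmr_m)
  tab <- tab[, c("outcome", stages$mrmr)]
  las <- lasso_select(tab, n_folds = n_folds, seed = seed, lambda = lambda)
  stages$lasso <- las$features
  structure(
    list(stages = stages, lasso = las,
         model = radscore_model(las$intercept, las$coefficients)),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> stages:",
      paste(sprintf("%s=%d", names(x$stages), lengths(x$stages)), collapse = " -> "),
      "\n")
  invisible(x)
}

#' Radiomics score models
#'
#' A radscore is a linear combination `intercept + sum(coef * feature)`.
#' `radscore_model()` builds one from an intercept and named coefficients;
#' `radscore_fixture()` loads one of the two published models shipped with
#' the package (`"paper_voi"`, the whole-tumor score with 6 features;
#' `"paper_sub"`, the subregional habitat score with 7 features);
#' `evaluate_radscore()` evaluates a model on a feature table or named
#' vector, erroring with the missing names if any model feature is absent.
#'
#' @param intercept scalar intercept.
#' @param coefficients named numeric vector.
#' @return a `radscore_model`.
#' @export
radscore_model <- function(intercept, coefficients) {
  stopifnot(!is.null(names(coefficients)), all(nzchar(names(coefficients))))
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients),
            class = "radscore_model")
}

#' @param name fixture name: `"paper_voi"` or `"paper_sub"`.
#' @rdname radscore_model
#' @export
radscore_fixture <- function(name = c("paper_voi", "paper_sub")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("radscore-", sub("_", "-", name), ".json"),
                      package = "habikit")
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  radscore_model(j$intercept, unlist(j$coefficients))
}

#' @param model a `radscore_model`.
#' @param features a data frame (one row per patient) or named numeric vector.
#' @rdname radscore_model
#' @export
evaluate_radscore <- function(model, features) {
  stopifnot(inherits(model, "radscore_model"))
  need <- names(model$coefficients)
  if (is.data.frame(features)) {
    missing <- setdiff(need, names(features))
    if (length(missing)) {
      stop("missing model features: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    x <- as.matrix(features[, need, drop = FALSE])
  } else {
    missing <- setdiff(need, names(features))
    if (length(missing)) {
      stop("missing model features: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    x <- matrix(features[need], nrow = 1)
  }
  as.numeric(model$intercept + x %*% model$coefficients)
}

#' @export
print.radscore_model <- function(x, ...) {
  cat("<radscore_model> intercept", format(x$intercept), "+",
      length(x$coefficients), "features\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.radscore_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @importFrom generics glance
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(n_icc = length(x$stages$icc),
                 n_correlation = length(x$stages$correlation),
                 n_mrmr = length(x$stages$mrmr),
                 n_selected = length(x$stages$lasso),
                 lambda = x$lasso$lambda)
}
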