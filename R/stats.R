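#' Stratified training/validation split
#'
#' Random split stratified by the binary outcome: within each outcome class,
#' `round(ratio * n_class)` patients go to training, the rest to validation,
#' under the given seed.
#'
#' @param table tibble with an `outcome` column.
#' @param ratio training fraction.
#' @param seed integer seed.
#' @return the table with a `split` column (`"training"` / `"validation"`).
#' @export
split_cohort <- function(table, ratio = 0.7, seed = 1L) {
  stopifnot(nrow(table) >= 10, "outcome" %in% names(table))
  set.seed(seed)
  split <- rep("validation", nrow(table))
  for (cl in unique(table$outcome)) {
    idx <- sample(which(table$outcome == cl))
    n_tr <- round(ratio * length(idx))
    split[idx[seq_len(n_tr)]] <- "training"
  }
  dplyr::mutate(table, split = split)
}

#' Between-group comparison of cohort characteristics
#'
#' Mann-Whitney U test for continuous variables; chi-squared test for
#' categorical variables, replaced by Fisher's exact test whenever any
#' expected cell count is below 5. Variables with more than `cont_cutoff`
#' distinct numeric values are treated as continuous.
#'
#' @param table tibble of per-patient variables.
#' @param group name of the two-level grouping column (default `"split"`).
#' @param vars variables to compare (default: all except identifiers,
#'   outcome and the group).
#' @param cont_cutoff distinct-value threshold for continuous treatment.
#' @return tibble: `variable`, `type`, `test`, `statistic`, `p_value`.
#' @export
cohort_compare <- function(table, group = "split", vars = NULL,
                           cont_cutoff = 6L) {
  g <- factor(table[[group]])
  stopifnot(nlevels(g) == 2, all(table(g) > 0))
  if (is.null(vars)) {
    vars <- setdiff(names(table), c("patient", "outcome", group))
  }
  rows <- lapply(vars, function(v) {
    x <- table[[v]]
    if (is.numeric(x) && length(unique(x)) > cont_cutoff) {
      wt <- suppressWarnings(stats::wilcox.test(x ~ g, exact = FALSE, correct = TRUE))
      tibble::tibble(variable = v, type = "continuous", test = "mann-whitney",
                     statistic = unname(wt$statistic), p_value = wt$p.value)
    } else {
      tab <- table(factor(x), g)
      exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(exp_cells < 5)) {
        ft <- stats::fisher.test(tab)
        tibble::tibble(variable = v, type = "categorical", test = "fisher",
                       statistic = NA_real_, p_value = ft$p.value)
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        tibble::tibble(variable = v, type = "categorical", test = "chi-squared",
                       statistic = unname(ct$statistic), p_value = ct$p.value)
      }
    }
  })
  dplyr::bind_rows(rows)
}

check_separation <- function(fit) {
  probs <- stats::fitted(fit)
  isTRUE(any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)) ||
    any(probs > 1 - 1e-8) || any(probs < 1e-8)
}

#' Clinical risk model
#'
#' Maximum-likelihood logistic regression of the outcome on the four
#' dichotomized clinical risk factors: age >= 65, N2 stage, any gene
#' mutation, and EGFR mutation. Quasi-separation is detected and reported
#' (flag + warning), never silently.
#'
#' @param table clinical tibble with `outcome` and the four flag columns
#'   (`age_ge65`, `n2_stage`, `mutation_any`, `egfr`); typically the
#'   training split.
#' @param covariates covariate column names.
#' @return a `bm_model`: `fit` (the glm), `coefficients` tibble (estimate,
#'   std.error, odds ratio, p), `separation` flag, `aic`.
#' @export
fit_clinical_model <- function(table,
                               covariates = c("age_ge65", "n2_stage",
                                              "mutation_any", "egfr")) {
  stopifnot(all(c("outcome", covariates) %in% names(table)))
  fml <- stats::as.formula(paste("outcome ~", paste(covariates, collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = table)
  sep <- check_separation(fit)
  if (sep) warning("quasi-separation detected in clinical model fit")
  sm <- summary(fit)$coefficients
  structure(
    list(fit = fit,
         coefficients = tibble::tibble(
           term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
           odds_ratio = exp(sm[, 1]), p_value = sm[, 4]),
         separation = sep, aic = stats::AIC(fit)),
    class = "bm_model"
  )
}

#' Univariable logistic model on a radiomics score
#'
#' @param scores numeric score per patient (e.g. a radscore).
#' @param outcome 0/1 outcome vector.
#' @return a `bm_model` (see [fit_clinical_model()]).
#' @export
fit_score_model <- function(scores, outcome) {
  d <- data.frame(outcome = outcome, score = scores)
  fit <- stats::glm(outcome ~ score, family = stats::binomial(), data = d)
  sep <- check_separation(fit)
  if (sep) warning("quasi-separation detected in score model fit")
  sm <- summary(fit)$coefficients
  structure(
    list(fit = fit,
         coefficients = tibble::tibble(
           term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
           odds_ratio = exp(sm[, 1]), p_value = sm[, 4]),
         separation = sep, aic = stats::AIC(fit)),
    class = "bm_model"
  )
}

#' @export
print.bm_model <- function(x, ...) {
  cat("<bm_model> AIC", format(x$aic), if (x$separation) "(separation!)", "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.bm_model <- function(x, ...) x$coefficients

#' @export
glance.bm_model <- function(x, ...) {
  tibble::tibble(aic = x$aic, separation = x$separation,
                 n = length(stats::fitted(x$fit)))
}

# DeLong structural components via midranks. Returns AUC, and the per-case
# components V10 (positives) and V01 (negatives).
delong_components <- function(scores, outcome) {
  pos <- scores[outcome == 1]
  neg <- scores[outcome == 0]
  m <- length(pos); n <- length(neg)
  stopifnot(m > 0, n > 0)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' ROC evaluation of a score
#'
#' AUC by the Mann-Whitney identity (half credit for ties), a 95% CI from
#' the DeLong structural-component variance, the Youden-optimal operating
#' point (ties resolved toward higher specificity), accuracy at that point,
#' and the AIC of the univariable logistic fit of the outcome on the score.
#'
#' @param scores numeric predictions (higher = more likely positive).
#' @param outcome 0/1 outcome vector, both classes present.
#' @return one-row tibble: `auc`, `ci_low`, `ci_high`, `threshold`,
#'   `sensitivity`, `specificity`, `accuracy`, `aic`, `n_pos`, `n_neg`.
#' @export
evaluate_model <- function(scores, outcome) {
  dc <- delong_components(scores, outcome)
  v <- stats::var(dc$v10) / dc$m + stats::var(dc$v01) / dc$n
  ci <- pmin(1, pmax(0, dc$auc + c(-1, 1) * stats::qnorm(0.975) * sqrt(v)))
  roc <- roc_curve(scores, outcome)
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j == max(j))
  best <- best[which.max(roc$specificity[best])]
  thr <- roc$threshold[best]
  pred <- as.integer(scores >= thr)
  acc <- mean(pred == outcome)
  aic <- tryCatch(fit_score_model(scores, outcome)$aic, warning = function(w) {
    suppressWarnings(fit_score_model(scores, outcome)$aic)
  })
  tibble::tibble(auc = dc$auc, ci_low = ci[1], ci_high = ci[2],
                 threshold = thr, sensitivity = roc$sensitivity[best],
                 specificity = roc$specificity[best], accuracy = acc,
                 aic = aic, n_pos = dc$m, n_neg = dc$n)
}

#' ROC curve coordinates
#'
#' @inheritParams evaluate_model
#' @return tibble: `threshold`, `sensitivity`, `specificity`, one row per
#'   distinct score cutoff (prediction positive when `score >= threshold`).
#' @export
roc_curve <- function(scores, outcome) {
  thr <- c(sort(unique(scores)), Inf)
  pos <- outcome == 1
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  tibble::tibble(threshold = thr, sensitivity = sens, specificity = spec)
}

#' DeLong's test for two correlated AUCs
#'
#' Paired comparison of two scores on the same patients: the difference in
#' AUCs divided by the DeLong structural-component variance of the
#' difference, referred to a standard normal (two-sided). Identical ranks
#' give Z = 0, p = 1.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param outcome shared 0/1 outcome.
#' @return one-row tibble: `auc_a`, `auc_b`, `auc_diff`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, outcome) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(outcome))
  a <- delong_components(scores_a, outcome)
  b <- delong_components(scores_b, outcome)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / a$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / a$n
  d <- a$auc - b$auc
  if (v < 1e-300) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(auc_a = a$auc, auc_b = b$auc, auc_diff = d, z = z, p_value = p)
}

#' Calibration curve
#'
#' Bins predicted probabilities into `n_bins` equal-width bins over `[0,1]`
#' and reports the mean prediction and observed event rate per occupied bin.
#'
#' @param probabilities predicted probabilities in `[0,1]`.
#' @param outcome 0/1 outcome vector.
#' @param n_bins number of bins.
#' @return tibble: `bin`, `n`, `mean_predicted`, `observed_rate`.
#' @export
calibration_curve <- function(probabilities, outcome, n_bins = 10) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  bin <- pmin(n_bins, floor(probabilities * n_bins) + 1L)
  tibble::tibble(p = probabilities, y = outcome, bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(), mean_predicted = mean(.data$p),
                     observed_rate = mean(.data$y), .groups = "drop")
}

#' Decision curve analysis
#'
#' Net benefit of treating at probability threshold `pt`:
#' `NB(pt) = TP/n - (FP/n) * pt/(1-pt)`, against the treat-all policy
#' `prev - (1-prev) * pt/(1-pt)` and treat-none (zero).
#'
#' @param probabilities predicted probabilities.
#' @param outcome 0/1 outcome vector.
#' @param thresholds probability thresholds to evaluate.
#' @return tibble: `threshold`, `net_benefit`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(probabilities, outcome,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  n <- length(outcome)
  prev <- mean(outcome)
  rows <- lapply(thresholds, function(pt) {
    treat <- probabilities >= pt
    tp <- sum(treat & outcome == 1)
    fp <- sum(treat & outcome == 0)
    w <- pt / (1 - pt)
    tibble::tibble(threshold = pt,
                   net_benefit = tp / n - (fp / n) * w,
                   treat_all = prev - (1 - prev) * w,
                   treat_none = 0)
  })
  dplyr::bind_rows(rows)
}
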