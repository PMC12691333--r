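sim_feature_table <- function(n = 60, p = 8, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  tibble::tibble(patient = paste0("P", seq_len(n))) |>
    dplyr::bind_cols(tibble::as_tibble(x))
}

test_that("ICC: perfect agreement, pure noise, brute-force mean squares", {
  ta <- sim_feature_table(40, 6, seed = 2)
  rep <- icc_filter(ta, ta)
  expect_equal(unname(rep$icc_inter), rep(1, 6), tolerance = 1e-12)
  expect_true(all(rep$pass))

  tb <- sim_feature_table(40, 6, seed = 3)   # independent noise
  rep2 <- icc_filter(ta, tb)
  expect_lt(mean(abs(rep2$icc_inter)), 0.3)
  expect_false(any(rep2$pass))

  # 6-patient hand check against the two-way ANOVA mean-squares formula
  a <- c(9, 6, 8, 7, 10, 6); b <- c(2, 1, 4, 1, 5, 2)
  m <- cbind(a, b); n <- 6; k <- 2
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  mse <- (sum((m - outer(rowMeans(m), rep(1, k)) -
                 outer(rep(1, n), colMeans(m)) + grand)^2)) / ((n - 1) * (k - 1))
  expected <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  ta6 <- tibble::tibble(patient = 1:6, f = a)
  tb6 <- tibble::tibble(patient = 1:6, f = b)
  expect_equal(unname(icc_filter(ta6, tb6)$icc_inter), expected, tolerance = 1e-12)

  # zero-variance feature fails with undefined ICC
  tz <- ta; tz$f01 <- 1; tz2 <- tb; tz2$f01 <- 1
  repz <- icc_filter(tz, tz2)
  expect_true(is.na(repz$icc_inter[repz$feature == "f01"]))
  expect_false(repz$pass[repz$feature == "f01"])
})

test_that("correlation filter: duplicates, orthogonality, block structure", {
  tab <- sim_feature_table(50, 4, seed = 4)
  tab$dup <- tab$f01
  kept <- correlation_filter(tab)
  expect_equal(sum(c("f01", "dup") %in% kept), 1L)

  ortho <- tibble::tibble(a = rep(c(1, -1), 10), b = rep(c(1, 1, -1, -1), 5),
                          c = rnorm(20))
  expect_setequal(correlation_filter(ortho), c("a", "b", "c"))

  set.seed(5)
  base <- matrix(rnorm(3 * 80), 80, 3)
  blocks <- do.call(cbind, lapply(1:3, function(j) {
    sapply(1:5, function(i) base[, j] + rnorm(80, 0, 0.2))
  }))
  colnames(blocks) <- sprintf("g%02d", 1:15)
  btab <- tibble::as_tibble(blocks)
  kept <- correlation_filter(btab, r_max = 0.75)
  expect_equal(length(kept), 3L)
  # post-hoc certificate: pairwise |r| <= 0.75, exhaustively
  cm <- abs(cor(btab[, kept]))
  expect_true(all(cm[upper.tri(cm)] <= 0.75))
})

test_that("mRMR: relevance first, redundancy punished, greedy = exhaustive", {
  set.seed(6)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  tab <- tibble::tibble(
    exact = as.numeric(y),
    inform = y + rnorm(n, 0, 0.7),
    noise1 = rnorm(n), noise2 = rnorm(n)
  )
  r <- mrmr_rank(tab, outcome = y, m = 4)
  expect_equal(r[1], "exact")

  # an exact duplicate of a strong (noisy) predictor is maximally redundant:
  # an independent informative feature is preferred at step two
  a <- rnorm(n); b <- rnorm(n)
  y2 <- rbinom(n, 1, plogis(2 * a + 2 * b))
  tab2 <- tibble::tibble(strong = a, copy_of_strong = a, other = b,
                         noise = rnorm(n))
  r2 <- mrmr_rank(tab2, outcome = y2, m = 3)
  expect_true(r2[1] %in% c("strong", "copy_of_strong"))
  expect_equal(r2[2], "other")

  # every greedy step matches exhaustive evaluation of the MID criterion
  set.seed(7)
  small <- tibble::tibble(a = rnorm(40), b = rnorm(40), c = rnorm(40), d = rnorm(40))
  ys <- rbinom(40, 1, plogis(small$a))
  picked <- mrmr_rank(small, outcome = ys, m = 4, n_bins = 3)
  qb <- function(x) as.integer(cut(x, unique(quantile(x, 0:3 / 3)), include.lowest = TRUE))
  mi <- function(u, v) {
    tab <- table(u, v) / length(u)
    pu <- rowSums(tab); pv <- colSums(tab)
    s <- 0
    for (i in seq_along(pu)) for (j in seq_along(pv)) {
      if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (pu[i] * pv[j]))
    }
    s
  }
  dd <- lapply(small, qb)
  sel <- character(0)
  for (step in 1:4) {
    cand <- setdiff(sort(names(small)), sel)
    sc <- sapply(cand, function(f) {
      mi(dd[[f]], ys) - if (length(sel)) mean(sapply(sel, function(s2) mi(dd[[f]], dd[[s2]]))) else 0
    })
    sel <- c(sel, cand[which.max(sc)])
  }
  expect_identical(picked, sel)
})

test_that("LASSO: shrinkage limit, near-unpenalized equivalence, determinism", {
  set.seed(8)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.4 + 1.2 * x1 - 0.8 * x2))
  tab <- tibble::tibble(x1 = x1, x2 = x2, x3 = x3)

  big <- lasso_select(tab, outcome = y, n_folds = 5, seed = 1, lambda = 1e6)
  expect_length(big$features, 0)
  expect_equal(unname(big$intercept), qlogis(mean(y)), tolerance = 1e-6)

  tiny <- lasso_select(tab, outcome = y, n_folds = 5, seed = 1, lambda = 1e-7)
  ml <- glm(y ~ x1 + x2 + x3, family = binomial())
  expect_equal(unname(tiny$coefficients[c("x1", "x2", "x3")]),
               unname(coef(ml)[c("x1", "x2", "x3")]), tolerance = 1e-4)

  a <- lasso_select(tab, outcome = y, n_folds = 10, seed = 5)
  b <- lasso_select(tab, outcome = y, n_folds = 10, seed = 5)
  expect_identical(a$features, b$features)
  expect_identical(a$coefficients, b$coefficients)
})

test_that("selection pipeline produces strictly nested stages", {
  set.seed(9)
  n <- 80
  x <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, sprintf("v%02d", 1:30)))
  x[, 2] <- x[, 1] + rnorm(n, 0, 0.1)     # redundant pair
  y <- rbinom(n, 1, plogis(x[, 1] - x[, 5]))
  tab <- dplyr::bind_cols(tibble::tibble(outcome = y), tibble::as_tibble(x))
  res <- select_features(tab, mrmr_m = 10, n_folds = 5, seed = 3)
  st <- res$stages
  expect_true(all(st$correlation %in% st$icc))
  expect_true(all(st$mrmr %in% st$correlation))
  expect_true(all(st$lasso %in% st$mrmr))
  expect_lte(length(st$correlation), length(st$icc) - 1)  # dropped the duplicate
  g <- glance(res)
  expect_equal(g$n_selected, length(st$lasso))
})

test_that("radscore models evaluate linearly and validate inputs", {
  m <- radscore_model(2, c(a = 1.5, b = -2))
  expect_equal(evaluate_radscore(m, c(a = 0, b = 0)), 2)
  x0 <- c(a = 0.3, b = 1.1)
  x1 <- x0; x1["a"] <- x0["a"] + 0.25
  expect_equal(evaluate_radscore(m, x1) - evaluate_radscore(m, x0), 1.5 * 0.25)
  expect_error(evaluate_radscore(m, c(a = 1)), "missing model features: b")

  tb <- tibble::tibble(a = c(0, 1), b = c(0, 1), junk = c(9, 9))
  expect_equal(evaluate_radscore(m, tb), c(2, 2 + 1.5 - 2))
  td <- tidy(m)
  expect_equal(td$estimate[td$term == "(Intercept)"], 2)
})

test_that("published score fixtures load with their printed coefficients", {
  voi <- radscore_fixture("paper_voi")
  expect_length(voi$coefficients, 6)
  expect_equal(unname(voi$coefficients["log.sigma.4.0.mm.3D_glcm_Idn"]),
               37.5565903019046)
  sub <- radscore_fixture("paper_sub")
  expect_length(sub$coefficients, 7)
  expect_equal(
    unname(sub$coefficients["Sub3_wavelet.LHH_glszm_LargeAreaLowGrayLevelEmphasis"]),
    1.21232489590441e-8)
})
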