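test_that("stratified split hits the target sizes and is deterministic", {
  set.seed(1)
  tab <- tibble::tibble(patient = 1:195, outcome = rbinom(195, 1, 0.4))
  sp <- split_cohort(tab, ratio = 0.7, seed = 9)
  n_tr <- sum(sp$split == "training")
  expect_true(n_tr >= 136 && n_tr <= 138)
  prev_all <- mean(tab$outcome)
  prev_tr <- mean(sp$outcome[sp$split == "training"])
  expect_lt(abs(prev_tr * n_tr - prev_all * n_tr), 1.5)  # within one patient
  sp2 <- split_cohort(tab, ratio = 0.7, seed = 9)
  expect_identical(sp$split, sp2$split)
  expect_false(identical(sp$split, split_cohort(tab, ratio = 0.7, seed = 10)$split))
})

test_that("group comparison: no-difference, Fisher enumeration, chi-squared formula", {
  tab <- tibble::tibble(
    split = rep(c("training", "validation"), each = 20),
    age = rep(c(60, 65, 70, 75, 80), 8),
    sexm = rep(c(0, 1), 20)
  )
  cmp <- cohort_compare(tab, vars = c("age", "sexm"))
  expect_equal(cmp$p_value[cmp$variable == "age"], 1, tolerance = 1e-9)
  # balanced 20/20 groups: all expected cells 10 >= 5, chi-squared applies
  expect_equal(cmp$test[cmp$variable == "sexm"], "chi-squared")
  expect_equal(cmp$p_value[cmp$variable == "sexm"], 1, tolerance = 1e-9)

  # Fisher 2x2 (3,1;1,3) against hypergeometric enumeration over all tables
  t22 <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(fisher.test(t22)$p.value, oracle_fisher_2x2(t22), tolerance = 1e-10)
  g <- rep(c("a", "b"), each = 4)
  x <- c(1, 1, 1, 0, 1, 0, 0, 0)
  cmp2 <- cohort_compare(tibble::tibble(split = g, x = x), vars = "x")
  expect_equal(cmp2$p_value, oracle_fisher_2x2(t22), tolerance = 1e-10)

  # chi-squared with all expected counts >= 5 matches sum((O-E)^2/E)
  g2 <- rep(c("a", "b"), c(40, 40))
  x2 <- c(rep(1, 25), rep(0, 15), rep(1, 12), rep(0, 28))
  O <- table(x2, g2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum((O - E)^2 / E)
  cmp3 <- cohort_compare(tibble::tibble(split = g2, x = x2), vars = "x")
  expect_equal(cmp3$test, "chi-squared")
  expect_equal(cmp3$statistic, stat, tolerance = 1e-10)
})

test_that("clinical model recovers generating coefficients within 2 SE", {
  set.seed(21)
  n <- 2000
  tab <- tibble::tibble(
    age_ge65 = rbinom(n, 1, 0.5), n2_stage = rbinom(n, 1, 0.3),
    mutation_any = rbinom(n, 1, 0.6), egfr = rbinom(n, 1, 0.45)
  )
  beta <- c(0.6, 0.9, 0.5, -0.4)
  eta <- -1 + as.matrix(tab) %*% beta
  tab$outcome <- rbinom(n, 1, plogis(eta))
  fit <- fit_clinical_model(tab)
  co <- fit$coefficients
  for (i in seq_along(beta)) {
    row <- co[co$term == names(tab)[i], ]
    expect_lt(abs(row$estimate - beta[i]), 2 * row$std_error)
  }
  expect_false(fit$separation)

  # quasi-separation is detected, not silent
  tab2 <- tibble::tibble(age_ge65 = c(rep(0, 30), rep(1, 30)),
                         n2_stage = 0, mutation_any = 0, egfr = 0,
                         outcome = c(rep(0, 30), rep(1, 30)))
  w <- capture_warnings(fit2 <- fit_clinical_model(tab2))
  expect_true(any(grepl("separation", w)))
  expect_true(fit2$separation)
})

test_that("score model is calibrated when the score is the true log-odds", {
  set.seed(22)
  n <- 5000
  s <- rnorm(n)
  y <- rbinom(n, 1, plogis(s))
  fit <- fit_score_model(s, y)
  co <- fit$coefficients
  expect_lt(abs(co$estimate[co$term == "score"] - 1), 0.1)
  expect_lt(abs(co$estimate[co$term == "(Intercept)"]), 0.1)

  # outcome-independent score: AUC near 1/2; monotone transform invariance
  s0 <- rnorm(500); y0 <- rbinom(500, 1, 0.4)
  expect_lt(abs(evaluate_model(s0, y0)$auc - 0.5), 0.1)
  ev1 <- evaluate_model(s0, y0)
  ev2 <- evaluate_model(exp(3 * s0), y0)
  expect_equal(ev1$auc, ev2$auc)
})

test_that("ROC evaluation: separation, pair counting, label flip", {
  ev <- evaluate_model(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(ev$auc, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)

  s <- c(0.1, 0.4, 0.35, 0.8); y <- c(0, 0, 1, 1)
  expect_equal(evaluate_model(s, y)$auc, oracle_auc(s, y))
  set.seed(23)
  s2 <- sample(1:6, 40, replace = TRUE)  # heavy ties
  y2 <- rbinom(40, 1, 0.5)
  expect_equal(evaluate_model(s2, y2)$auc, oracle_auc(s2, y2), tolerance = 1e-12)
  expect_equal(evaluate_model(-s2, y2)$auc, 1 - oracle_auc(s2, y2), tolerance = 1e-12)
  expect_true(ev$ci_low <= ev$auc && ev$auc <= ev$ci_high)
})

test_that("DeLong test: identity, rank invariance, sign convention", {
  set.seed(24)
  s <- rnorm(60); y <- rbinom(60, 1, 0.5)
  d0 <- delong_test(s, s, y)
  expect_equal(d0$z, 0)
  expect_equal(d0$p_value, 1)
  d1 <- delong_test(s, plogis(2 * s), y)   # monotone transform: same ranks
  expect_equal(d1$z, 0)

  sa <- y + rnorm(60, 0, 0.5)   # informative
  sb <- rnorm(60)               # noise
  d2 <- delong_test(sa, sb, y)
  expect_equal(sign(d2$z), sign(d2$auc_a - d2$auc_b))
  expect_gt(d2$auc_a, d2$auc_b)
})

test_that("calibration curve bins form a partition and converge when calibrated", {
  set.seed(25)
  p <- runif(20000)
  y <- rbinom(20000, 1, p)
  cc <- calibration_curve(p, y, n_bins = 10)
  expect_equal(sum(cc$n), 20000)
  expect_lt(max(abs(cc$mean_predicted - cc$observed_rate)), 0.04)

  cc2 <- calibration_curve(rep(0.35, 100), rbinom(100, 1, 0.35), n_bins = 10)
  expect_equal(nrow(cc2), 1)
  expect_equal(cc2$mean_predicted, 0.35)
})

test_that("decision curve: perfect model, treat-all limit, random bound", {
  y <- c(rep(1, 30), rep(0, 70))
  p_perfect <- as.numeric(y)
  dc <- decision_curve(p_perfect, y, thresholds = c(0.1, 0.5, 0.9))
  expect_equal(dc$net_benefit, rep(0.3, 3))
  expect_equal(dc$treat_all[1], 0.3 - 0.7 * (0.1 / 0.9))
  expect_lt(abs(dc$treat_all[dc$threshold == 0.1] - 0.3), 0.08)

  set.seed(26)
  pr <- runif(4000); yr <- rbinom(4000, 1, 0.3)
  dcr <- decision_curve(pr, yr)
  expect_true(all(dcr$net_benefit <= pmax(dcr$treat_all, 0) + 0.03))
})

test_that("structural-component AUC equals pair-counting AUC exactly", {
  set.seed(27)
  for (i in 1:10) {
    s <- sample(seq(0, 1, 0.1), 30, replace = TRUE)
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    dc <- habikit:::delong_components(s, y)
    expect_equal(dc$auc, mean(dc$v10))
    expect_equal(dc$auc, oracle_auc(s, y), tolerance = 1e-12)
  }
})

test_that("AIC drops when an informative score joins an intercept-only model", {
  set.seed(28)
  n <- 400
  s <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * s))
  fit <- fit_score_model(s, y)
  aic0 <- AIC(glm(y ~ 1, family = binomial()))
  expect_lt(fit$aic, aic0)
  ev <- evaluate_model(s, y)
  expect_equal(ev$aic, fit$aic)
})

test_that("DeLong Z and CI agree with an independent ROC implementation", {
  set.seed(29)
  n <- 80
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(z))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  sa <- z + rnorm(n, 0, 0.8)
  sb <- rnorm(n)
  ours <- delong_test(sa, sb, y)
  ra <- pROC::roc(y, sa, quiet = TRUE, direction = "<", levels = c(0, 1))
  rb <- pROC::roc(y, sb, quiet = TRUE, direction = "<", levels = c(0, 1))
  ref <- pROC::roc.test(ra, rb, method = "delong")
  expect_equal(unname(ours$z), unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)

  ev <- evaluate_model(sa, y)
  ci <- pROC::ci.auc(ra, method = "delong")
  expect_equal(ev$auc, as.numeric(ci[2]), tolerance = 1e-12)
  expect_equal(ev$ci_low, max(0, as.numeric(ci[1])), tolerance = 1e-10)
})
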