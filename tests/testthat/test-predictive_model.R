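# Small synthetic logistic datasets used across the model tests.
make_logit_data <- function(n, beta, seed) {
  set.seed(seed)
  x <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  eta <- beta[1] * x$x1 + beta[2] * x$x2 + beta[3] * x$x3
  y <- rbinom(n, 1, plogis(eta))
  list(x = x, y = y)
}

test_that("logistic fit satisfies the information-criterion identities", {
  d <- make_logit_data(80, c(1.2, 0, 0), seed = 30)
  fit <- fit_logistic_ml(d$x, d$y)
  k <- length(fit$features) + 1
  expect_equal(fit$aic, 2 * k - 2 * fit$loglik)
  expect_equal(fit$bic, k * log(fit$n) - 2 * fit$loglik)
  expect_equal(fit$aic, AIC(fit$fit))
  expect_equal(fit$bic, BIC(fit$fit))
})

test_that("one-feature coefficients match a likelihood grid optimum", {
  set.seed(31)
  x <- data.frame(x1 = c(-2.1, -1.5, -1, -0.4, -0.2, 0.1,
                         0.3, 0.8, 1.2, 1.7, 2.0, 2.4))
  y <- c(0, 0, 0, 1, 0, 0, 1, 0, 1, 1, 1, 1)
  fit <- fit_logistic_ml(x, y)
  # brute-force profile over (intercept, slope)
  grid <- expand.grid(b0 = seq(-3, 3, by = 0.002),
                      b1 = seq(0, 4, by = 0.002))
  loglik <- mapply(function(b0, b1) {
    eta <- b0 + b1 * x$x1
    sum(y * eta - log1p(exp(eta)))
  }, grid$b0, grid$b1)
  best <- grid[which.max(loglik), ]
  expect_equal(unname(coef(fit$fit)[1]), best$b0, tolerance = 5e-3)
  expect_equal(unname(coef(fit$fit)[2]), best$b1, tolerance = 5e-3)
})

test_that("degenerate designs are flagged or rejected", {
  # perfectly separating feature: AUC 1 and a separation warning
  x <- data.frame(x1 = c(1:6, 101:106))
  y <- rep(c(0, 1), each = 6)
  expect_warning(fit <- fit_logistic_ml(x, y), "separation")
  expect_equal(fit$auc, 1.0)
  expect_true(fit$separation)
  # intercept-only on balanced outcomes
  fit0 <- fit_logistic_ml(data.frame(row.names = 1:40),
                          rep(c(0, 1), 20))
  expect_equal(unname(coef(fit0$fit)[1]), 0, tolerance = 1e-8)
  expect_equal(fit0$auc, 0.5)
  expect_error(fit_logistic_ml(data.frame(x1 = rep(1, 10)),
                               rep(c(0, 1), 5)), "constant")
  d <- make_logit_data(30, c(1, 0, 0), seed = 1)
  d$x$x2 <- d$x$x1
  expect_error(fit_logistic_ml(d$x, d$y), "singular")
})

test_that("rank-based AUC equals the exhaustive pairwise oracle", {
  expect_equal(roc_auc(1:10, c(rep(0, 5), rep(1, 5))), 1.0)
  expect_equal(roc_auc(10:1, c(rep(0, 5), rep(1, 5))), 0.0)
  set.seed(33)
  for (i in 1:10) {
    scores <- sample(1:8, 16, replace = TRUE)   # plenty of ties
    y <- rbinom(16, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(scores, y), oracle_auc(scores, y))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both outcome classes")
})

test_that("forward selection gates on significance and ranks by AUC", {
  # informative x1, weaker x2, noise x3
  d <- make_logit_data(150, c(2, 0.7, 0), seed = 34)
  sel <- forward_select(c("x1", "x2", "x3"), d$x, d$y)
  expect_equal(sel$selected[1], "x1")
  expect_true(all(sel$trace$wald_p < 0.05))
  expect_false("x3" %in% sel$selected)
  # whitelist restricts and orders the pool
  sel_w <- forward_select(c("x1", "x2", "x3"), d$x, d$y,
                          whitelist = c("x2"))
  expect_equal(sel_w$selected, "x2")
  # alpha = 1 disables the gate: greedy AUC ordering of all candidates
  sel_all <- forward_select(c("x1", "x2", "x3"), d$x, d$y, alpha = 1)
  expect_setequal(sel_all$selected, c("x1", "x2", "x3"))
  expect_equal(sel_all$selected[1], "x1")
  # empty candidate list returns the base spec
  expect_equal(forward_select(character(0), d$x, d$y)$selected,
               character(0))
})

test_that("null candidates are rarely selected at alpha = 0.05", {
  picked <- vapply(1:30, function(s) {
    d <- make_logit_data(60, c(0, 0, 0), seed = 400 + s)
    length(forward_select(c("x1", "x2", "x3"), d$x, d$y)$selected) == 0
  }, logical(1))
  expect_gte(mean(picked), 0.75)
})

test_that("cross-validated AUC reflects true separability", {
  d <- make_logit_data(120, c(3, 0, 0), seed = 36)
  cv <- kfold_cv_auc("x1", d$x, d$y, k = 5, seed = 1)
  expect_gt(cv, 0.85)
  # shuffled labels: chance-level CV AUC on average
  nulls <- vapply(1:20, function(s) {
    set.seed(600 + s)
    kfold_cv_auc("x1", d$x, sample(d$y), k = 5, seed = s)
  }, numeric(1))
  expect_lt(abs(mean(nulls) - 0.5), 0.1)
  # leave-one-out path runs and returns a pooled AUC
  small <- make_logit_data(16, c(2, 0, 0), seed = 37)
  loo <- kfold_cv_auc("x1", small$x, small$y, k = 16, seed = 1)
  expect_true(is.finite(loo))
  expect_error(kfold_cv_auc("x1", d$x, d$y, k = 1), "k must")
})

test_that("likelihood-ratio test separates signal from noise additions", {
  d <- make_logit_data(200, c(1.5, 0.8, 0), seed = 38)
  base <- fit_logistic_ml(d$x[, "x1", drop = FALSE], d$y)
  aug_signal <- fit_logistic_ml(d$x[, c("x1", "x2")], d$y)
  aug_noise <- fit_logistic_ml(d$x[, c("x1", "x3")], d$y)
  expect_lt(lr_test_add_feature(base, aug_signal), 0.01)
  expect_gt(lr_test_add_feature(base, aug_noise), 0.01)
  # identical log-likelihood: p = 1
  same <- base
  same$features <- c("x1", "dummy")
  expect_equal(lr_test_add_feature(base, same), 1)
  expect_error(lr_test_add_feature(aug_signal, base), "nested|adds no")
  # null calibration: adding pure noise gives roughly uniform p
  ps <- vapply(1:40, function(s) {
    dn <- make_logit_data(120, c(1, 0, 0), seed = 700 + s)
    b <- fit_logistic_ml(dn$x[, "x1", drop = FALSE], dn$y)
    a <- fit_logistic_ml(dn$x[, c("x1", "x3")], dn$y)
    lr_test_add_feature(b, a)
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("permutation empiric p has the add-one floor and preserves counts", {
  d <- make_logit_data(60, c(3, 0, 0), seed = 39)
  res <- permutation_auc_p("x1", d$x, d$y, n_perm = 99, seed = 1)
  expect_equal(res$empiric_p, 1 / 100)   # minimum attainable
  expect_gt(res$auc, 0.85)
  # permutations preserve class counts by construction (sample() of y)
  set.seed(2)
  expect_equal(sum(sample(d$y)), sum(d$y))
  expect_error(permutation_auc_p("x1", d$x, d$y, n_perm = 50), "99")
})

test_that("model-score stratification recovers survival structure", {
  set.seed(40)
  n <- 150
  x <- data.frame(x1 = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * x$x1))
  fit <- fit_logistic_ml(x, y)
  # hazard tied to the true linear predictor
  os <- rexp(n, rate = 0.02 * exp(1.2 * x$x1))
  surv <- data.frame(os_months = os, os_event = 1,
                     pfs_months = os * 0.6, pfs_event = 1)
  out <- stratify_by_model_score(fit, x, surv)
  expect_lt(out$os$p, 0.01)
  expect_lt(out$pfs$p, 0.01)
  expect_equal(levels(out$score_group), c("low", "high"))
  # one-subject group is an error
  tiny_fit <- fit_logistic_ml(data.frame(x1 = c(-9, -8, 9, 9.1)),
                              c(0, 0, 1, 1))
  expect_error(
    stratify_by_model_score(tiny_fit,
                            data.frame(x1 = c(1, 1, 1, 2)),
                            surv[1:4, ]),
    "fewer than 2")
})

test_that("cross-subgroup application harness runs and reports", {
  cfg <- default_sim_config(n_patients = 120, n_genes = 800,
                            mhc2_effect_size = 1)
  b <- simulate_cohort(cfg, seed = 41)
  fe <- cohort_features(b)
  fe <- fe[!is.na(fe$mhc2_ssgsea), ]
  ipi <- fe$prior_ipilimumab
  fit_ipi <- fit_logistic_ml(fe[ipi, "mhc2_ssgsea", drop = FALSE],
                             fe$pd[ipi])
  # apply the ipi-experienced model to the naive subgroup and report AUC
  score <- predict(fit_ipi$fit, newdata = fe[!ipi, , drop = FALSE],
                   type = "response")
  cross_auc <- roc_auc(score, fe$pd[!ipi])
  expect_true(is.finite(cross_auc))
  expect_gte(cross_auc, 0)
  expect_lte(cross_auc, 1)
})
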