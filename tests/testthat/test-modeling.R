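test_that("split sizes follow floor-plus-remainder-to-train rounding", {
  s <- split_data(1000, c(0.65, 0.10, 0.25), seed = 1)
  expect_equal(as.integer(table(s)), c(650L, 100L, 250L))
  s <- split_data(1056, c(0.65, 0.10, 0.25), seed = 1)
  expect_equal(as.integer(table(s)), c(687L, 105L, 264L))
  s <- split_data(100, c(0.8, 0.2, 0), seed = 1)
  expect_equal(as.integer(table(s)), c(80L, 20L, 0L))
  expect_identical(split_data(500, seed = 7), split_data(500, seed = 7))
  expect_false(identical(split_data(500, seed = 7), split_data(500, seed = 8)))
  expect_error(split_data(10, c(0.9, 0.2, -0.1)), "configuration error")
  expect_error(split_data(10, c(0.5, 0.1, 0.1)), "configuration error")
})

test_that("zero-noise refits recover the reference coefficients exactly", {
  cfg <- synth_config(n_cells = 1056, noise_sd = 0, donor_shift_sd = 0,
                      seed = 2)
  tab <- generate_feature_table(cfg)$table
  rm <- reference_model()
  fit <- fit_linear(tab, rm)
  expect_equal(unname(fit$spec$estimates), unname(rm$estimates),
               tolerance = 1e-7)
  expect_true(all(fit$vifs[-1] >= 1))
  expect_true(is.na(fit$vifs[1]))
  # t = estimate / SE identity
  expect_equal(fit$t_ratios, fit$spec$estimates / fit$std_errors)
  expect_true(all(fit$p_values >= 0 & fit$p_values <= 1))
})

test_that("uncorrelated predictors have VIF 1 and duplicates raise RankError", {
  n <- 64
  tab <- data.frame(x1 = rep(c(-1, 1), n / 2),
                    x2 = rep(c(-1, -1, 1, 1), n / 4),
                    y = rnorm(n))
  spec <- model_spec(list(model_term(), model_term("x1"), model_term("x2")),
                     response = "y")
  fit <- fit_linear(tab, spec, response = "y")
  expect_equal(unname(fit$vifs[-1]), c(1, 1), tolerance = 1e-12)

  tab$x3 <- tab$x1
  spec2 <- model_spec(list(model_term(), model_term("x1"), model_term("x3")),
                      response = "y")
  expect_error(fit_linear(tab, spec2, response = "y"), "RankError")
})

test_that("95% t-intervals achieve nominal coverage", {
  # simulate from a small spec with Gaussian noise; coverage of the slope
  set.seed(99)
  centers <- c(a = 1, b = 2)
  spec <- model_spec(list(model_term(), model_term("a"),
                          model_term(c("a", "b"), centers)),
                     estimates = c(0.5, -1, 2), response = "y")
  slope_hits <- vapply(1:500, function(i) {
    tab <- data.frame(a = rnorm(60, 1, 1), b = rnorm(60, 2, 1))
    tab$y <- predict(spec, tab) + rnorm(60)
    fit <- fit_linear(tab, spec, response = "y")
    lo <- fit$spec$estimates[2] + qt(0.025, fit$dof) * fit$std_errors[2]
    hi <- fit$spec$estimates[2] + qt(0.975, fit$dof) * fit$std_errors[2]
    lo <= -1 && -1 <= hi
  }, logical(1))
  expect_lt(abs(mean(slope_hits) - 0.95), 0.025)
})

test_that("forward selection recovers a sparse truth at high signal-to-noise", {
  hits <- 0
  for (s in 1:10) {
    cfg <- synth_config(n_cells = 400, seed = 700 + s)
    tab <- generate_feature_table(cfg)$table
    cand <- candidate_terms(tab)
    labels <- vapply(cand, function(t) t$label, character(1))
    true_idx <- c(which(labels == "C"), which(labels == "AA"),
                  grep("^\\(L-.*\\*\\(VA-", labels))
    true_spec <- model_spec(cand[c(1, true_idx)], response = "y")
    X <- build_design_matrix(tab, true_spec)
    beta <- c(0.2, 1.5, -0.8, 2.0)
    tab$y <- drop(X %*% beta) + rnorm(400, 0, 0.05)
    sel <- forward_select(tab, cand, seed = s, response = "y")
    sel_labels <- vapply(sel$terms, function(t) t$label, character(1))
    hits <- hits + setequal(sel_labels, c("(Intercept)", labels[true_idx]))
  }
  expect_gte(hits, 9)
})

test_that("forward selection is conservative on pure noise and deterministic", {
  intercept_only <- 0
  for (s in 1:10) {
    tab <- small_table(n = 150, seed = 800 + s)
    tab$y <- rnorm(150)
    sel <- forward_select(tab, seed = s, response = "y")
    intercept_only <- intercept_only + (length(sel$terms) == 1)
  }
  expect_gte(intercept_only, 6)  # most seeds select nothing

  tab <- small_table(n = 200, seed = 12)
  s1 <- forward_select(tab, seed = 5)
  s2 <- forward_select(tab, seed = 5)
  expect_identical(vapply(s1$terms, function(t) t$label, character(1)),
                   vapply(s2$terms, function(t) t$label, character(1)))
})

test_that("the selected model sits within the parsimony band of the path maximum", {
  tab <- small_table(n = 500, seed = 13)
  sel <- forward_select(tab, seed = 3)
  trace <- attr(sel, "trace")
  k <- max(which(trace$selected))
  i <- which.max(trace$cv_r2)
  expect_gte(trace$cv_r2[k], trace$cv_r2[i] - 3 * trace$cv_se[i])
  expect_lte(k, i)
  # on signal data the selection beats the intercept-only model
  expect_gt(trace$cv_r2[k], trace$cv_r2[1])
  expect_gt(length(sel$terms), 1)
})

test_that("logistic labels split at the training rank threshold", {
  tab <- small_table(n = 1000, seed = 14)
  split <- split_data(nrow(tab), seed = 14)
  fit <- fit_logistic(tab, split, threshold_percentile = 80)
  train_lab <- fit$labels[split == "train"]
  expect_equal(mean(train_lab), 0.2, tolerance = 0.02)
  p <- predict(fit, tab, type = "prob")
  expect_true(all(p > 0 & p < 1))
})

test_that("logistic classification is exact on separable classes", {
  n <- 400
  set.seed(20)
  tab <- data.frame(C = c(rnorm(n / 2, 0.7, 0.01), rnorm(n / 2, 0.95, 0.01)),
                    HW = rnorm(n, 3.4, 0.1), L = rnorm(n, 5, 0.1),
                    MW = rnorm(n, 1.3, 0.05), VA = rnorm(n, 0.7, 0.05),
                    AA = rnorm(n, 3.8, 0.2))
  tab$ln_dfi <- c(rep(-1, n / 2), rep(-3, n / 2)) + rnorm(n, 0, 0.01)
  split <- split_data(n, c(0.5, 0.25, 0.25), seed = 3)
  # rank threshold at the actual low-class share of the training rows
  thr_pct <- 100 * mean(tab$ln_dfi[split == "train"] < -2)
  fit <- suppressWarnings(fit_logistic(tab, split, threshold_percentile = thr_pct))
  test <- split == "test"
  pred <- predict(fit, tab[test, ], type = "class")
  truth <- as.integer(tab$ln_dfi[test] > fit$ln_dfi_threshold)
  expect_gte(confusion_matrix(pred, truth)$accuracy, 0.99)
})

test_that("logistic coefficients are recovered from a known model", {
  set.seed(30)
  n <- 5000
  tab <- data.frame(C = rnorm(n), HW = rnorm(n), L = rnorm(n),
                    MW = rnorm(n), VA = rnorm(n), AA = rnorm(n))
  eta <- -0.5 + 1.2 * tab$C - 0.8 * tab$AA
  lab <- rbinom(n, 1, plogis(eta))
  # feed labels through ln_dfi so the rank threshold reproduces them:
  # positives get high ln_dfi
  tab$ln_dfi <- ifelse(lab == 1, 1, -1) + rnorm(n, 0, 0.01)
  split <- split_data(n, c(0.8, 0.1, 0.1), seed = 4)
  thr_pct <- 100 * mean(tab$ln_dfi[split == "train"] <= 0)
  fit <- fit_logistic(tab, split, threshold_percentile = thr_pct)
  truth <- c(1.2, -0.8)
  est <- fit$coefficients[c("C", "AA")]
  se <- summary(fit$glm)$coefficients[c("C", "AA"), "Std. Error"]
  expect_true(all(abs(est - truth) < 3 * se))
})

test_that("single-class training sets are rejected", {
  tab <- small_table(n = 100, seed = 15)
  split <- split_data(100, seed = 15)
  expect_error(fit_logistic(tab, split, threshold_percentile = 100),
               "ClassBalanceError")
})
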