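test_that("pearson_r matches hand arithmetic and guards degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -2 * x + 1), -1)
  y <- c(1, 3, 2, 5)
  # covariance formula by hand
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), r_hand)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "DegenerateInput")
  expect_error(pearson_r(1:2, 2:3), "DegenerateInput")
})

test_that("rank groups have the exact-division sizes", {
  expect_equal(tabulate(rank_groups(rnorm(100)), 7),
               c(5, 5, 10, 60, 10, 5, 5))
  expect_equal(tabulate(rank_groups(rnorm(20)), 7),
               c(1, 1, 2, 12, 2, 1, 1))
  # all-tied predictions keep input order
  g <- rank_groups(rep(0, 20))
  expect_equal(g, rank_groups(seq_len(20)))
  expect_error(rank_groups(rnorm(10), cbind(lo = c(0, 40), hi = c(50, 100))),
               "configuration error")
})

test_that("rank-group sizes always sum to n and ignore bound order", {
  set.seed(6)
  for (n in c(7, 53, 264, 1000)) {
    p <- rnorm(n)
    g <- rank_groups(p)
    expect_equal(length(g), n)
    expect_equal(sum(tabulate(g, 7)), n)
    # permuting the bound rows changes nothing
    b <- default_rank_bounds()
    expect_equal(rank_groups(p, b[sample(7), ]), g)
  }
})

test_that("group means and Welch tests match base R on hand cases", {
  # group identical to the whole set: t = 0, p = 1
  x <- rnorm(30)
  gs <- group_mean_and_test(rep(4L, 30), x)
  expect_equal(gs$t[4], 0)
  expect_equal(gs$p_vs_overall[4], 1)
  # Welch test of A = {1,2,3} against the pooled set, by hand
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  groups <- c(1L, 1L, 1L, 7L, 7L, 7L)
  gs <- group_mean_and_test(groups, c(a, b))
  tt <- t.test(a, c(a, b))
  expect_equal(gs$t[1], unname(tt$statistic))
  expect_equal(gs$p_vs_overall[1], tt$p.value)
  # hand Welch statistic
  t_hand <- (mean(a) - mean(c(a, b))) /
    sqrt(var(a) / 3 + var(c(a, b)) / 6)
  expect_equal(gs$t[1], t_hand)
})

test_that("noise-free predictions give strictly increasing group means", {
  tab <- small_table(n = 500, seed = 16, noise_sd = 0)
  pred <- tab$ln_dfi
  gs <- group_mean_and_test(rank_groups(pred), tab$ln_dfi)
  expect_true(all(diff(gs$mean_actual) > 0))
})

test_that("enrichment percentile follows the mid-rank counting rule", {
  x <- rnorm(101)
  # the whole set scores 50 within 100/(2n)
  expect_lt(abs(enrichment_percentile(x, x) - 50), 100 / (2 * 101))
  # the single best (lowest) value among 100 distinct scores 99.5
  y <- seq_len(100)
  expect_equal(enrichment_percentile(min(y), y), 99.5)
  expect_equal(enrichment_percentile(max(y), y), 0.5)
  # direction flip
  expect_equal(enrichment_percentile(min(y), y, higher_is_better = FALSE),
               0.5)
})

test_that("random groups of a uniform sample center on the 50th percentile", {
  set.seed(7)
  x <- runif(400)
  ps <- vapply(1:1000, function(i) {
    enrichment_percentile(sample(x, 20), x)
  }, numeric(1))
  expect_lt(abs(mean(ps) - 50), 2)
})

test_that("AUC matches the pairwise concordance estimate", {
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  concordance <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    d <- outer(pos, neg, "-")
    (sum(d > 0) + 0.5 * sum(d == 0)) / length(d)
  }
  set.seed(8)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    roc <- roc_auc(scores, labels)
    expect_equal(roc$auc, concordance(scores, labels), tolerance = 1e-9)
    expect_true(all(diff(roc$points$fpr) >= 0))
    expect_true(all(diff(roc$points$tpr) >= 0))
  }
  # labels independent of scores: AUC near 1/2
  scores <- runif(4000); labels <- rbinom(4000, 1, 0.5)
  expect_lt(abs(roc_auc(scores, labels)$auc - 0.5), 0.05)
  expect_error(roc_auc(runif(5), rep(1, 5)), "DegenerateInput")
})

test_that("confusion matrices count and transpose correctly", {
  cm <- confusion_matrix(rep(1, 10), rep(1, 10))
  expect_equal(cm$accuracy, 1)
  pred <- c(rep(1, 3), rep(0, 7)); truth <- c(1, 1, 0, 0, 0, 0, 1, 1, 1, 1)
  cm <- confusion_matrix(pred, truth)
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(2, 1, 3, 4))
  expect_equal(cm$accuracy, 0.5)
  sw <- confusion_matrix(truth, pred)
  expect_equal(c(sw$tp, sw$fp, sw$tn, sw$fn), c(cm$tp, cm$fn, cm$tn, cm$fp))
  expect_error(confusion_matrix(c(0, 2), c(0, 1)), "SchemaError")
})

test_that("Welch p-values are uniform under the null", {
  set.seed(9)
  ps <- vapply(1:2000, function(i) {
    t.test(rnorm(15), rnorm(25))$p.value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("leave-one-donor-out produces one leakage-free report per donor", {
  tab <- small_table(n = 360, seed = 18)
  reports <- leave_one_donor_out(tab, model = "linear", seed = 2)
  expect_length(reports, 6)
  for (rep_i in reports) {
    expect_false(rep_i$donor %in% rep_i$train_donors)
    expect_equal(rep_i$n_test, sum(tab$donor == rep_i$donor))
    expect_true(is.finite(rep_i$r))
  }
})

test_that("a strongly shifted donor is the correlation minimum under clipping", {
  cfg <- synth_config(n_cells = 900, seed = 19)
  tab <- generate_feature_table(cfg)$table
  # donor 5 gets a large upward Ln(DFI) shift; clipping at DFI < 1
  # compresses its dynamic range
  shift <- ifelse(tab$donor == 5, 2.5, 0)
  tab$DFI <- pmin(pmax(exp(tab$ln_dfi + shift), 1e-6), 1 - 1e-6)
  tab$ln_dfi <- log(tab$DFI)
  reports <- leave_one_donor_out(tab, model = "linear", seed = 3)
  rs <- vapply(reports, function(x) x$r, numeric(1))
  donors <- vapply(reports, function(x) x$donor, numeric(1))
  expect_equal(donors[which.min(rs)], 5)
})

test_that("logistic leave-one-donor-out reports AUC and accuracy", {
  tab <- small_table(n = 480, seed = 20)
  reports <- leave_one_donor_out(tab, model = "logistic", seed = 4)
  expect_length(reports, 6)
  for (rep_i in reports) {
    # a held-out donor can be label-degenerate, in which case AUC is NA
    expect_true(is.na(rep_i$auc) || (rep_i$auc > 0 && rep_i$auc < 1))
    expect_true(rep_i$accuracy >= 0 && rep_i$accuracy <= 1)
  }
  expect_true(sum(vapply(reports, function(x) is.finite(x$auc), logical(1))) >= 4)
})
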