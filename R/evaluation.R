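# Evaluation of DFI predictions: Pearson r, percentile rank groups with
# Welch tests and enrichment percentiles, ROC/AUC, confusion matrices, and
# leave-one-donor-out reports.

#' Default percentile rank-group bounds
#'
#' The seven rank groups used throughout: 0-5, 5-10, 10-20, 20-80, 80-90,
#' 90-95 and 95-100 percent of predicted Ln(DFI), ranked low to high.
#' @return 7 x 2 matrix of (lo, hi] percentile bounds.
#' @export
default_rank_bounds <- function() {
  cbind(lo = c(0, 5, 10, 20, 80, 90, 95),
        hi = c(5, 10, 20, 80, 90, 95, 100))
}

#' Pearson correlation
#'
#' @param actual,predicted numeric vectors of equal length >= 3, neither
#'   constant.
#' @return sample Pearson correlation coefficient.
#' @export
pearson_r <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("lengths differ")
  if (length(actual) < 3) stop("DegenerateInput: need at least 3 pairs")
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0) {
    stop("DegenerateInput: constant vector")
  }
  stats::cor(actual, predicted)
}

#' Assign cells to percentile rank groups of a prediction
#'
#' Cells are sorted ascending by `predicted` (ties keep input order); the
#' cell of sort rank i (1-based) falls in group (lo, hi] when
#' lo < 100*i/n <= hi.
#'
#' @param predicted numeric vector.
#' @param bounds matrix of (lo, hi] percentile bounds covering (0, 100]
#'   without overlap (default [default_rank_bounds()]).
#' @return integer vector: each cell's group index (row of `bounds`).
#' @export
rank_groups <- function(predicted, bounds = default_rank_bounds()) {
  bounds <- bounds[order(bounds[, 1]), , drop = FALSE]
  if (bounds[1, 1] != 0 || bounds[nrow(bounds), 2] != 100 ||
      any(bounds[-1, 1] != bounds[-nrow(bounds), 2])) {
    stop("configuration error: bounds must partition (0, 100]")
  }
  n <- length(predicted)
  ord <- order(predicted)  # stable in R: ties keep input order
  pct <- 100 * seq_len(n) / n
  grp_sorted <- findInterval(pct, bounds[, 1], left.open = FALSE)
  # pct == lo belongs to the previous (lo', lo] group (with float tolerance)
  at_lo <- pct <= bounds[grp_sorted, 1] + 1e-9
  grp_sorted[at_lo] <- grp_sorted[at_lo] - 1L
  out <- integer(n)
  out[ord] <- grp_sorted
  out
}

#' Per-group mean of actual Ln(DFI) with Welch tests
#'
#' For each rank group: the mean of the actual values, a two-sided Welch
#' t-test (Welch-Satterthwaite degrees of freedom) of the group against the
#' full set, and the group's enrichment percentile
#' ([enrichment_percentile()]). Groups with fewer than 2 cells skip the
#' test (`p_vs_overall = NA`, flag set).
#'
#' @param groups integer group assignment from [rank_groups()].
#' @param actual numeric vector of actual Ln(DFI).
#' @param bounds the bounds used for the assignment.
#' @return data.frame of class `rank_group_summary`: `lo`, `hi`, `n`,
#'   `mean_actual`, `median_actual`, `t`, `p_vs_overall`,
#'   `enrichment_percentile`, `flag`.
#' @export
group_mean_and_test <- function(groups, actual,
                                bounds = default_rank_bounds()) {
  stopifnot(length(groups) == length(actual))
  k <- nrow(bounds)
  out <- data.frame(lo = bounds[, 1], hi = bounds[, 2], n = 0L,
                    mean_actual = NA_real_, median_actual = NA_real_,
                    t = NA_real_, p_vs_overall = NA_real_,
                    enrichment_percentile = NA_real_, flag = "")
  for (g in seq_len(k)) {
    x <- actual[groups == g]
    out$n[g] <- length(x)
    if (length(x) == 0) {
      out$flag[g] <- "empty"
      next
    }
    out$mean_actual[g] <- mean(x)
    out$median_actual[g] <- stats::median(x)
    out$enrichment_percentile[g] <- enrichment_percentile(x, actual)
    if (length(x) < 2) {
      out$flag[g] <- "test_skipped"
    } else if (length(x) == length(actual)) {
      # self-comparison: identical distributions by construction
      out$t[g] <- 0; out$p_vs_overall[g] <- 1
    } else {
      tt <- stats::t.test(x, actual)
      out$t[g] <- unname(tt$statistic)
      out$p_vs_overall[g] <- tt$p.value
    }
  }
  class(out) <- c("rank_group_summary", "data.frame")
  out
}

#' Enrichment percentile of a rank group
#'
#' Takes the group's median actual Ln(DFI) and returns its percentile
#' within all actual values under the quality ordering (lower Ln(DFI) =
#' better = higher percentile), with mid-rank tie handling:
#' 100 * (#worse + 0.5 * #tied) / n. A group matching the whole set scores
#' 50 (within 100/(2n)); set `higher_is_better = FALSE` to flip the
#' ordering.
#'
#' @param group_actual actual Ln(DFI) of the group's cells (nonempty).
#' @param all_actual actual Ln(DFI) of the full set.
#' @param higher_is_better direction flag; default `TRUE` maps low Ln(DFI)
#'   to high percentile.
#' @return percentile in (0, 100).
#' @export
enrichment_percentile <- function(group_actual, all_actual,
                                  higher_is_better = TRUE) {
  if (length(group_actual) == 0) stop("empty group")
  med <- stats::median(group_actual)
  worse <- if (higher_is_better) sum(all_actual > med) else sum(all_actual < med)
  ties <- sum(all_actual == med)
  100 * (worse + 0.5 * ties) / length(all_actual)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (tie-aware), AUC by the
#' trapezoidal rule; equals the pairwise-concordance (Mann-Whitney)
#' estimate.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return object of class `roc_curve`: data.frame `points` with `fpr`
#'   (1 - specificity) and `tpr` (sensitivity), and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("SchemaError: labels must be 0/1")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0 || nn == 0) stop("DegenerateInput: both classes required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)  # last index of each tied block
  tpr <- c(0, cumsum(l)[keep] / np)
  fpr <- c(0, cumsum(1 - l)[keep] / nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d operating points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Confusion matrix and accuracy
#'
#' @param predicted,actual 0/1 label vectors of equal length.
#' @return object of class `confusion_matrix`: `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`.
#' @export
confusion_matrix <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("lengths differ")
  predicted <- as.integer(predicted); actual <- as.integer(actual)
  if (!all(predicted %in% c(0L, 1L)) || !all(actual %in% c(0L, 1L))) {
    stop("SchemaError: labels must be 0/1")
  }
  tp <- sum(predicted == 1 & actual == 1)
  fp <- sum(predicted == 1 & actual == 0)
  tn <- sum(predicted == 0 & actual == 0)
  fn <- sum(predicted == 0 & actual == 1)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / length(actual)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(actual = c("1", "0"),
                              predicted = c("1", "0")))
  print(m)
  cat(sprintf("accuracy = %.4f\n", x$accuracy))
  invisible(x)
}

#' Leave-one-donor-out evaluation
#'
#' For each donor, the remaining donors' cells are split 0.8/0.2 into
#' training and validation, a model is fitted, and the held-out donor is
#' scored: Pearson r and rank-group summaries for the regression models,
#' AUC/accuracy for the logistic classifier. Donors with fewer than 3 cells
#' are skipped with a warning.
#'
#' @param table feature table with a `donor` column.
#' @param model `"linear"` (forward selection then OLS), `"nn"`, or
#'   `"logistic"`.
#' @param seed seed driving the per-donor splits and fits.
#' @param bounds rank-group bounds for the regression reports.
#' @param threshold_percentile rank split for the logistic model.
#' @return list of per-donor reports (fields `donor`, `n_test`, and either
#'   `r` + `groups` or `auc` + `accuracy`).
#' @export
leave_one_donor_out <- function(table, model = c("linear", "nn", "logistic"),
                                seed = 1L, bounds = default_rank_bounds(),
                                threshold_percentile = 80) {
  model <- match.arg(model)
  donors <- unique(table$donor)
  if (length(donors) < 2) stop("need at least 2 donors")
  reports <- list()
  for (i in seq_along(donors)) {
    d <- donors[i]
    test <- table[table$donor == d, , drop = FALSE]
    rest <- table[table$donor != d, , drop = FALSE]
    if (nrow(test) < 3) {
      warning("donor ", d, " has fewer than 3 cells; skipped", call. = FALSE)
      next
    }
    sub_seed <- seed + i
    split <- split_data(nrow(rest), c(0.8, 0.2, 0), seed = sub_seed)
    rep_i <- list(donor = d, n_test = nrow(test),
                  train_donors = unique(rest$donor))
    if (model == "linear") {
      spec <- forward_select(rest[split == "train", ], seed = sub_seed)
      fit <- fit_linear(rest[split == "train", ], spec)
      pred <- predict(fit, test)
      rep_i$r <- tryCatch(pearson_r(test$ln_dfi, pred),
                          error = function(e) NA_real_)
      rep_i$groups <- group_mean_and_test(rank_groups(pred, bounds),
                                          test$ln_dfi, bounds)
    } else if (model == "nn") {
      fit <- fit_nn(rest, split, nn_config(seed = sub_seed))
      pred <- predict(fit, test)
      rep_i$r <- tryCatch(pearson_r(test$ln_dfi, pred),
                          error = function(e) NA_real_)
      rep_i$groups <- group_mean_and_test(rank_groups(pred, bounds),
                                          test$ln_dfi, bounds)
    } else {
      fit <- fit_logistic(rest, split, threshold_percentile)
      prob <- predict(fit, test, type = "prob")
      truth <- as.integer(test$ln_dfi > fit$ln_dfi_threshold)
      rep_i$auc <- if (length(unique(truth)) == 2) {
        roc_auc(prob, truth)$auc
      } else {
        NA_real_
      }
      rep_i$accuracy <- confusion_matrix(as.integer(prob > fit$cutoff),
                                         truth)$accuracy
    }
    reports[[length(reports) + 1]] <- rep_i
  }
  reports
}
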