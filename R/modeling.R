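# Predictive models on feature tables: centered-interaction least squares
# with forward selection by cross-validated R^2, and logistic classification
# of Ln(DFI) rank categories.

#' Random train/validation/test split
#'
#' Group sizes are `floor(n * fraction)`, with remaining cells assigned in
#' train, validation, test order; the permutation is seeded and
#' deterministic.
#'
#' @param n number of records (or a data.frame, whose row count is used).
#' @param fractions length-3 non-negative fractions summing to 1.
#' @param seed integer seed.
#' @return factor of length `n` with levels `train`, `validation`, `test`.
#' @export
split_data <- function(n, fractions = c(0.65, 0.10, 0.25), seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  if (length(fractions) != 3 || any(fractions < 0)) {
    stop("configuration error: fractions must be 3 non-negative numbers")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("configuration error: fractions must sum to 1")
  }
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  i <- 1L
  while (rem > 0) {
    sizes[i] <- sizes[i] + 1L
    rem <- rem - 1L
    i <- if (i == 3L) 1L else i + 1L
  }
  labels <- rep(c("train", "validation", "test"), times = sizes)
  perm <- with_seed(seed, sample.int(n))
  out <- character(n)
  out[perm] <- labels
  factor(out, levels = c("train", "validation", "test"))
}

#' Ordinary least squares fit of a model spec
#'
#' Fits the spec's terms by OLS using the centers stored in the spec.
#' Standard errors come from the unbiased residual-variance estimator,
#' t ratios and two-sided P values from the t distribution on n - p degrees
#' of freedom, and each non-intercept term's VIF is 1/(1 - R^2) of that
#' column regressed on the other non-intercept columns.
#'
#' @param table data.frame with the feature columns and the response.
#' @param spec a [model_spec()].
#' @param response response column name; defaults to the spec's.
#' @return object of class `linear_fit`: the spec with refreshed estimates
#'   plus `std_errors`, `t_ratios`, `p_values`, `vifs`, `sigma`,
#'   `r_squared`, `n`, `dof`.
#' @export
fit_linear <- function(table, spec, response = spec$response) {
  X <- build_design_matrix(table, spec)
  y <- as.numeric(table[[response]])
  if (is.null(y)) stop("SchemaError: missing response column ", response)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("fit requires more records than terms")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("RankError: collinear terms: ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  res <- y - drop(X %*% beta)
  dof <- n - p
  sigma2 <- sum(res^2) / dof
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tv <- beta / se
  pv <- 2 * stats::pt(-abs(tv), dof)
  vifs <- vif_columns(X)
  spec$estimates <- stats::setNames(beta, colnames(X))
  structure(list(spec = spec,
                 std_errors = stats::setNames(se, colnames(X)),
                 t_ratios = stats::setNames(tv, colnames(X)),
                 p_values = stats::setNames(pv, colnames(X)),
                 vifs = vifs,
                 sigma = sqrt(sigma2),
                 r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
                 n = n, dof = dof, response = response),
            class = "linear_fit")
}

# VIF of each non-intercept column: 1/(1 - R^2_j) from regressing column j
# on the other non-intercept columns (with intercept), via the inverse
# correlation matrix. The intercept gets NA.
vif_columns <- function(X) {
  labels <- colnames(X)
  is_int <- apply(X, 2, function(col) all(col == col[1]))
  out <- stats::setNames(rep(NA_real_, ncol(X)), labels)
  Z <- X[, !is_int, drop = FALSE]
  if (ncol(Z) == 1) {
    out[!is_int] <- 1
  } else if (ncol(Z) > 1) {
    out[!is_int] <- diag(solve(stats::cor(Z)))
  }
  out
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit: n = %d, dof = %d, R^2 = %.4f, sigma = %.4f\n",
              x$n, x$dof, x$r_squared, x$sigma))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.linear_fit <- function(x, ...) {
  data.frame(term = names(x$spec$estimates),
             estimate = unname(x$spec$estimates),
             std_error = unname(x$std_errors),
             t_ratio = unname(x$t_ratios),
             p_value = unname(x$p_values),
             vif = unname(x$vifs))
}

#' @export
predict.linear_fit <- function(object, newdata, ...) {
  predict(object$spec, newdata)
}

# fold-averaged cross-validated R^2 (and its fold standard error) of an
# OLS fit with the given design columns; the per-fold baseline is the
# training mean, so the intercept-only model scores near zero
cv_r_squared <- function(X, y, folds) {
  k <- max(folds)
  r2 <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- stats::lm.fit(X[tr, , drop = FALSE], y[tr])
    if (any(is.na(fit$coefficients))) return(c(mean = -Inf, se = 0))
    yh <- X[!tr, , drop = FALSE] %*% fit$coefficients
    yt <- y[!tr]
    ss_tot <- sum((yt - mean(y[tr]))^2)
    if (ss_tot == 0) return(c(mean = -Inf, se = 0))
    r2[f] <- 1 - sum((yt - yh)^2) / ss_tot
  }
  c(mean = mean(r2), se = stats::sd(r2) / sqrt(k))
}

#' Forward term selection by cross-validated R^2
#'
#' Greedy forward addition over a candidate term set: at each step the term
#' with the largest k-fold cross-validated R^2 (fold-averaged, shared fold
#' assignment) joins the path; ties are broken by candidate order and the
#' intercept is always included. The path is extended until cross-validated
#' R^2 has failed to reach a new maximum for `patience` consecutive steps.
#' The returned model is the shortest path prefix whose cross-validated R^2
#' is within `se_mult` fold standard errors of the path maximum. The
#' parsimony margin is needed because the maximum over many candidate gains
#' is optimistically biased at any sample size: a plain
#' "stop when validation R^2 stops improving" rule almost always accepts
#' spurious terms on a pure-noise response, whereas the one-or-more-SE rule
#' returns the intercept-only model there and still recovers a sparse truth
#' exactly at high signal-to-noise.
#'
#' @param table data.frame with features and response.
#' @param candidates list of [model_term()] objects (default
#'   [candidate_terms()] over the six morphology features).
#' @param folds number of cross-validation folds (default 5).
#' @param seed seed for the fold assignment.
#' @param response response column name.
#' @param patience path extension patience, in steps past the running
#'   maximum.
#' @param se_mult parsimony multiplier on the fold standard error.
#' @return a [model_spec()] of the selected terms (no estimates; pass to
#'   [fit_linear()]), with the path trace in attribute `trace` (columns
#'   `step`, `term`, `cv_r2`, `cv_se`, `selected`).
#' @export
forward_select <- function(table, candidates = candidate_terms(table),
                           folds = 5L, seed = 1L, response = "ln_dfi",
                           patience = 4L, se_mult = 3) {
  if (length(candidates) == 0) stop("candidates must be nonempty")
  y <- as.numeric(table[[response]])
  n <- length(y)
  full_spec <- model_spec(candidates, response = response)
  Xall <- build_design_matrix(table, full_spec)
  labels <- colnames(Xall)
  fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  selected <- which(labels == "(Intercept)")
  remaining <- setdiff(seq_along(candidates), selected)
  cv <- cv_r_squared(Xall[, selected, drop = FALSE], y, fold)
  path <- list(selected)
  cvm <- cv[["mean"]]; cvs <- cv[["se"]]
  terms_added <- "(Intercept)"
  since_best <- 0L
  while (length(remaining) > 0 && since_best < patience &&
         n > length(selected) + 3) {
    gains <- vapply(remaining, function(j) {
      cv_r_squared(Xall[, c(selected, j), drop = FALSE], y, fold)[["mean"]]
    }, numeric(1))
    j <- remaining[which.max(gains)]
    selected <- c(selected, j)
    remaining <- setdiff(remaining, j)
    cv <- cv_r_squared(Xall[, selected, drop = FALSE], y, fold)
    path[[length(path) + 1]] <- selected
    cvm <- c(cvm, cv[["mean"]]); cvs <- c(cvs, cv[["se"]])
    terms_added <- c(terms_added, labels[j])
    since_best <- if (which.max(cvm) == length(cvm)) 0L else since_best + 1L
  }
  i_max <- which.max(cvm)
  k <- which(cvm >= cvm[i_max] - se_mult * cvs[i_max])[1]
  spec <- model_spec(candidates[sort(path[[k]])], response = response)
  attr(spec, "trace") <- data.frame(step = seq_along(cvm) - 1L,
                                    term = terms_added, cv_r2 = cvm,
                                    cv_se = cvs,
                                    selected = seq_along(cvm) <= k)
  spec
}

#' Logistic classification of Ln(DFI) rank categories
#'
#' Labels cells by whether their Ln(DFI) ranks above the
#' `threshold_percentile` of the *training* distribution (computed on
#' training data only, to avoid leakage), then fits a maximum-likelihood
#' logistic regression of the label on the six morphology features.
#'
#' @param table feature table with `ln_dfi`.
#' @param split factor from [split_data()].
#' @param threshold_percentile rank split point, percent (default 80: the
#'   0-80% vs 80-100% categorization).
#' @param features predictor columns.
#' @param cutoff probability cutoff for predicted class labels.
#' @return object of class `logistic_fit`: `glm` coefficients,
#'   `threshold_percentile`, `ln_dfi_threshold`, `cutoff`, `labels`
#'   (per-record 0/1 for all rows of `table`), `split`.
#' @export
fit_logistic <- function(table, split, threshold_percentile = 80,
                         features = c("C", "HW", "L", "MW", "VA", "AA"),
                         cutoff = 0.5) {
  stopifnot(length(split) == nrow(table))
  thr <- stats::quantile(table$ln_dfi[split == "train"],
                         threshold_percentile / 100, names = FALSE)
  labels <- as.integer(table$ln_dfi > thr)
  train_lab <- labels[split == "train"]
  if (length(unique(train_lab)) < 2) {
    stop("ClassBalanceError: training labels are single-class")
  }
  dat <- cbind(data.frame(.label = labels), table[features])
  fml <- stats::as.formula(paste(".label ~", paste(features, collapse = "+")))
  glm_fit <- stats::glm(fml, family = stats::binomial(),
                        data = dat[split == "train", ])
  structure(list(glm = glm_fit,
                 coefficients = stats::coef(glm_fit),
                 features = features,
                 threshold_percentile = threshold_percentile,
                 ln_dfi_threshold = thr,
                 cutoff = cutoff,
                 labels = labels,
                 split = split),
            class = "logistic_fit")
}

#' @export
predict.logistic_fit <- function(object, newdata,
                                 type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- stats::predict(object$glm, newdata = newdata, type = "response")
  if (type == "prob") unname(p) else as.integer(p > object$cutoff)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic fit: rank split at %.0f%% (ln_dfi > %.3f), cutoff %.2f\n",
    x$threshold_percentile, x$ln_dfi_threshold, x$cutoff))
  print(x$coefficients, digits = 4)
  invisible(x)
}
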