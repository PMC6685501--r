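# End-to-end pipeline: synthetic generation or file input, optional image
# measurement, model fitting and evaluation, with reproducible artifacts.

#' Pipeline configuration
#'
#' @param mode input mode: `"synthetic"` (generate a feature table),
#'   `"images"` (generate paired images and re-measure them), or
#'   `"features"` (read a feature-table CSV from `path`).
#' @param path input CSV for `"features"` mode.
#' @param synth a [synth_config()] for the synthetic modes.
#' @param seed master seed; overrides `synth$seed` and drives splits/fits.
#' @param fractions train/validation/test fractions.
#' @param rank_bounds percentile rank-group bounds.
#' @param threshold_percentile logistic rank split, percent.
#' @param models character subset of `c("linear", "nn", "logistic")`.
#' @param out_dir optional directory; when set, the feature table (CSV),
#'   model fits (JSON) and evaluation reports (JSON/CSV) are written there,
#'   each stamped with the seed and config hash.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "images", "features"),
                            path = NULL, synth = synth_config(),
                            seed = 1L, fractions = c(0.65, 0.10, 0.25),
                            rank_bounds = default_rank_bounds(),
                            threshold_percentile = 80,
                            models = c("linear", "nn", "logistic"),
                            out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "features" && is.null(path)) {
    stop("configuration error: features mode requires a path")
  }
  models <- match.arg(models, several.ok = TRUE)
  synth$seed <- as.integer(seed)
  structure(list(mode = mode, path = path, synth = synth,
                 seed = as.integer(seed), fractions = fractions,
                 rank_bounds = rank_bounds,
                 threshold_percentile = threshold_percentile,
                 models = models, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages: data acquisition (synthetic table,
#' synthetic images re-measured cell by cell, or a CSV), a seeded
#' train/validation/test split, the requested model fits, and the standard
#' evaluation (per-split Pearson r and rank-group summaries for the
#' regression models; ROC/AUC and confusion matrices for the classifier).
#' Identical configuration and seed give identical bundles; artifacts, when
#' written, embed the seed and config hash.
#'
#' @param config a [pipeline_config()].
#' @return a list bundle: `table`, `split`, `fits`, `evaluation`,
#'   `dfi_summary`, `seed`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  table <- switch(config$mode,
    synthetic = generate_feature_table(config$synth)$table,
    images = {
      ds <- generate_image_dataset(config$synth)
      measured <- do.call(rbind, lapply(ds$images, measure_cell))
      measured$donor <- ds$table$donor
      measured$cell_id <- ds$table$cell_id
      measured
    },
    features = read_feature_table(config$path)
  )
  split <- split_data(nrow(table), config$fractions, seed = config$seed)
  test <- table[split == "test", , drop = FALSE]

  fits <- list()
  evaluation <- list()
  if ("linear" %in% config$models) {
    spec <- forward_select(table[split == "train", ], seed = config$seed)
    fits$linear <- fit_linear(table[split == "train", ], spec)
    evaluation$linear <- evaluate_regression(fits$linear, table, split,
                                             config$rank_bounds)
  }
  if ("nn" %in% config$models) {
    fits$nn <- fit_nn(table, split, nn_config(seed = config$seed))
    evaluation$nn <- evaluate_regression(fits$nn, table, split,
                                         config$rank_bounds)
  }
  if ("logistic" %in% config$models) {
    fits$logistic <- fit_logistic(table, split, config$threshold_percentile)
    evaluation$logistic <- evaluate_classifier(fits$logistic, table, split)
  }
  dfi_summary <- summarize_dfi(table$DFI, interval = c(0.07, 0.15))

  bundle <- list(table = table, split = split, fits = fits,
                 evaluation = evaluation, dfi_summary = dfi_summary,
                 seed = config$seed, config_hash = hash)
  if (!is.null(config$out_dir)) write_bundle(bundle, config)
  bundle
}

# per-split Pearson r plus test-set rank-group summary for one regressor
evaluate_regression <- function(fit, table, split, bounds) {
  out <- list()
  for (s in levels(split)) {
    rows <- split == s
    if (sum(rows) >= 3) {
      out[[paste0("r_", s)]] <- tryCatch(
        pearson_r(table$ln_dfi[rows], predict(fit, table[rows, ])),
        error = function(e) NA_real_)
    }
  }
  test <- table[split == "test", , drop = FALSE]
  pred <- predict(fit, test)
  out$groups <- group_mean_and_test(rank_groups(pred, bounds),
                                    test$ln_dfi, bounds)
  out
}

# ROC/AUC and confusion matrix per split for the logistic classifier
evaluate_classifier <- function(fit, table, split) {
  out <- list()
  for (s in levels(split)) {
    rows <- split == s
    truth <- fit$labels[rows]
    if (length(unique(truth)) < 2) next
    prob <- predict(fit, table[rows, ], type = "prob")
    out[[s]] <- list(auc = roc_auc(prob, truth)$auc,
                     confusion = confusion_matrix(
                       as.integer(prob > fit$cutoff), truth))
  }
  out
}

# serialize a bundle's artifacts; every file carries seed + config hash
write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- c(seed = bundle$seed, config_hash = bundle$config_hash)
  write_feature_table(bundle$table,
                      file.path(config$out_dir, "features.csv"),
                      comments = stamp)
  fits_json <- lapply(bundle$fits, serialize_fit)
  jsonlite::write_json(c(as.list(stamp), fits_json),
                       file.path(config$out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  ev <- bundle$evaluation
  jsonlite::write_json(c(as.list(stamp), ev),
                       file.path(config$out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (m in names(ev)) {
    if (!is.null(ev[[m]]$groups)) {
      utils::write.csv(ev[[m]]$groups,
                       file.path(config$out_dir,
                                 paste0("rank_groups_", m, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(config$out_dir)
}

# JSON-friendly view of a fitted model
serialize_fit <- function(fit) {
  if (inherits(fit, "linear_fit")) {
    list(kind = "linear", table = as.data.frame(fit),
         n = fit$n, dof = fit$dof, sigma = fit$sigma,
         r_squared = fit$r_squared)
  } else if (inherits(fit, "dfi_nn")) {
    list(kind = "nn", hidden_nodes = fit$config$hidden_nodes,
         epochs = fit$epochs, val_mse = fit$val_mse, flag = fit$flag,
         theta = fit$theta, mu_x = fit$mu_x, sd_x = fit$sd_x,
         mu_y = fit$mu_y, sd_y = fit$sd_y)
  } else if (inherits(fit, "logistic_fit")) {
    list(kind = "logistic", coefficients = as.list(fit$coefficients),
         threshold_percentile = fit$threshold_percentile,
         ln_dfi_threshold = fit$ln_dfi_threshold, cutoff = fit$cutoff)
  } else {
    list(kind = class(fit)[1])
  }
}
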