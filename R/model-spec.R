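# Centered-interaction linear model specifications.
#
# A model spec is an ordered list of terms; each non-intercept term is the
# product of one or two centered features, (x1 - c1) * (x2 - c2), or a bare
# main effect x. Centers travel with the term so a spec can be evaluated on
# any table without recomputing training means.

#' Construct a single model term
#'
#' @param features character vector of 0 (intercept), 1 (main effect) or 2
#'   (centered product; a repeated feature gives a quadratic term) feature
#'   names.
#' @param centers named numeric vector of centering constants for the
#'   features of a product term. Main effects and the intercept carry no
#'   centers.
#' @return an object of class `model_term` with fields `kind`
#'   (`"intercept"`, `"main"`, `"interaction"` or `"quadratic"`),
#'   `features`, `centers` and a human-readable `label`.
#' @export
model_term <- function(features = character(), centers = NULL) {
  features <- as.character(features)
  if (length(features) == 0) {
    t <- list(kind = "intercept", features = character(), centers = NULL,
              label = "(Intercept)")
  } else if (length(features) == 1) {
    t <- list(kind = "main", features = features, centers = NULL,
              label = features)
  } else if (length(features) == 2) {
    if (is.null(centers)) stop("product terms require centering constants")
    centers <- centers[features]
    if (anyNA(centers)) stop("centers must be named for every feature")
    kind <- if (features[1] == features[2]) "quadratic" else "interaction"
    lab <- paste(sprintf("(%s-%.6g)", features, centers), collapse = "*")
    t <- list(kind = kind, features = features,
              centers = stats::setNames(as.numeric(centers), features),
              label = lab)
  } else {
    stop("a term involves at most two features")
  }
  structure(t, class = "model_term")
}

#' Construct a linear model specification
#'
#' @param terms list of [model_term()] objects; exactly one intercept, no
#'   duplicate labels.
#' @param estimates optional numeric vector of per-term coefficients, in
#'   term order.
#' @param response name of the response column (default `"ln_dfi"`).
#' @return an object of class `linear_model_spec`.
#' @export
model_spec <- function(terms, estimates = NULL, response = "ln_dfi") {
  labels <- vapply(terms, function(t) t$label, character(1))
  if (sum(labels == "(Intercept)") != 1) {
    stop("a model spec contains exactly one intercept term")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate terms: ", paste(labels[duplicated(labels)], collapse = ", "))
  }
  if (!is.null(estimates)) {
    if (length(estimates) != length(terms)) {
      stop("one estimate per term is required")
    }
    estimates <- stats::setNames(as.numeric(estimates), labels)
  }
  structure(list(terms = terms, estimates = estimates, response = response),
            class = "linear_model_spec")
}

#' @export
print.linear_model_spec <- function(x, ...) {
  cat("Linear model spec:", length(x$terms), "terms, response",
      x$response, "\n")
  labels <- vapply(x$terms, function(t) t$label, character(1))
  if (is.null(x$estimates)) {
    cat(paste(" ", labels, collapse = "\n"), "\n")
  } else {
    print(data.frame(term = labels, estimate = unname(x$estimates)),
          row.names = FALSE)
  }
  invisible(x)
}

# Centering constants of the reference model (sample means of the source
# cohort's six morphology features).
reference_centers <- c(C = 0.86097, L = 4.9618, HW = 3.3639,
                       MW = 1.32059, VA = 0.68287, AA = 3.80839)

#' Reference Ln(DFI) interaction model
#'
#' The published 14-term least-squares model linking six single-sperm
#' morphology features (head circularity C, head width HW, head length L,
#' midpiece width MW, vacuole area VA, acrosome area AA; lengths in
#' micrometers, areas in square micrometers) to Ln(DFI): an intercept, main
#' effects for C, VA and AA, and ten centered quadratic/two-factor
#' interaction terms. The synthetic-data generator uses it as ground truth,
#' and round-trip tests refit it on simulated cohorts.
#'
#' @return a [model_spec()] carrying the published coefficient estimates.
#' @export
reference_model <- function() {
  cc <- reference_centers
  terms <- list(
    model_term(),
    model_term("C"),
    model_term("VA"),
    model_term("AA"),
    model_term(c("C", "C"), cc),
    model_term(c("C", "L"), cc),
    model_term(c("MW", "MW"), cc),
    model_term(c("C", "VA"), cc),
    model_term(c("L", "VA"), cc),
    model_term(c("VA", "VA"), cc),
    model_term(c("C", "AA"), cc),
    model_term(c("HW", "AA"), cc),
    model_term(c("L", "AA"), cc),
    model_term(c("AA", "AA"), cc)
  )
  est <- c(-1.59, -0.48, 0.04, -0.06,
           -5.16, -0.39, 0.01, -0.40, -0.03, -0.01,
           0.35, -0.02, 0.02, 0.01)
  model_spec(terms, estimates = est)
}

#' Build the design matrix of a model spec
#'
#' One column per term: 1 for the intercept, the raw feature for main
#' effects, and the product of centered features for interaction/quadratic
#' terms, using the centers stored in the spec.
#'
#' @param table data.frame holding every feature the spec references.
#' @param spec a [model_spec()].
#' @return numeric matrix with one column per term, labelled.
#' @export
build_design_matrix <- function(table, spec) {
  stopifnot(inherits(spec, "linear_model_spec"))
  needed <- unique(unlist(lapply(spec$terms, function(t) t$features)))
  missing <- setdiff(needed, names(table))
  if (length(missing) > 0) {
    stop("SchemaError: missing feature column(s): ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(table)
  cols <- lapply(spec$terms, function(t) {
    switch(t$kind,
      intercept = rep(1, n),
      main = as.numeric(table[[t$features]]),
      (as.numeric(table[[t$features[1]]]) - t$centers[1]) *
        (as.numeric(table[[t$features[2]]]) - t$centers[2])
    )
  })
  X <- do.call(cbind, cols)
  colnames(X) <- vapply(spec$terms, function(t) t$label, character(1))
  X
}

#' Predict from a linear model spec with estimates
#'
#' @param object a [model_spec()] carrying estimates.
#' @param newdata data.frame of features.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.linear_model_spec <- function(object, newdata, ...) {
  if (is.null(object$estimates)) stop("spec carries no estimates")
  unname(drop(build_design_matrix(newdata, object) %*% object$estimates))
}

#' Full candidate term set for forward selection
#'
#' Intercept, the six main effects, and every product of two centered
#' factors including squares: 1 + 6 + choose(6, 2) + 6 = 28 terms. Centers
#' are the sample means of `table` (recomputed at build time; the reference
#' model's printed centers are that cohort's means).
#'
#' @param table data.frame with the feature columns.
#' @param features feature names (default the six morphology parameters).
#' @return list of [model_term()] objects.
#' @export
candidate_terms <- function(table,
                            features = c("C", "HW", "L", "MW", "VA", "AA")) {
  missing <- setdiff(features, names(table))
  if (length(missing) > 0) {
    stop("SchemaError: missing feature column(s): ",
         paste(missing, collapse = ", "))
  }
  centers <- vapply(features, function(f) mean(as.numeric(table[[f]])),
                    numeric(1))
  terms <- list(model_term())
  for (f in features) terms <- c(terms, list(model_term(f)))
  for (i in seq_along(features)) {
    for (j in i:length(features)) {
      terms <- c(terms, list(model_term(c(features[i], features[j]), centers)))
    }
  }
  terms
}
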