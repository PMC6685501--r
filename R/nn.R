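# Single-hidden-layer feed-forward regression network, trained full-batch
# by Levenberg-Marquardt with validation-based early stopping: tanh hidden
# units, linear output, inputs and response standardized on training
# statistics, and the weights returned are those with the best validation
# loss seen during training.

#' Neural-network configuration
#'
#' @param hidden_nodes hidden-layer width (default 20).
#' @param max_validation_failures consecutive epochs without validation
#'   improvement before training stops (default 20).
#' @param max_epochs hard cap on accepted update steps.
#' @param seed seed for the weight initialization.
#' @param lambda0 initial Levenberg-Marquardt damping.
#' @return a validated list of class `nn_config`.
#' @export
nn_config <- function(hidden_nodes = 20L, max_validation_failures = 20L,
                      max_epochs = 300L, seed = 1L, lambda0 = 1e-2) {
  stopifnot(hidden_nodes >= 1, max_validation_failures >= 1, max_epochs >= 1)
  structure(list(hidden_nodes = as.integer(hidden_nodes),
                 max_validation_failures = as.integer(max_validation_failures),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), lambda0 = lambda0),
            class = "nn_config")
}

# forward pass: returns predictions (scaled units) and hidden activations
nn_forward <- function(theta, Z, h) {
  d <- ncol(Z)
  W1 <- matrix(theta[seq_len(h * d)], h, d)
  b1 <- theta[h * d + seq_len(h)]
  w2 <- theta[h * d + h + seq_len(h)]
  b2 <- theta[h * d + 2 * h + 1]
  H <- tanh(sweep(Z %*% t(W1), 2, b1, "+"))
  list(yhat = drop(H %*% w2) + b2, H = H, w2 = w2)
}

# Jacobian of predictions wrt parameters, n x p
nn_jacobian <- function(fw, Z, h) {
  n <- nrow(Z); d <- ncol(Z)
  G <- (1 - fw$H^2) * matrix(fw$w2, n, h, byrow = TRUE)  # d yhat / d b1
  JW1 <- matrix(0, n, h * d)
  for (k in seq_len(d)) JW1[, (k - 1) * h + seq_len(h)] <- G * Z[, k]
  cbind(JW1, G, fw$H, 1)
}

#' Fit the Ln(DFI) regression network
#'
#' Trains on the `train` rows, monitors mean squared error on the
#' `validation` rows after every accepted Levenberg-Marquardt step, and
#' stops once validation error has failed to improve for
#' `max_validation_failures` consecutive steps (or at `max_epochs`). The
#' returned model carries the weights of the best validation epoch.
#'
#' @param table feature table.
#' @param split factor from [split_data()]; train and validation must be
#'   nonempty.
#' @param config an [nn_config()].
#' @param features predictor columns.
#' @param response response column.
#' @return object of class `dfi_nn` with a [predict][predict.dfi_nn] method;
#'   fields include `val_mse`, `epochs`, `flag` (`"ok"` or
#'   `"constant_response"`).
#' @export
fit_nn <- function(table, split, config = nn_config(),
                   features = c("C", "HW", "L", "MW", "VA", "AA"),
                   response = "ln_dfi") {
  stopifnot(length(split) == nrow(table))
  tr <- split == "train"; va <- split == "validation"
  if (!any(tr) || !any(va)) stop("train and validation sets must be nonempty")
  X <- as.matrix(table[features])
  y <- as.numeric(table[[response]])
  mu_x <- colMeans(X[tr, , drop = FALSE])
  sd_x <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  sd_x[sd_x == 0] <- 1
  mu_y <- mean(y[tr]); sd_y <- stats::sd(y[tr])
  base <- list(features = features, response = response, mu_x = mu_x,
               sd_x = sd_x, mu_y = mu_y, sd_y = sd_y, config = config)
  if (!is.finite(sd_y) || sd_y == 0) {
    out <- c(base, list(theta = NULL, flag = "constant_response",
                        val_mse = 0, epochs = 0L))
    return(structure(out, class = "dfi_nn"))
  }
  Z <- sweep(sweep(X, 2, mu_x), 2, sd_x, "/")
  ys <- (y - mu_y) / sd_y
  Ztr <- Z[tr, , drop = FALSE]; ytr <- ys[tr]
  Zva <- Z[va, , drop = FALSE]; yva <- ys[va]
  h <- config$hidden_nodes
  d <- length(features)
  p <- h * d + 2 * h + 1
  theta <- with_seed(config$seed, stats::runif(p, -0.7, 0.7) / sqrt(d))

  fw <- nn_forward(theta, Ztr, h)
  r <- ytr - fw$yhat
  sse <- sum(r^2)
  if (!is.finite(sse)) stop("TrainingError: non-finite loss at initialization")
  val_mse <- mean((yva - nn_forward(theta, Zva, h)$yhat)^2)
  best <- list(theta = theta, val_mse = val_mse)
  val_trace <- val_mse
  lambda <- config$lambda0
  fails <- 0L
  epoch <- 0L
  while (epoch < config$max_epochs) {
    J <- nn_jacobian(fw, Ztr, h)
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    accepted <- FALSE
    for (try in 1:30) {
      delta <- tryCatch(solve(JtJ + lambda * diag(p), g),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + drop(delta)
        fw_c <- nn_forward(cand, Ztr, h)
        r_c <- ytr - fw_c$yhat
        sse_c <- sum(r_c^2)
        if (is.finite(sse_c) && sse_c < sse) {
          theta <- cand; fw <- fw_c; r <- r_c; sse <- sse_c
          lambda <- max(lambda / 10, 1e-12)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!accepted) break
    epoch <- epoch + 1L
    val_mse <- mean((yva - nn_forward(theta, Zva, h)$yhat)^2)
    if (!is.finite(val_mse)) stop("TrainingError: non-finite validation loss")
    val_trace <- c(val_trace, val_mse)
    if (val_mse < best$val_mse - 1e-12) {
      best <- list(theta = theta, val_mse = val_mse)
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= config$max_validation_failures) break
    }
  }
  structure(c(base, list(theta = best$theta, val_mse = best$val_mse,
                         val_trace = val_trace, epochs = epoch,
                         flag = "ok")),
            class = "dfi_nn")
}

#' Predict from a fitted regression network
#'
#' @param object a `dfi_nn` from [fit_nn()].
#' @param newdata data.frame with the feature columns.
#' @param ... unused.
#' @return numeric predictions in response units.
#' @export
predict.dfi_nn <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$features])
  if (identical(object$flag, "constant_response")) {
    return(rep(object$mu_y, nrow(X)))
  }
  Z <- sweep(sweep(X, 2, object$mu_x), 2, object$sd_x, "/")
  fw <- nn_forward(object$theta, Z, object$config$hidden_nodes)
  fw$yhat * object$sd_y + object$mu_y
}

#' @export
print.dfi_nn <- function(x, ...) {
  cat(sprintf(
    "dfi_nn: %d tanh hidden nodes, %d epochs, best validation MSE %.4g%s\n",
    x$config$hidden_nodes, x$epochs, x$val_mse,
    if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}
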