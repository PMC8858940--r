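#' Logistic sigmoid activation
#'
#' `logsig(x) = 1 / (1 + exp(-x))`, the transfer function of both the
#' hidden and output layers. Monotone increasing, range (0, 1); infinities
#' saturate cleanly to 0/1.
#'
#' @param x Numeric.
#' @return Numeric of the same shape.
#' @examples
#' logsig(0)      # 0.5
#' logsig(log(3)) # 0.75
#' @export
logsig <- function(x) 1 / (1 + exp(-x))

#' Candidate hidden-node counts from the size heuristic
#'
#' The base count is `round(sqrt(n_input + n_output))`; an additive constant
#' 0..11 spans the trial-and-error range, intersected with \[4, 15\]. For
#' the 14-input, 1-output configuration this is exactly 4..15.
#'
#' @param n_input,n_output Layer sizes.
#' @return Integer vector of candidate hidden-node counts.
#' @export
heuristic_hidden_range <- function(n_input, n_output = 1) {
  stopifnot(n_input >= 1, n_output >= 1)
  base <- round(sqrt(n_input + n_output))
  cand <- base + 0:11
  sort(unique(cand[cand >= 4 & cand <= 15]))
}

#' Initialise a single-hidden-layer network
#'
#' Weights (including biases) are drawn uniformly on \[-0.5, 0.5\] from the
#' seed. `w1` is `n_hidden x (n_input + 1)` and `w2` is
#' `n_output x (n_hidden + 1)`; the final column of each is the bias.
#' Scaling is unset until the network is fitted.
#'
#' @param n_input,n_hidden,n_output Layer sizes.
#' @param seed Integer seed.
#' @return An object of class `ee_bpnn`.
#' @export
init_network <- function(n_input, n_hidden, n_output = 1, seed = 1L) {
  stopifnot(n_input >= 1, n_hidden >= 1, n_output >= 1)
  withr::with_seed(seed, {
    w1 <- matrix(runif(n_hidden * (n_input + 1), -0.5, 0.5),
                 nrow = n_hidden, ncol = n_input + 1)
    w2 <- matrix(runif(n_output * (n_hidden + 1), -0.5, 0.5),
                 nrow = n_output, ncol = n_hidden + 1)
  })
  structure(
    list(n_input = n_input, n_hidden = n_hidden, n_output = n_output,
         w1 = w1, w2 = w2, scaling = NULL, seed = seed,
         history = numeric(0)),
    class = "ee_bpnn"
  )
}

#' @export
print.ee_bpnn <- function(x, ...) {
  cat(sprintf("<ee_bpnn> %d-%d-%d logsig network%s\n",
              x$n_input, x$n_hidden, x$n_output,
              if (is.null(x$scaling)) " (unfitted)" else " (fitted)"))
  if (length(x$history) > 0) {
    cat(sprintf("  trained %d epochs, final scaled MSE %.3g\n",
                length(x$history), x$history[length(x$history)]))
  }
  invisible(x)
}

# forward pass keeping activations; X is n x n_input, scaled
bpnn_pass <- function(w1, w2, X) {
  A0 <- cbind(X, 1)
  U <- logsig(A0 %*% t(w1))       # n x h hidden activations
  A1 <- cbind(U, 1)
  Y <- logsig(A1 %*% t(w2))       # n x n_output
  list(A0 = A0, U = U, A1 = A1, Y = Y)
}

#' Forward pass of a network on scaled inputs
#'
#' Applies `logsig` at the hidden layer and again at the output layer, so
#' the raw output lies in (0, 1). Operates on the scaled representation;
#' use [predict.ee_bpnn()] for kcal-scale predictions.
#'
#' @param model An `ee_bpnn`.
#' @param x A scaled input vector of length `n_input`, or an
#'   `n x n_input` matrix.
#' @return Scaled output(s) in (0, 1).
#' @export
bpnn_forward <- function(model, x) {
  stopifnot(inherits(model, "ee_bpnn"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != model$n_input) {
    stop("input length must equal n_input = ", model$n_input, call. = FALSE)
  }
  drop(bpnn_pass(model$w1, model$w2, X)$Y)
}

#' Analytic error gradient of a network
#'
#' Gradient of the scaled mean-squared error `mean((Y - target)^2)` with
#' respect to every weight, by backpropagation. This is the quantity
#' checked against central finite differences in the test suite.
#'
#' @param model An `ee_bpnn`.
#' @param X Scaled input matrix (`n x n_input`).
#' @param target Scaled target vector/matrix.
#' @return List `w1`, `w2` (gradient matrices) and `error` (current MSE).
#' @export
bpnn_gradient <- function(model, X, target) {
  stopifnot(inherits(model, "ee_bpnn"))
  X <- as.matrix(X)
  dimnames(X) <- NULL
  target <- matrix(target, nrow = nrow(X))
  p <- bpnn_pass(model$w1, model$w2, X)
  n <- nrow(X) * ncol(target)
  d2 <- (2 / n) * (p$Y - target) * p$Y * (1 - p$Y)     # n x n_output
  g_w2 <- t(d2) %*% p$A1                               # n_output x (h+1)
  d1 <- (d2 %*% model$w2[, seq_len(model$n_hidden), drop = FALSE]) *
    p$U * (1 - p$U)                                    # n x h
  g_w1 <- t(d1) %*% p$A0                               # h x (n_input+1)
  list(w1 = g_w1, w2 = g_w2, error = mean((p$Y - target)^2))
}

#' Training configuration for the backpropagation network
#'
#' Batch gradient descent on the scaled MSE with a momentum term and an
#' adaptive learning rate: after each epoch, if the error grew by more than
#' `err_ratio` the step is discarded, the learning rate is multiplied by
#' `lr_down` and the momentum buffer is reset; otherwise the step is kept
#' and the rate is multiplied by `lr_up`. Training stops when the scaled
#' MSE reaches `goal` or after `max_epochs` epochs.
#'
#' @param max_epochs Upper limit on epochs (default 5000).
#' @param lr0 Initial learning rate (default 0.05).
#' @param momentum Momentum constant in \[0, 1) (default 0.9).
#' @param goal Scaled-MSE stopping goal (default 0.001).
#' @param lr_up,lr_down,err_ratio Adaptive-rate constants.
#' @param seed Seed recorded for weight initialisation by [fit_bpnn()].
#' @return A `bpnn_train_config` list.
#' @export
train_config <- function(max_epochs = 5000, lr0 = 0.05, momentum = 0.9,
                         goal = 0.001, lr_up = 1.05, lr_down = 0.7,
                         err_ratio = 1.04, seed = 1L) {
  stopifnot(max_epochs >= 0, lr0 > 0, momentum >= 0, momentum < 1,
            goal >= 0, lr_up >= 1, lr_down > 0, lr_down <= 1, err_ratio >= 1)
  structure(
    list(max_epochs = as.integer(max_epochs), lr0 = lr0, momentum = momentum,
         goal = goal, lr_up = lr_up, lr_down = lr_down,
         err_ratio = err_ratio, seed = as.integer(seed)),
    class = "bpnn_train_config"
  )
}

#' Train a network on scaled data
#'
#' Low-level trainer operating on already-scaled inputs (features in
#' \[0, 1\], targets in \[0.1, 0.9\]); [fit_bpnn()] wraps it with the
#' min-max scaling bookkeeping.
#'
#' @param model An `ee_bpnn` (weights used as the starting point).
#' @param X Scaled input matrix (`n x n_input`).
#' @param target Scaled target vector.
#' @param config A [train_config()].
#' @return List `model` (trained), `history` (scaled MSE after each epoch;
#'   length = epochs run), `lr_final`.
#' @export
bpnn_train <- function(model, X, target, config = train_config()) {
  stopifnot(inherits(model, "ee_bpnn"))
  X <- as.matrix(X)
  dimnames(X) <- NULL
  target <- matrix(target, nrow = nrow(X))
  w1 <- model$w1; w2 <- model$w2
  v1 <- w1 * 0; v2 <- w2 * 0
  lr <- config$lr0
  err <- mean((bpnn_pass(w1, w2, X)$Y - target)^2)
  history <- numeric(config$max_epochs)
  epochs <- 0L
  while (epochs < config$max_epochs && err > config$goal) {
    g <- bpnn_gradient(structure(
      list(n_input = model$n_input, n_hidden = model$n_hidden,
           n_output = model$n_output, w1 = w1, w2 = w2),
      class = "ee_bpnn"), X, target)
    if (!all(is.finite(g$w1)) || !all(is.finite(g$w2))) {
      stop(sprintf("non-finite gradient at epoch %d (lr = %.3g)",
                   epochs + 1L, lr), call. = FALSE)
    }
    v1_try <- config$momentum * v1 - lr * g$w1
    v2_try <- config$momentum * v2 - lr * g$w2
    w1_try <- w1 + v1_try
    w2_try <- w2 + v2_try
    err_try <- mean((bpnn_pass(w1_try, w2_try, X)$Y - target)^2)
    if (err_try > config$err_ratio * err) {
      lr <- lr * config$lr_down          # reject step
      v1 <- v1 * 0; v2 <- v2 * 0
    } else {
      w1 <- w1_try; w2 <- w2_try         # accept step
      v1 <- v1_try; v2 <- v2_try
      err <- err_try
      lr <- lr * config$lr_up
    }
    epochs <- epochs + 1L
    history[epochs] <- err
  }
  model$w1 <- w1
  model$w2 <- w2
  model$history <- history[seq_len(epochs)]
  list(model = model, history = history[seq_len(epochs)], lr_final = lr)
}

# min-max ranges; constant columns get an artificial unit range centred on
# the value so the scaled feature sits at 0.5
minmax_ranges <- function(M) {
  lo <- apply(M, 2, min)
  hi <- apply(M, 2, max)
  flat <- hi <= lo
  lo[flat] <- lo[flat] - 0.5
  hi[flat] <- hi[flat] + 0.5
  list(min = lo, max = hi)
}

scale_minmax <- function(M, rng) {
  sweep(sweep(M, 2, rng$min, "-"), 2, rng$max - rng$min, "/")
}

#' Fit a backpropagation EE network on feature rows
#'
#' High-level fit: min-max scales the 14 model-input features to \[0, 1\]
#' and the kcal targets to \[0.1, 0.9\] (headroom keeps the logsig output
#' away from its saturated ends), initialises the weights from the seed,
#' and trains with [bpnn_train()]. The fitted object carries its scaling so
#' [predict.ee_bpnn()] accepts unscaled rows and returns kcal.
#'
#' @param data Feature tibble (e.g. [window_features()] rows for one
#'   period).
#' @param target Target column name.
#' @param features Input column names (default [bpnn_feature_names()]).
#' @param n_hidden Hidden-node count.
#' @param config A [train_config()]; its `seed` drives initialisation.
#' @return A fitted `ee_bpnn` with `scaling` and `history`.
#' @export
fit_bpnn <- function(data, target = "ee", features = bpnn_feature_names(),
                     n_hidden = 6, config = train_config()) {
  missing_cols <- setdiff(c(features, target), names(data))
  if (length(missing_cols) > 0) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  Xr <- as.matrix(data[features])
  tr <- data[[target]]
  if (max(tr) <= min(tr)) stop("target has zero range", call. = FALSE)
  x_rng <- minmax_ranges(Xr)
  t_rng <- list(min = min(tr), max = max(tr))
  Xs <- scale_minmax(Xr, x_rng)
  ts <- 0.1 + 0.8 * (tr - t_rng$min) / (t_rng$max - t_rng$min)
  model <- init_network(length(features), n_hidden, 1, seed = config$seed)
  fit <- bpnn_train(model, Xs, ts, config)
  model <- fit$model
  model$scaling <- list(features = features, x_min = x_rng$min,
                        x_max = x_rng$max, t_min = t_rng$min,
                        t_max = t_rng$max)
  model$config <- config
  model
}

#' Predict energy expenditure from a fitted network
#'
#' Scales the input features with the ranges stored at fit time, runs the
#' forward pass, and inverts the \[0.1, 0.9\] target scaling back to kcal
#' per window.
#'
#' @param object A fitted `ee_bpnn` (from [fit_bpnn()]).
#' @param newdata Tibble holding the model's feature columns (unscaled).
#' @param ... Unused.
#' @return Numeric kcal/window predictions.
#' @export
predict.ee_bpnn <- function(object, newdata, ...) {
  if (is.null(object$scaling)) {
    stop("network has not been fitted (no scaling set)", call. = FALSE)
  }
  sc <- object$scaling
  miss <- setdiff(sc$features, names(newdata))
  if (length(miss) > 0) {
    stop("newdata lacks feature columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  Xs <- scale_minmax(as.matrix(newdata[sc$features]),
                     list(min = sc$x_min, max = sc$x_max))
  y <- bpnn_forward(object, Xs)
  sc$t_min + (y - 0.1) / 0.8 * (sc$t_max - sc$t_min)
}

# tie rule: smallest candidate among those attaining the minimum RMSE
select_hidden <- function(n_hidden, rmse) {
  o <- order(n_hidden)
  n_hidden <- n_hidden[o]; rmse <- rmse[o]
  n_hidden[which.min(rmse)]
}

#' Search the hidden-node count by held-out RMSE
#'
#' Trains one freshly initialised network per candidate count (seeded
#' deterministically from `config$seed` plus the candidate), evaluates RMSE
#' on a held-out quarter of the rows, and returns the candidate with the
#' lowest RMSE; ties go to the smallest count.
#'
#' @param data Feature tibble.
#' @param target Target column name.
#' @param candidates Candidate hidden-node counts (>= 2 of them), e.g.
#'   [heuristic_hidden_range()].
#' @param config A [train_config()].
#' @param features Input columns.
#' @param holdout Fraction of rows held out for the RMSE comparison.
#' @return An object of class `ee_node_search`: `best` and a `results`
#'   tibble (`n_hidden`, `rmse`).
#' @export
hidden_node_search <- function(data, target = "ee",
                               candidates = heuristic_hidden_range(14, 1),
                               config = train_config(),
                               features = bpnn_feature_names(),
                               holdout = 0.25) {
  stopifnot(length(candidates) >= 2, holdout > 0, holdout < 1)
  n <- nrow(data)
  idx_test <- withr::with_seed(config$seed,
                               sample.int(n, max(1L, round(holdout * n))))
  train <- data[-idx_test, , drop = FALSE]
  test <- data[idx_test, , drop = FALSE]
  res <- purrr::map_dfr(candidates, function(h) {
    cfg <- config
    cfg$seed <- config$seed + h
    m <- fit_bpnn(train, target = target, features = features,
                  n_hidden = h, config = cfg)
    tibble(n_hidden = h,
           rmse = rmse(test[[target]], predict(m, test)))
  })
  structure(
    list(best = select_hidden(res$n_hidden, res$rmse), results = res),
    class = "ee_node_search"
  )
}

#' @export
print.ee_node_search <- function(x, ...) {
  cat(sprintf("<ee_node_search> best n_hidden = %d of {%s}\n", x$best,
              paste(x$results$n_hidden, collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ee_bpnn <- function(x, ...) {
  w1 <- as.data.frame(as.table(x$w1))
  w2 <- as.data.frame(as.table(x$w2))
  dplyr::bind_rows(
    tibble(layer = "hidden", row = as.integer(w1$Var1),
           col = as.integer(w1$Var2), weight = w1$Freq),
    tibble(layer = "output", row = as.integer(w2$Var1),
           col = as.integer(w2$Var2), weight = w2$Freq)
  )
}

#' @exportS3Method generics::glance
glance.ee_bpnn <- function(x, ...) {
  tibble(
    n_input = x$n_input, n_hidden = x$n_hidden, n_output = x$n_output,
    epochs = length(x$history),
    final_mse = if (length(x$history)) x$history[length(x$history)] else NA_real_,
    fitted = !is.null(x$scaling)
  )
}
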