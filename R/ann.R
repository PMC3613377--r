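# Single-hidden-layer backpropagation network.
#
# Architecture: 4L one-hot inputs -> H logistic hidden units -> 1 logistic
# output. Targets are normalized by the maximum training strength so they fit
# the (0,1) output range; predictions are multiplied back by that maximum.
# Training is full-batch gradient descent on the sum-squared error with a
# momentum term and an adaptive learning rate: the rate grows after an epoch
# that reduces the SSE and shrinks (with the step rejected and momentum
# flushed) after an epoch that worsens it beyond a small factor.

#' Training configuration for the backpropagation network
#'
#' Defaults follow the classic gradient-descent-with-momentum-and-adaptive-
#' learning-rate scheme: 5,000 epochs maximum, SSE goal 0.2 (on
#' normalized targets), momentum 0.95, initial rate 0.01 adapted by factors
#' 1.05 (up) / 0.7 (down) with step rejection when the SSE grows by more than
#' 4%.
#'
#' @param hidden_neurons hidden-layer width H (model selection explores 5-30).
#' @param max_epochs maximum number of full-batch epochs.
#' @param sse_goal stop once the training SSE on normalized targets drops to
#'   this value.
#' @param momentum momentum factor in \[0, 1).
#' @param initial_learning_rate starting learning rate.
#' @param lr_increase_factor multiplier applied after an improving epoch (> 1).
#' @param lr_decrease_factor multiplier applied after a rejected epoch (in (0,1)).
#' @param max_perf_increase reject a step when `SSE_new > max_perf_increase *
#'   SSE_old`.
#' @param init_scale half-width of the uniform weight initialization,
#'   `U(-init_scale, init_scale)`.
#' @param seed RNG seed for weight initialization.
#' @return object of class `training_config`.
#' @export
training_config <- function(hidden_neurons = 19L,
                            max_epochs = 5000L,
                            sse_goal = 0.2,
                            momentum = 0.95,
                            initial_learning_rate = 0.01,
                            lr_increase_factor = 1.05,
                            lr_decrease_factor = 0.7,
                            max_perf_increase = 1.04,
                            init_scale = 0.5,
                            seed = 1L) {
  stopifnot(is_count(hidden_neurons), hidden_neurons >= 1,
            is_count(max_epochs), max_epochs >= 1,
            is_scalar_num(sse_goal), sse_goal > 0,
            is_scalar_num(momentum), momentum >= 0, momentum < 1,
            is_scalar_num(initial_learning_rate), initial_learning_rate > 0,
            is_scalar_num(lr_increase_factor), lr_increase_factor >= 1,
            is_scalar_num(lr_decrease_factor), lr_decrease_factor > 0,
            lr_decrease_factor <= 1,
            is_scalar_num(max_perf_increase), max_perf_increase > 1,
            is_scalar_num(init_scale), init_scale > 0,
            is_count(seed))
  structure(list(hidden_neurons = as.integer(hidden_neurons),
                 max_epochs = as.integer(max_epochs),
                 sse_goal = sse_goal, momentum = momentum,
                 initial_learning_rate = initial_learning_rate,
                 lr_increase_factor = lr_increase_factor,
                 lr_decrease_factor = lr_decrease_factor,
                 max_perf_increase = max_perf_increase,
                 init_scale = init_scale,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Logistic sigmoid activation
#'
#' `1 / (1 + exp(-x))`, elementwise; saturates numerically at 0 and 1
#' without overflow for any finite input.
#'
#' @param x numeric vector or matrix.
#' @return values in (0, 1), same shape as `x`.
#' @export
#' @examples
#' logsig(0)   # 0.5
#' logsig(1)   # 0.731...
logsig <- function(x) {
  # split by sign to avoid exp() overflow on large negative input
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Sum-squared error
#'
#' @param pred,target equal-length numeric vectors.
#' @return `sum((pred - target)^2)`.
#' @export
sse <- function(pred, target) {
  if (length(pred) != length(target) || length(pred) == 0L)
    fail("pred (%d) and target (%d) must be non-empty and equal length",
         length(pred), length(target))
  sum((pred - target)^2)
}

#' Prediction error (mean absolute error)
#'
#' The per-sequence prediction error `sum(|pred - target|) / n`, reported
#' alongside the SSE when evaluating models.
#'
#' @param pred,target equal-length numeric vectors.
#' @return non-negative scalar.
#' @export
prediction_error <- function(pred, target) {
  if (length(pred) != length(target) || length(pred) == 0L)
    fail("pred (%d) and target (%d) must be non-empty and equal length",
         length(pred), length(target))
  mean(abs(pred - target))
}

# forward pass on raw weights; returns list(a1 = hidden activations n x H,
# yhat = outputs length n)
ann_forward_pass <- function(w, X) {
  z1 <- X %*% t(w$W1)
  z1 <- sweep(z1, 2L, w$b1, "+")
  a1 <- logsig(z1)
  yhat <- as.numeric(logsig(a1 %*% t(w$W2) + w$b2))
  list(a1 = a1, yhat = yhat)
}

#' Analytic gradient of the SSE with respect to all weights
#'
#' Backpropagation gradients of `sum((yhat - t)^2)` for the two-layer
#' logistic network, exposed so they can be checked against finite
#' differences.
#'
#' @param weights list with `W1` (H x D), `b1` (H), `W2` (1 x H), `b2`
#'   (scalar).
#' @param X design matrix (n x D).
#' @param target normalized targets, length n.
#' @return list of gradients with the same shapes as `weights`.
#' @export
ann_gradient <- function(weights, X, target) {
  fp <- ann_forward_pass(weights, X)
  e <- fp$yhat - target
  d2 <- 2 * e * fp$yhat * (1 - fp$yhat)          # n
  gW2 <- matrix(d2 %*% fp$a1, nrow = 1L)          # 1 x H
  gb2 <- sum(d2)
  d1 <- (d2 %*% weights$W2) * fp$a1 * (1 - fp$a1) # n x H
  gW1 <- t(d1) %*% X                              # H x D
  gb1 <- colSums(d1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

#' Forward pass of a trained model
#'
#' Raw network outputs `logsig(W2 logsig(W1 x + b1) + b2)` per row of `X`,
#' on the normalized (0,1) scale. Use [predict_strength()] for denormalized
#' strengths.
#'
#' @param model an `ann_model`.
#' @param X encoded matrix with `model$input_length` columns.
#' @return numeric vector in (0, 1), one value per row.
#' @export
ann_forward <- function(model, X) {
  stopifnot(inherits(model, "ann_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$input_length)
    fail("input width mismatch: model expects %d columns, received %d",
         model$input_length, ncol(X))
  w <- list(W1 = model$hidden_weights, b1 = model$hidden_bias,
            W2 = model$output_weights, b2 = model$output_bias)
  ann_forward_pass(w, X)$yhat
}

#' Train the backpropagation network
#'
#' Fits the single-hidden-layer logistic network to one-hot encoded sequences
#' and their relative strengths. Targets are divided by `max(y)` before
#' fitting (the logistic output lives in (0,1)); the divisor is stored in the
#' model as `normalization_max` and multiplied back at prediction time.
#' Optimization is full-batch gradient descent with momentum and an adaptive
#' learning rate; training stops when the SSE on normalized targets reaches
#' `config$sse_goal` or after `config$max_epochs` epochs. Fully reproducible
#' from `config$seed`.
#'
#' @param X encoded design matrix (n x 4L) from [encode_library()], or a
#'   character vector of equal-length sequences.
#' @param y non-negative relative strengths, one per row; `max(y)` must be
#'   positive.
#' @param config a [training_config()].
#' @return object of class `ann_model`: weights, biases, `normalization_max`,
#'   per-epoch SSE trace (`training_log`), `final_sse`, `converged`, and the
#'   config used.
#' @export
train_network <- function(X, y, config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  if (is.character(X)) X <- encode_library(X)
  if (!is.matrix(X)) fail("`X` must be an encoded matrix or character vector")
  n <- nrow(X); D <- ncol(X)
  if (n < 2L) fail("training needs at least 2 sequences")
  if (length(y) != n)
    fail("rows of X (%d) and length of y (%d) differ", n, length(y))
  if (any(!is.finite(y)) || any(y < 0)) fail("strengths must be finite and >= 0")
  ymax <- max(y)
  if (ymax <= 0) fail("degenerate targets: all strengths are zero")
  t <- y / ymax
  H <- config$hidden_neurons
  storage.mode(X) <- "double"

  w <- with_seed(config$seed, list(
    W1 = matrix(runif(H * D, -config$init_scale, config$init_scale), H, D),
    b1 = runif(H, -config$init_scale, config$init_scale),
    W2 = matrix(runif(H, -config$init_scale, config$init_scale), 1L, H),
    b2 = runif(1L, -config$init_scale, config$init_scale)))

  lr <- config$initial_learning_rate
  mc <- config$momentum
  v <- list(W1 = w$W1 * 0, b1 = w$b1 * 0, W2 = w$W2 * 0, b2 = 0)
  sse_cur <- sse(ann_forward_pass(w, X)$yhat, t)
  trace <- numeric(config$max_epochs)
  epoch <- 0L
  while (epoch < config$max_epochs && sse_cur > config$sse_goal) {
    epoch <- epoch + 1L
    g <- ann_gradient(w, X, t)
    # momentum step: v <- mc * v + lr * (1 - mc) * (-grad)
    step <- list(W1 = mc * v$W1 - lr * (1 - mc) * g$W1,
                 b1 = mc * v$b1 - lr * (1 - mc) * g$b1,
                 W2 = mc * v$W2 - lr * (1 - mc) * g$W2,
                 b2 = mc * v$b2 - lr * (1 - mc) * g$b2)
    cand <- list(W1 = w$W1 + step$W1, b1 = w$b1 + step$b1,
                 W2 = w$W2 + step$W2, b2 = w$b2 + step$b2)
    sse_new <- sse(ann_forward_pass(cand, X)$yhat, t)
    if (!is.finite(sse_new))
      fail("non-finite training loss at epoch %d (learning rate %.3g)",
           epoch, lr)
    if (sse_new > config$max_perf_increase * sse_cur) {
      # reject: shrink the rate and flush accumulated momentum
      lr <- lr * config$lr_decrease_factor
      v <- list(W1 = w$W1 * 0, b1 = w$b1 * 0, W2 = w$W2 * 0, b2 = 0)
    } else {
      if (sse_new < sse_cur) lr <- lr * config$lr_increase_factor
      w <- cand
      v <- step
      sse_cur <- sse_new
    }
    trace[epoch] <- sse_cur
  }

  structure(list(input_length = D,
                 hidden_weights = w$W1, hidden_bias = w$b1,
                 output_weights = w$W2, output_bias = w$b2,
                 normalization_max = ymax,
                 activation = "logsig",
                 training_log = trace[seq_len(epoch)],
                 final_sse = sse_cur,
                 converged = sse_cur <= config$sse_goal,
                 epochs = epoch,
                 config = config),
            class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("ann_model: %d -> %d -> 1 (logsig), normalization max %.4g\n",
              x$input_length, x$config$hidden_neurons, x$normalization_max))
  cat(sprintf("  trained %d epochs, final SSE %.4g (%s goal %.3g)\n",
              x$epochs, x$final_sse,
              if (x$converged) "reached" else "did not reach",
              x$config$sse_goal))
  invisible(x)
}

#' Predict relative strengths with a trained model
#'
#' Runs the forward pass and multiplies by the stored training maximum, so
#' predictions land on the measurement scale. Every prediction lies strictly
#' inside (0, `normalization_max`): the model cannot design beyond the
#' strongest element it was trained on.
#'
#' @param model an `ann_model` from [train_network()].
#' @param seqs character vector of sequences of the trained length, or an
#'   encoded matrix with `model$input_length` columns.
#' @return numeric vector of predicted relative strengths.
#' @export
predict_strength <- function(model, seqs) {
  stopifnot(inherits(model, "ann_model"))
  if (is.character(seqs)) {
    L <- model$input_length / 4L
    bad <- nchar(seqs) != L
    if (any(bad))
      fail("sequence length %d does not match trained length %d nt",
           nchar(seqs[bad][1L]), L)
    seqs <- encode_library(seqs)
  }
  ann_forward(model, seqs) * model$normalization_max
}

#' Serialize a trained model to JSON
#'
#' Weights are stored row-major with the input length, normalization constant
#' and full training configuration, version-tagged, so models round-trip
#' across platforms.
#'
#' @param model an `ann_model`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  obj <- list(format = "promnet_ann_model", version = 1L,
              input_length = model$input_length,
              hidden_weights = model$hidden_weights,
              hidden_bias = model$hidden_bias,
              output_weights = as.numeric(model$output_weights),
              output_bias = model$output_bias,
              normalization_max = model$normalization_max,
              activation = model$activation,
              training_log = model$training_log,
              final_sse = model$final_sse,
              converged = model$converged,
              epochs = model$epochs,
              config = unclass(model$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a trained model from JSON
#'
#' @param path path written by [write_model()].
#' @return an `ann_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "promnet_ann_model"))
    fail("'%s' is not a serialized model", path)
  cfg <- do.call(training_config, as.list(obj$config))
  W1 <- obj$hidden_weights
  if (!is.matrix(W1)) W1 <- matrix(W1, nrow = cfg$hidden_neurons, byrow = TRUE)
  structure(list(input_length = as.integer(obj$input_length),
                 hidden_weights = W1,
                 hidden_bias = as.numeric(obj$hidden_bias),
                 output_weights = matrix(obj$output_weights, nrow = 1L),
                 output_bias = as.numeric(obj$output_bias),
                 normalization_max = obj$normalization_max,
                 activation = obj$activation,
                 training_log = as.numeric(obj$training_log),
                 final_sse = obj$final_sse,
                 converged = obj$converged,
                 epochs = as.integer(obj$epochs),
                 config = cfg),
            class = "ann_model")
}
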