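# Tied-weight denoising auto-encoders and greedy layer-wise pretraining.
#
# A layer encodes V -> h = s(W V + b) and decodes h -> Vhat = s(W' h + b')
# with tied decoder weights W' = t(W). Training minimizes the summed
# cross-entropy between the clean input and the reconstruction of a
# stochastically corrupted input (a fraction P of entries set to zero).

#' Numerically stable logistic sigmoid
#'
#' `1 / (1 + exp(-x))`, computed without overflow for large `|x|`.
#'
#' @param x numeric vector, matrix or scalar.
#' @return values in (0, 1), same shape as `x`.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Create a denoising auto-encoder layer
#'
#' Weights are initialized uniformly in `+/- 4 sqrt(6 / (d_v + d_h))` (the
#' standard range for sigmoid layers, drawn from the current RNG stream);
#' biases start at zero. Decoder weights are tied to `t(W)` and never stored.
#'
#' @param d_v visible (input) dimension.
#' @param d_h hidden dimension.
#' @param P corruption fraction in \[0, 1\].
#' @return object of class `dae_layer`: list with `W` (`d_h` x `d_v`), `b`
#'   (length `d_h`), `b_prime` (length `d_v`), `P`.
#' @export
dae_layer <- function(d_v, d_h, P = 0.25) {
  stopifnot(d_v >= 1, d_h >= 1, P >= 0, P <= 1)
  r <- 4 * sqrt(6 / (d_v + d_h))
  structure(
    list(
      W = matrix(stats::runif(d_h * d_v, -r, r), nrow = d_h, ncol = d_v),
      b = rep(0, d_h),
      b_prime = rep(0, d_v),
      P = P
    ),
    class = "dae_layer"
  )
}

.as_batch <- function(V, d) {
  if (is.matrix(V)) {
    if (ncol(V) != d) stop("input dimension mismatch", call. = FALSE)
    V
  } else {
    if (length(V) != d) stop("input dimension mismatch", call. = FALSE)
    matrix(V, nrow = 1)
  }
}

#' Encode inputs to hidden representations
#'
#' `h = sigmoid(W V + b)`, applied row-wise to a batch.
#'
#' @param layer a [dae_layer()].
#' @param V numeric vector of length `d_v` or matrix with `d_v` columns.
#' @return hidden activations in (0, 1); a vector for vector input, a matrix
#'   (one row per input) otherwise.
#' @export
dae_encode <- function(layer, V) {
  vec <- !is.matrix(V)
  Vm <- .as_batch(V, ncol(layer$W))
  h <- sigmoid(sweep(Vm %*% t(layer$W), 2, layer$b, "+"))
  if (vec) as.numeric(h) else h
}

#' Decode hidden representations to reconstructions
#'
#' `Vhat = sigmoid(t(W) h + b_prime)` (tied weights), applied row-wise.
#'
#' @param layer a [dae_layer()].
#' @param h numeric vector of length `d_h` or matrix with `d_h` columns.
#' @return reconstructions in (0, 1), shaped like the input convention of
#'   [dae_encode()].
#' @export
dae_decode <- function(layer, h) {
  vec <- !is.matrix(h)
  hm <- .as_batch(h, nrow(layer$W))
  v <- sigmoid(sweep(hm %*% layer$W, 2, layer$b_prime, "+"))
  if (vec) as.numeric(v) else v
}

#' Cross-entropy reconstruction loss
#'
#' `-sum_k [V_k log Vhat_k + (1 - V_k) log(1 - Vhat_k)]` per sample.
#' Reconstruction values at exactly 0 or 1 are clipped to `[eps, 1 - eps]`
#' (with a warning) so the loss stays finite.
#'
#' @param V clean inputs in \[0, 1\] (vector or matrix, one row per sample).
#' @param V_hat reconstructions in (0, 1), same shape.
#' @param eps clipping bound.
#' @return per-sample loss (scalar for vector input, vector for a batch).
#' @export
cross_entropy <- function(V, V_hat, eps = 1e-12) {
  stopifnot(length(V) == length(V_hat))
  if (any(V_hat <= 0 | V_hat >= 1)) {
    warning("reconstruction values clipped to (0, 1) for the log loss")
    V_hat <- pmin(pmax(V_hat, eps), 1 - eps)
  }
  l <- -(V * log(V_hat) + (1 - V) * log(1 - V_hat))
  if (is.matrix(V)) rowSums(l) else sum(l)
}

#' Stochastic corruption
#'
#' Independently zeroes each entry with probability `P` (draws from the
#' current RNG stream), leaving the others untouched.
#'
#' @param V numeric vector or matrix.
#' @param P corruption fraction in \[0, 1\].
#' @return corrupted copy of `V`.
#' @export
corrupt <- function(V, P) {
  stopifnot(P >= 0, P <= 1)
  if (P == 0) return(V)
  V * (stats::runif(length(V)) >= P)
}

# forward pass pieces shared by loss and gradient
.dae_forward <- function(layer, batch, corrupted) {
  h <- dae_encode(layer, corrupted)
  v_hat <- dae_decode(layer, h)
  list(h = h, v_hat = v_hat)
}

#' Denoising objective of a batch
#'
#' Summed cross-entropy between the clean batch and the reconstruction of
#' its corrupted version.
#'
#' @param layer a [dae_layer()].
#' @param batch matrix of clean inputs in \[0, 1\], one row per sample.
#' @param corrupted optional pre-corrupted batch (same shape); corrupted
#'   with the layer's `P` from the current RNG stream when `NULL`.
#' @return total loss (sum over the batch).
#' @export
dae_loss <- function(layer, batch, corrupted = NULL) {
  batch <- .as_batch(batch, ncol(layer$W))
  if (is.null(corrupted)) corrupted <- corrupt(batch, layer$P)
  f <- .dae_forward(layer, batch, corrupted)
  sum(cross_entropy(batch, f$v_hat))
}

#' Gradient of the denoising objective
#'
#' Exact backpropagation gradient of the summed corrupted-input
#' reconstruction cross-entropy with respect to `W`, `b` and `b_prime`.
#' Tied weights accumulate both the encoder-side and the decoder-side
#' contribution into the single `W` gradient. Sums over the batch (so a
#' duplicated batch doubles the gradient).
#'
#' @inheritParams dae_loss
#' @return list with `W`, `b`, `b_prime` gradients and the batch `loss`.
#' @export
dae_gradient <- function(layer, batch, corrupted = NULL) {
  batch <- .as_batch(batch, ncol(layer$W))
  if (is.null(corrupted)) corrupted <- corrupt(batch, layer$P)
  corrupted <- .as_batch(corrupted, ncol(layer$W))
  f <- .dae_forward(layer, batch, corrupted)
  h <- .as_batch(f$h, nrow(layer$W))
  v_hat <- .as_batch(f$v_hat, ncol(layer$W))
  d_out <- v_hat - batch                      # dL/dz' for sigmoid + BCE
  d_h <- (d_out %*% t(layer$W)) * h * (1 - h) # back through tied decoder
  list(
    W = t(d_h) %*% corrupted + t(h) %*% d_out,
    b = colSums(d_h),
    b_prime = colSums(d_out),
    loss = sum(cross_entropy(batch, v_hat))
  )
}

#' Train one denoising auto-encoder by mini-batch SGD
#'
#' Shuffled mini-batches; the update uses the batch-mean gradient scaled by
#' `lr`. The reported history entry for an epoch is the mean objective per
#' sample evaluated at the parameters in force when each batch was visited.
#' Corruption is resampled every epoch per example unless
#' `resample_corruption = FALSE`, in which case one corruption mask drawn at
#' the start is reused throughout (useful for verifying monotone descent).
#'
#' @param layer a [dae_layer()].
#' @param data matrix of inputs in \[0, 1\], one row per sample.
#' @param epochs number of passes over the data.
#' @param lr learning rate (> 0 to train; 0 leaves parameters unchanged).
#' @param batch_size mini-batch size; `>= nrow(data)` gives full-batch
#'   descent.
#' @param resample_corruption redraw the corruption mask every epoch.
#' @param shuffle shuffle sample order every epoch.
#' @return list with the trained `layer` and `loss_history` (mean objective
#'   per epoch).
#' @export
train_dae <- function(layer, data, epochs = 30, lr = 0.1, batch_size = 32,
                      resample_corruption = TRUE, shuffle = TRUE) {
  stopifnot(lr >= 0, epochs >= 1)
  data <- .as_batch(data, ncol(layer$W))
  n <- nrow(data)
  fixed_corr <- if (!resample_corruption) corrupt(data, layer$P) else NULL
  history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    corr <- if (resample_corruption) corrupt(data, layer$P) else fixed_corr
    ord <- if (shuffle && batch_size < n) sample.int(n) else seq_len(n)
    total <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      g <- dae_gradient(layer, data[idx, , drop = FALSE],
                        corrupted = corr[idx, , drop = FALSE])
      if (!is.finite(g$loss)) {
        stop("non-finite reconstruction loss at epoch ", e, call. = FALSE)
      }
      total <- total + g$loss
      m <- length(idx)
      layer$W <- layer$W - lr * g$W / m
      layer$b <- layer$b - lr * g$b / m
      layer$b_prime <- layer$b_prime - lr * g$b_prime / m
    }
    history[e] <- total / n
  }
  list(layer = layer, loss_history = history)
}

#' Greedy layer-wise pretraining of a stacked denoising auto-encoder
#'
#' Trains the first layer on the data, then each subsequent layer on the
#' clean (uncorrupted) encodings of the previous one. Layer sizes must be
#' strictly decreasing and smaller than the input dimension, so the stack
#' abstracts progressively compact features.
#'
#' @param data matrix of inputs in \[0, 1\], one row per sample.
#' @param layer_sizes strictly decreasing hidden sizes, first smaller than
#'   `ncol(data)`.
#' @param P corruption fraction.
#' @param lr,epochs,batch_size SGD hyperparameters per layer, see
#'   [train_dae()].
#' @return object of class `sda_model`: list with `layers` (trained
#'   [dae_layer()]s), `input_dim`, `loss_histories`.
#' @export
sda_pretrain <- function(data, layer_sizes, P = 0.25, lr = 0.1, epochs = 30,
                         batch_size = 32) {
  data <- as.matrix(data)
  if (nrow(data) == 0) stop("empty training data", call. = FALSE)
  sizes <- as.integer(layer_sizes)
  if (length(sizes) == 0 || any(diff(sizes) >= 0) || sizes[1] >= ncol(data)) {
    stop("layer_sizes must be strictly decreasing and smaller than the input dimension",
         call. = FALSE)
  }
  layers <- vector("list", length(sizes))
  histories <- vector("list", length(sizes))
  current <- data
  for (k in seq_along(sizes)) {
    layer <- dae_layer(ncol(current), sizes[k], P = P)
    fit <- train_dae(layer, current, epochs = epochs, lr = lr,
                     batch_size = batch_size)
    layers[[k]] <- fit$layer
    histories[[k]] <- fit$loss_history
    current <- dae_encode(fit$layer, current)
  }
  structure(
    list(layers = layers, input_dim = ncol(data), loss_histories = histories),
    class = "sda_model"
  )
}

#' Bottleneck features of a stacked model
#'
#' Composition of all encoder layers; the abstracted feature representation
#' fed to the classifier head.
#'
#' @param model an [sda_pretrain()] result.
#' @param V input vector of length `input_dim` or matrix with that many
#'   columns.
#' @return bottleneck activations in (0, 1).
#' @export
sda_features <- function(model, V) {
  stopifnot(inherits(model, "sda_model"))
  for (layer in model$layers) V <- dae_encode(layer, V)
  V
}
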