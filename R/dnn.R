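# Softmax deep neural network classifier initialized from a pretrained
# stacked denoising auto-encoder, with supervised fine-tuning and
# patient-specific adaptation.

#' Initialize a DNN classifier from a pretrained stacked model
#'
#' Copies the encoder weights and biases by value and adds a 4-way softmax
#' head (classes in the fixed order N, S, V, F) with zero-initialized
#' weights, so an untrained head outputs uniform class probabilities. The
#' source model is never modified by subsequent training of the classifier.
#'
#' @param sda an [sda_pretrain()] result with at least one layer.
#' @return object of class `dnn_classifier`: list with `layers` (each `W`,
#'   `b`), `softmax_W` (4 x bottleneck), `softmax_b` (length 4), `classes`,
#'   `input_dim`.
#' @export
dnn_from_sda <- function(sda) {
  if (!inherits(sda, "sda_model") || length(sda$layers) == 0) {
    stop("need a trained stacked model with at least one layer", call. = FALSE)
  }
  layers <- lapply(sda$layers, function(l) list(W = l$W, b = l$b))
  d <- nrow(sda$layers[[length(sda$layers)]]$W)
  structure(
    list(
      layers = layers,
      softmax_W = matrix(0, nrow = 4, ncol = d),
      softmax_b = rep(0, 4),
      classes = aami_classes(),
      input_dim = sda$input_dim
    ),
    class = "dnn_classifier"
  )
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass; returns hidden activations per layer and class probabilities
.dnn_forward <- function(clf, X) {
  H <- vector("list", length(clf$layers))
  a <- X
  for (i in seq_along(clf$layers)) {
    a <- sigmoid(sweep(a %*% t(clf$layers[[i]]$W), 2, clf$layers[[i]]$b, "+"))
    H[[i]] <- a
  }
  logits <- sweep(a %*% t(clf$softmax_W), 2, clf$softmax_b, "+")
  list(H = H, probs = .softmax(logits))
}

#' Class probabilities
#'
#' Forward pass through the encoder layers and the softmax head.
#'
#' @param clf a [dnn_from_sda()] classifier.
#' @param X input vector of length `input_dim` or matrix with that many
#'   columns, entries in \[0, 1\].
#' @return probability matrix (one row per input, columns N, S, V, F), rows
#'   summing to 1; a named vector for vector input.
#' @export
dnn_predict_proba <- function(clf, X) {
  vec <- !is.matrix(X)
  Xm <- .as_batch(X, clf$input_dim)
  p <- .dnn_forward(clf, Xm)$probs
  colnames(p) <- clf$classes
  if (vec) p[1, ] else p
}

#' Predicted heartbeat class
#'
#' Argmax of the class probabilities; ties are broken toward the earlier
#' class in the fixed order N < S < V < F.
#'
#' @inheritParams dnn_predict_proba
#' @return character vector of predicted classes.
#' @export
dnn_predict <- function(clf, X) {
  p <- dnn_predict_proba(clf, .as_batch(X, clf$input_dim))
  clf$classes[max.col(p, ties.method = "first")]
}

.one_hot <- function(y, classes) {
  bad <- setdiff(unique(y), classes)
  if (length(bad) > 0) {
    stop("unknown class label: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- matrix(0, nrow = length(y), ncol = length(classes))
  m[cbind(seq_along(y), match(y, classes))] <- 1
  m
}

#' Gradient of the mean categorical cross-entropy
#'
#' Exact backpropagation through the softmax head and all encoder layers.
#' The loss is the mean cross-entropy over the batch.
#'
#' @param clf a `dnn_classifier`.
#' @param X input matrix (rows in \[0, 1\]).
#' @param y character labels in N, S, V, F.
#' @return list with `softmax_W`, `softmax_b`, `layers` (list of `W`, `b`
#'   gradients per encoder layer), `loss`, `accuracy`.
#' @export
dnn_gradient <- function(clf, X, y) {
  X <- .as_batch(X, clf$input_dim)
  Y <- .one_hot(y, clf$classes)
  n <- nrow(X)
  f <- .dnn_forward(clf, X)
  p <- pmin(pmax(f$probs, 1e-300), 1)
  loss <- -sum(Y * log(p)) / n
  acc <- mean(clf$classes[max.col(f$probs, ties.method = "first")] == y)

  d <- (f$probs - Y) / n # dL/dlogits for softmax + CE, mean convention
  last <- length(clf$layers)
  g_sw <- t(d) %*% f$H[[last]]
  g_sb <- colSums(d)
  g_layers <- vector("list", last)
  delta <- (d %*% clf$softmax_W) * f$H[[last]] * (1 - f$H[[last]])
  for (i in last:1) {
    below <- if (i == 1) X else f$H[[i - 1]]
    g_layers[[i]] <- list(W = t(delta) %*% below, b = colSums(delta))
    if (i > 1) {
      delta <- (delta %*% clf$layers[[i]]$W) * f$H[[i - 1]] * (1 - f$H[[i - 1]])
    }
  }
  list(softmax_W = g_sw, softmax_b = g_sb, layers = g_layers,
       loss = loss, accuracy = acc)
}

.dnn_sgd_epoch <- function(clf, X, y, lr, batch_size, shuffle = TRUE) {
  n <- nrow(X)
  ord <- if (shuffle && batch_size < n) sample.int(n) else seq_len(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- ord[start:min(start + batch_size - 1, n)]
    g <- dnn_gradient(clf, X[idx, , drop = FALSE], y[idx])
    if (!is.finite(g$loss)) stop("non-finite training loss", call. = FALSE)
    clf$softmax_W <- clf$softmax_W - lr * g$softmax_W
    clf$softmax_b <- clf$softmax_b - lr * g$softmax_b
    for (i in seq_along(clf$layers)) {
      clf$layers[[i]]$W <- clf$layers[[i]]$W - lr * g$layers[[i]]$W
      clf$layers[[i]]$b <- clf$layers[[i]]$b - lr * g$layers[[i]]$b
    }
  }
  clf
}

#' Supervised fine-tuning of the classifier
#'
#' Mini-batch SGD on the mean categorical cross-entropy, updating the
#' softmax head and all encoder layers jointly from the start.
#'
#' @param clf a `dnn_classifier`.
#' @param X input matrix (rows in \[0, 1\]).
#' @param y character labels in N, S, V, F.
#' @param lr learning rate.
#' @param epochs passes over the data.
#' @param batch_size mini-batch size.
#' @param shuffle shuffle sample order every epoch.
#' @return list with the trained `classifier` and `history` (data frame of
#'   per-epoch training loss and accuracy, evaluated after each epoch).
#' @export
dnn_fine_tune <- function(clf, X, y, lr = 0.1, epochs = 30, batch_size = 32,
                          shuffle = TRUE) {
  stopifnot(lr >= 0, epochs >= 1)
  X <- .as_batch(X, clf$input_dim)
  stopifnot(nrow(X) == length(y))
  .one_hot(y, clf$classes) # label validation
  history <- data.frame(epoch = seq_len(epochs), loss = NA_real_,
                        accuracy = NA_real_)
  for (e in seq_len(epochs)) {
    if (lr > 0) clf <- .dnn_sgd_epoch(clf, X, y, lr, batch_size, shuffle)
    g <- dnn_gradient(clf, X, y)
    history$loss[e] <- g$loss
    history$accuracy[e] <- g$accuracy
  }
  list(classifier = clf, history = history)
}

#' Patient-specific adaptation
#'
#' Fine-tunes an independent copy of an interpatient classifier on the first
#' `n_adapt` beats of a patient's record (time order), with early stopping:
#' training stops when adaptation-set accuracy has not improved for
#' `patience` consecutive epochs or after `max_iter` epochs, and the
#' parameters achieving the best adaptation-set accuracy are returned.
#' `n_adapt = 0` returns an unchanged copy. If fewer beats than `n_adapt`
#' are available, all are used and the shortfall is recorded.
#'
#' @param clf the interpatient `dnn_classifier` (left unmodified).
#' @param X patient beat representations, rows in time order.
#' @param y AAMI labels, one per row.
#' @param n_adapt number of initial beats used for adaptation.
#' @param lr,batch_size SGD hyperparameters.
#' @param patience epochs without accuracy improvement tolerated before
#'   stopping.
#' @param max_iter maximum number of adaptation epochs.
#' @return list with the adapted `classifier`, `history` (per-epoch
#'   adaptation-set accuracy), `n_used` and `shortfall`.
#' @export
patient_adapt <- function(clf, X, y, n_adapt = 300, lr = 0.1,
                          batch_size = 32, patience = 10, max_iter = 200) {
  stopifnot(n_adapt >= 0)
  X <- .as_batch(X, clf$input_dim)
  stopifnot(nrow(X) == length(y))
  if (n_adapt == 0) {
    return(list(classifier = clf, history = numeric(0), n_used = 0L,
                shortfall = 0L))
  }
  n_used <- min(n_adapt, nrow(X))
  shortfall <- n_adapt - n_used
  Xa <- X[seq_len(n_used), , drop = FALSE]
  ya <- y[seq_len(n_used)]
  .one_hot(ya, clf$classes)

  best <- clf
  best_acc <- mean(dnn_predict(clf, Xa) == ya)
  wait <- 0L
  history <- numeric(0)
  for (e in seq_len(max_iter)) {
    clf <- .dnn_sgd_epoch(clf, Xa, ya, lr, batch_size)
    acc <- mean(dnn_predict(clf, Xa) == ya)
    history <- c(history, acc)
    if (acc > best_acc + 1e-12) {
      best_acc <- acc
      best <- clf
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(classifier = best, history = history, n_used = as.integer(n_used),
       shortfall = as.integer(shortfall))
}
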