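make_sda <- function(d_v = 6, d_h = 3, seed = 1) {
  set.seed(seed)
  structure(
    list(layers = list(dae_layer(d_v, d_h)), input_dim = d_v,
         loss_histories = list(numeric(0))),
    class = "sda_model"
  )
}

test_that("classifier initialization copies the encoder by value", {
  sda <- make_sda()
  clf <- dnn_from_sda(sda)
  expect_identical(clf$layers[[1]]$W, sda$layers[[1]]$W)
  expect_identical(clf$softmax_W, matrix(0, 4, 3))
  expect_identical(clf$classes, c("N", "S", "V", "F"))
  # zero softmax head: uniform probabilities on any input
  p <- dnn_predict_proba(clf, runif(6))
  expect_equal(unname(p), rep(0.25, 4))
  # mutating the classifier leaves the source model untouched
  W0 <- sda$layers[[1]]$W
  clf$layers[[1]]$W[] <- 99
  expect_identical(sda$layers[[1]]$W, W0)
  expect_error(dnn_from_sda(structure(list(layers = list()),
                                      class = "sda_model")),
               "at least one layer")
})

test_that("softmax probabilities are a shift-invariant simplex", {
  sda <- make_sda()
  clf <- dnn_from_sda(sda)
  clf$softmax_b <- c(1, 0, 0, 0) # logits (1, 0, 0, 0) on any input
  p <- dnn_predict_proba(clf, runif(6))
  expect_equal(unname(p),
               c(exp(1), 1, 1, 1) / (exp(1) + 3), tolerance = 1e-12)
  expect_equal(unname(p[1]), 0.4754, tolerance = 1e-4)
  clf2 <- clf
  clf2$softmax_b <- clf$softmax_b + 7 # constant logit shift
  expect_equal(dnn_predict_proba(clf2, runif(6)),
               dnn_predict_proba(clf, runif(6)), tolerance = 1e-12)

  set.seed(4)
  X <- matrix(runif(60), 10, 6)
  P <- dnn_predict_proba(clf, X)
  expect_true(all(P > 0))
  expect_equal(unname(rowSums(P)), rep(1, 10), tolerance = 1e-12)
})

test_that("prediction is the argmax with ties broken toward N", {
  clf <- dnn_from_sda(make_sda())
  expect_equal(dnn_predict(clf, runif(6)), "N") # uniform -> first class
  clf$softmax_b <- log(c(0.1, 0.7, 0.1, 0.1))
  expect_equal(dnn_predict(clf, runif(6)), "S")
  set.seed(5)
  clf$softmax_W <- matrix(rnorm(12), 4, 3)
  X <- matrix(runif(600), 100, 6)
  P <- dnn_predict_proba(clf, X)
  expect_equal(dnn_predict(clf, X),
               clf$classes[apply(P, 1, which.max)])
})

test_that("backpropagation matches central finite differences", {
  set.seed(6)
  sda <- structure(
    list(layers = list(dae_layer(5, 4), dae_layer(4, 3)), input_dim = 5,
         loss_histories = list()),
    class = "sda_model"
  )
  clf <- dnn_from_sda(sda)
  clf$softmax_W <- matrix(rnorm(12, sd = 0.3), 4, 3)
  X <- matrix(runif(50), 10, 5)
  y <- sample(c("N", "S", "V", "F"), 10, replace = TRUE)
  g <- dnn_gradient(clf, X, y)
  eps <- 1e-5
  loss_at <- function(cl) dnn_gradient(cl, X, y)$loss
  check <- function(get, set, grad) {
    p <- get(clf)
    num <- p
    for (i in seq_along(p)) {
      cp <- clf; pp <- p; pp[i] <- pp[i] + eps; cp <- set(cp, pp)
      cm <- clf; pm <- p; pm[i] <- pm[i] - eps; cm <- set(cm, pm)
      num[i] <- (loss_at(cp) - loss_at(cm)) / (2 * eps)
    }
    expect_rel_error_lt(grad, num, 1e-5)
  }
  check(function(c) c$softmax_W,
        function(c, v) { c$softmax_W[] <- v; c }, g$softmax_W)
  check(function(c) c$softmax_b,
        function(c, v) { c$softmax_b <- v; c }, g$softmax_b)
  for (li in 1:2) {
    check(function(c) c$layers[[li]]$W,
          function(c, v) { c$layers[[li]]$W[] <- v; c }, g$layers[[li]]$W)
    check(function(c) c$layers[[li]]$b,
          function(c, v) { c$layers[[li]]$b <- v; c }, g$layers[[li]]$b)
  }
})

test_that("fine-tuning learns a separable toy problem", {
  set.seed(7)
  n <- 40
  X <- rbind(
    matrix(runif(n * 4, 0, 0.3), n, 4),
    matrix(runif(n * 4, 0.7, 1), n, 4)
  )
  y <- rep(c("N", "V"), each = n)
  clf <- dnn_from_sda(make_sda(4, 3, seed = 7))
  frozen <- dnn_fine_tune(clf, X, y, lr = 0, epochs = 2)
  expect_identical(frozen$classifier$layers[[1]]$W, clf$layers[[1]]$W)
  expect_error(dnn_fine_tune(clf, X, rep("Z", 2 * n)), "unknown class")

  fit <- dnn_fine_tune(clf, X, y, lr = 0.5, epochs = 200, batch_size = 16)
  expect_equal(tail(fit$history$accuracy, 1), 1)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
})

test_that("patient adaptation copies, early-stops and respects n_adapt = 0", {
  set.seed(8)
  X <- matrix(runif(200), 50, 4)
  y <- sample(c("N", "S", "V", "F"), 50, replace = TRUE)
  clf <- dnn_from_sda(make_sda(4, 3, seed = 8))
  base_pred <- dnn_predict(clf, X)

  none <- patient_adapt(clf, X, y, n_adapt = 0)
  expect_identical(dnn_predict(none$classifier, X), base_pred)
  expect_identical(none$n_used, 0L)

  fit <- patient_adapt(clf, X, y, n_adapt = 30, lr = 0.3, max_iter = 50,
                       patience = 5)
  expect_identical(fit$n_used, 30L)
  expect_lte(length(fit$history), 50)
  # the interpatient classifier itself is unchanged
  expect_identical(dnn_predict(clf, X), base_pred)
  # shortfall recorded when fewer beats than requested
  short <- patient_adapt(clf, X, y, n_adapt = 80, lr = 0.1, max_iter = 5)
  expect_identical(short$n_used, 50L)
  expect_identical(short$shortfall, 30L)
})
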