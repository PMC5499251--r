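test_that("sigmoid is correct, symmetric and overflow-safe", {
  expect_identical(sigmoid(0), 0.5)
  expect_equal(sigmoid(-3), 1 - sigmoid(3))
  expect_identical(sigmoid(710), 1)
  expect_lt(sigmoid(-710), 1e-300)
  expect_false(any(!is.finite(sigmoid(c(-1e6, 1e6)))))
})

test_that("encode and decode match hand evaluation and batch row-wise", {
  set.seed(1)
  layer <- dae_layer(2, 1)
  layer$W <- matrix(c(1, 1), nrow = 1)
  expect_equal(dae_encode(layer, c(1, 1)), sigmoid(2))

  zero <- dae_layer(3, 2)
  zero$W[] <- 0
  expect_equal(dae_encode(zero, runif(3)), c(0.5, 0.5))
  expect_equal(dae_decode(zero, runif(2)), rep(0.5, 3))

  # batches equal row-wise single calls; round trip restores length
  big <- dae_layer(4, 2)
  X <- matrix(runif(12), 3, 4)
  H <- dae_encode(big, X)
  expect_equal(H[2, ], dae_encode(big, X[2, ]))
  expect_length(dae_decode(big, dae_encode(big, X[1, ])), 4)

  # tied weights: perturbing W changes both directions
  pert <- big
  pert$W <- pert$W + 0.5
  expect_false(identical(dae_encode(big, X[1, ]), dae_encode(pert, X[1, ])))
  h <- dae_encode(big, X[1, ])
  expect_false(identical(dae_decode(big, h), dae_decode(pert, h)))
})

test_that("cross-entropy matches hand values and is permutation invariant", {
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), 2 * log(2))
  expect_lt(cross_entropy(c(1, 0), c(1 - 1e-9, 1e-9)), 1e-8)
  set.seed(2)
  v <- runif(6); vh <- runif(6, 0.1, 0.9)
  p <- sample(6)
  expect_equal(cross_entropy(v, vh), cross_entropy(v[p], vh[p]))
  expect_warning(cross_entropy(c(1, 0), c(1, 0.5)), "clipped")
})

test_that("corruption zeroes the nominal fraction and nothing else", {
  v <- runif(50)
  expect_identical(corrupt(v, 0), v)
  expect_true(all(corrupt(v, 1) == 0))
  set.seed(3)
  x <- corrupt(rep(1, 1e5), 0.5)
  expect_lt(abs(mean(x == 0) - 0.5), 0.01)
  # untouched entries are copies, not rescaled
  set.seed(4)
  y <- corrupt(v, 0.3)
  expect_true(all(y %in% c(0, v)))
})

test_that("the denoising gradient matches central finite differences", {
  set.seed(5)
  layer <- dae_layer(6, 4, P = 0.3)
  batch <- matrix(runif(18), 3, 6)
  corr <- corrupt(batch, layer$P)
  g <- dae_gradient(layer, batch, corrupted = corr)
  eps <- 1e-5
  for (param in c("W", "b", "b_prime")) {
    p <- layer[[param]]
    num <- p
    for (i in seq_along(p)) {
      lp <- layer; lp[[param]][i] <- lp[[param]][i] + eps
      lm <- layer; lm[[param]][i] <- lm[[param]][i] - eps
      num[i] <- (dae_loss(lp, batch, corr) - dae_loss(lm, batch, corr)) /
        (2 * eps)
    }
    expect_rel_error_lt(g[[param]], num, 1e-5)
  }
  # sum convention: duplicating the batch doubles the gradient
  g2 <- dae_gradient(layer, rbind(batch, batch),
                     corrupted = rbind(corr, corr))
  expect_equal(g2$W, 2 * g$W)
  # zero batch with zero weights: reconstruction bias is pushed toward 0
  z <- dae_layer(4, 2); z$W[] <- 0
  zb <- matrix(0, 2, 4)
  expect_true(all(dae_gradient(z, zb, corrupted = zb)$b_prime > 0))
})

test_that("SGD training decreases the objective and is reproducible", {
  set.seed(6)
  data <- matrix(runif(40), 10, 4)
  layer <- dae_layer(4, 2, P = 0.2)
  frozen <- train_dae(layer, data, epochs = 5, lr = 0)$layer
  expect_identical(frozen$W, layer$W)

  # full-batch descent on a fixed corruption mask is monotone
  set.seed(7)
  fit <- train_dae(layer, data, epochs = 20, lr = 0.01, batch_size = 10,
                   resample_corruption = FALSE)
  expect_true(all(diff(fit$loss_history) <= 1e-10))

  run <- function() {
    set.seed(8)
    train_dae(layer, data, epochs = 3, lr = 0.1, batch_size = 4)$loss_history
  }
  expect_identical(run(), run())
})

test_that("greedy pretraining stacks strictly decreasing layers", {
  set.seed(9)
  data <- matrix(runif(600), 30, 20)
  model <- sda_pretrain(data, c(8, 4), epochs = 2)
  expect_s3_class(model, "sda_model")
  expect_equal(vapply(model$layers, function(l) nrow(l$W), integer(1)),
               c(8L, 4L))
  expect_equal(ncol(model$layers[[2]]$W), 8) # dims chain 20 -> 8 -> 4
  expect_error(sda_pretrain(data, c(4, 8)), "strictly decreasing")
  expect_error(sda_pretrain(data, c(20)), "strictly decreasing")
  expect_error(sda_pretrain(data[0, ], c(4)), "empty")

  f <- sda_features(model, data)
  expect_equal(dim(f), c(30, 4))
  expect_true(all(f > 0 & f < 1))
  # one-layer model: features are the first encoder output
  m1 <- sda_pretrain(data, 8, epochs = 1)
  expect_equal(sda_features(m1, data[1, ]),
               dae_encode(m1$layers[[1]], data[1, ]))
})
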