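test_that("encode matches direct evaluation of the activation rule", {
  sig <- function(a) 1 / (1 + exp(-a))
  l0 <- ae_layer(matrix(0, 3, 4), rep(0, 3), rep(0, 4), "sigmoid")
  expect_equal(encode(l0, runif(4)), rep(0.5, 3))

  lid <- ae_layer(diag(4), rep(0, 4), rep(0, 4), "relu")
  x <- c(0.3, 0, 1.2, 0.7)
  expect_equal(encode(lid, x), x)

  lsc <- ae_layer(matrix(2, 1, 1), 1, 0, "sigmoid")
  expect_equal(encode(lsc, -0.5), sig(0))  # 2 * (-0.5) + 1 = 0

  expect_error(encode(l0, runif(5)), class = "invalid_input")
})

test_that("decode uses the tied transpose and matches a matmul oracle", {
  l0 <- ae_layer(matrix(0, 3, 4), rep(0, 3), rep(0, 4), "sigmoid")
  expect_equal(decode(l0, runif(3)), rep(0.5, 4))

  l11 <- ae_layer(matrix(1, 1, 1), 0, 0, "linear")
  x <- 0.42
  expect_equal(decode(l11, encode(l11, x)), x)

  set.seed(9)
  w <- matrix(rnorm(3 * 5), 3, 5)
  b1 <- rnorm(3); b2 <- rnorm(5)
  l <- ae_layer(w, b1, b2, "sigmoid")
  y <- runif(3)
  oracle <- numeric(5)
  for (j in 1:5) {
    acc <- b2[j]
    for (i in 1:3) acc <- acc + w[i, j] * y[i]
    oracle[j] <- 1 / (1 + exp(-acc))
  }
  expect_equal(decode(l, y), oracle, tolerance = 1e-12)

  # tied-weight contract: one weight matrix, parameter count hidden*input +
  # hidden + input (no separate decoder matrix anywhere in the layer)
  expect_equal(length(l$w) + length(l$b1) + length(l$b2), 3 * 5 + 3 + 5)
  expect_named(l[lengths(l) > 0], c("w", "b1", "b2", "activation"))
  expect_error(decode(l, runif(4)), class = "invalid_input")
})

test_that("reconstruction loss is the mean half squared error", {
  x <- matrix(runif(12), 3, 4)
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(c(0, 0), c(1, 1)), 1)  # m=1, ||z-x||^2 = 2
  z <- x + 0.1
  expect_equal(reconstruction_loss(rbind(x, x), rbind(z, z)),
               reconstruction_loss(x, z))
  set.seed(2)
  zr <- matrix(runif(12), 3, 4)
  expect_equal(reconstruction_loss(x, zr), sum((zr - x)^2) / 6,
               tolerance = 1e-14)
  expect_error(reconstruction_loss(matrix(0, 0, 2), matrix(0, 0, 2)),
               class = "invalid_input")
  expect_error(reconstruction_loss(x, matrix(0, 2, 2)),
               class = "invalid_input")
})

test_that("pretraining descends deterministically", {
  set.seed(7)
  x <- matrix(runif(80 * 12), 80, 12)
  cfg <- fast_train(epochs = 40, seed = 5)
  l1 <- pretrain_layer(x, 5, cfg)
  l2 <- pretrain_layer(x, 5, cfg)
  expect_identical(l1$w, l2$w)
  expect_identical(l1$b1, l2$b1)

  j <- attr(l1, "training_log")
  expect_length(j, 41)
  expect_lte(j[length(j)], j[1])
  expect_lte(max(diff(j)), 1e-6)  # non-increasing up to tolerance

  xx <- x; xx[1, 1] <- NA
  expect_error(pretrain_layer(xx, 5, cfg), class = "invalid_input")
  expect_error(pretrain_layer(x, 0, cfg), class = "invalid_parameter")
})

test_that("a matching-width linear autoencoder recovers a linear manifold", {
  # 200 samples on a 3-dim linear manifold in 20-dim space; oracle: the
  # manifold is exactly representable, so the principal-subspace projection
  # error is ~0 and the final loss must fall below 1% of the initial loss
  set.seed(1)
  basis <- matrix(rnorm(20 * 3), 20, 3)
  z <- matrix(runif(200 * 3), 200, 3)
  x <- z %*% t(basis)
  x <- x / max(abs(x)) * 0.5 + 0.5
  l <- pretrain_layer(x, 3, train_config(epochs = 300, learning_rate = 0.05,
                                         batch_size = 16, seed = 2),
                      activation = "linear")
  j <- attr(l, "training_log")
  expect_lt(j[length(j)] / j[1], 0.01)
})

test_that("stacked fits chain layer dims and expose the last hidden width", {
  set.seed(3)
  x <- matrix(runif(40 * 30), 40, 30)
  m <- fit_sae(x, "30-20-10-5", cfg = fast_train(epochs = 5))
  expect_length(m$layers, 3)
  expect_equal(vapply(m$layers, function(l) nrow(l$w), 0L), c(20L, 10L, 5L))
  expect_equal(vapply(m$layers, function(l) ncol(l$w), 0L), c(30L, 20L, 10L))
  f <- deep_features(m, x)
  expect_identical(dim(f), c(40L, 5L))

  # single sample equals manual encoder chaining
  x1 <- x[7, ]
  h <- x1
  for (l in m$layers) h <- encode(l, h)
  expect_equal(as.vector(deep_features(m, x1)), h, tolerance = 1e-14)

  # identical inputs give identical rows, independent of order
  xx <- rbind(x[1, ], x[2, ], x[1, ])
  ff <- deep_features(m, xx)
  expect_identical(ff[1, ], ff[3, ])

  expect_error(fit_sae(x, "29-10-5"), class = "invalid_parameter")
  expect_error(deep_features(m, matrix(0, 2, 31)), class = "invalid_input")
})

test_that("every structure in the default sweep yields its stated feature width", {
  for (kind in names(default_structures())) {
    for (s in default_structures()[[kind]]) {
      dims <- as.integer(strsplit(s, "-")[[1]])
      set.seed(1)
      x <- matrix(runif(8 * dims[1]), 8, dims[1])
      m <- fit_sae(x, s, cfg = fast_train(epochs = 1, batch_size = 8))
      expect_identical(ncol(deep_features(m, x)), dims[length(dims)])
    }
  }
})

test_that("supervised fine-tuning lowers a convex head loss monotonically", {
  # targets an exact linear function of a 2-dim latent encoding
  set.seed(4)
  z <- matrix(runif(60 * 2), 60, 2)
  x <- cbind(z, z %*% matrix(runif(2 * 6), 2, 6))
  x <- x / max(x)
  targets <- 2 + 3 * z[, 1] - 1.5 * z[, 2]
  # frozen encoder: the head loss is convex, so full-batch descent must be
  # monotone and end below the intercept-only (mean predictor) loss
  mh2 <- fit_sae(x, c(8, 4, 2), targets = targets,
                 cfg = train_config(epochs = 30, finetune_epochs = 60,
                                    batch_size = 60, learning_rate = 0.3,
                                    seed = 6),
                 finetune_scope = "head")
  j <- mh2$training_log$finetune
  expect_length(j, 60)
  expect_lte(max(diff(j)), 1e-6)
  ts <- (targets - mean(targets)) / sd(targets)
  expect_lt(j[length(j)], sum(ts^2) / (2 * length(ts)))

  m <- fit_sae(x, c(8, 4, 2), targets = targets,
               cfg = fast_train(epochs = 30, finetune_epochs = 50, seed = 6))
  preds <- predict(m, x)
  expect_lt(rmse(targets, preds), sd(targets))  # beats the mean predictor

  mh <- fit_sae(x, c(8, 4, 2), cfg = fast_train(epochs = 2))
  expect_error(predict(mh, x), class = "incompatible_model")
})

test_that("models serialize and reload intact", {
  set.seed(8)
  x <- matrix(runif(20 * 10), 20, 10)
  m <- fit_sae(x, c(10, 4), targets = runif(20, 6, 14),
               cfg = fast_train(epochs = 3, finetune_epochs = 3))
  p <- tempfile(fileext = ".rds")
  save_sae(m, p)
  m2 <- load_sae(p)
  expect_equal(deep_features(m2, x), deep_features(m, x))
  expect_equal(predict(m2, x), predict(m, x))
})
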