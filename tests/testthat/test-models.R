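# direct (loop) convolution in double precision; independent of the compiled
# im2col + gemm path it checks
conv_reference <- function(x, Wm, b, k, pad) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Ho <- H + 2 * pad - k + 1
  Wo <- W + 2 * pad - k + 1
  F <- ncol(Wm)
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, C, N))
  xp[pad + 1:H, pad + 1:W, , ] <- x
  y <- array(0, c(Ho, Wo, F, N))
  for (n in 1:N) for (f in 1:F) for (wo in 1:Wo) for (ho in 1:Ho) {
    acc <- b[f]
    for (c in 1:C) for (dw in 1:k) for (dh in 1:k) {
      r <- dh + k * ((dw - 1) + k * (c - 1))
      acc <- acc + xp[ho + dh - 1, wo + dw - 1, c, n] * Wm[r, f]
    }
    y[ho, wo, f, n] <- acc
  }
  y
}

test_that("compiled convolution matches a direct-loop reference", {
  set.seed(10)
  x <- array(rnorm(9 * 8 * 2 * 3), c(9, 8, 2, 3))
  p <- podquant:::nn_init_conv(2, 4, 3)
  for (pad in 0:1) {
    y <- podquant:::conv_f(x, p, pad)$y
    yr <- conv_reference(x, p$W, p$b, 3, pad)
    expect_equal(dim(y), dim(yr))
    expect_lt(max(abs(y - yr)), 1e-4)
  }
})

test_that("convolution gradients match finite differences of the reference", {
  set.seed(11)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  p <- podquant:::nn_init_conv(2, 3, 3)
  fw <- podquant:::conv_f(x, p, 1)
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  bk <- podquant:::conv_b(p, fw$cache, dy)
  eps <- 1e-5
  gW <- p$W
  for (i in seq_along(p$W)) {
    W2 <- p$W; W2[i] <- W2[i] + eps
    fp <- sum(conv_reference(x, W2, p$b, 3, 1) * dy)
    W2[i] <- p$W[i] - eps
    fm <- sum(conv_reference(x, W2, p$b, 3, 1) * dy)
    gW[i] <- (fp - fm) / (2 * eps)
  }
  expect_lt(max(abs(gW - bk$grads$W)), 1e-3)
  gX <- array(0, dim(x))
  for (i in seq_along(x)) {
    x2 <- x; x2[i] <- x2[i] + eps
    fp <- sum(conv_reference(x2, p$W, p$b, 3, 1) * dy)
    x2[i] <- x[i] - eps
    fm <- sum(conv_reference(x2, p$W, p$b, 3, 1) * dy)
    gX[i] <- (fp - fm) / (2 * eps)
  }
  expect_lt(max(abs(gX - bk$dx)), 1e-3)
})

test_that("batch-norm gradients match finite differences", {
  set.seed(12)
  x <- array(rnorm(4 * 4 * 3 * 5), c(4, 4, 3, 5))
  p <- podquant:::nn_init_bn(3)
  p$gamma <- runif(3, 0.5, 1.5); p$beta <- rnorm(3)
  fw <- podquant:::bn_f(x, p, training = TRUE)
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  bk <- podquant:::bn_b(p, fw$cache, dy)
  eps <- 1e-6
  num <- array(0, dim(x))
  for (i in seq_along(x)) {
    x2 <- x; x2[i] <- x2[i] + eps
    fp <- sum(podquant:::bn_f(x2, p, TRUE)$y * dy)
    x2[i] <- x[i] - eps
    fm <- sum(podquant:::bn_f(x2, p, TRUE)$y * dy)
    num[i] <- (fp - fm) / (2 * eps)
  }
  expect_lt(max(abs(num - bk$dx)), 1e-6)
})

test_that("softmax probabilities are normalised and shape-checked", {
  m <- build_model(densenet_config(layers_per_block = 1, growth = 4,
                                   init_channels = 6), seed = 2)
  x <- array(rnorm(32 * 32 * 3 * 7), c(32, 32, 3, 7))
  pr <- predict_proba(m, x)
  expect_equal(dim(pr), c(7, 4))
  expect_lt(max(abs(rowSums(pr) - 1)), 1e-6)
  expect_true(all(max.col(pr) %in% 1:4))
  expect_error(predict_proba(m, array(0, c(16, 16, 3, 2))), "32x32")
})

test_that("dense blocks run at 32, 16 and 8 pixels with the stated channels", {
  cfg <- densenet_config(layers_per_block = 2)
  m <- build_model(cfg, seed = 1)
  fw <- podquant:::model_forward(m, array(rnorm(32 * 32 * 3 * 2),
                                          c(32, 32, 3, 2)))
  expect_equal(fw$shapes, c(32, 16, 8))
  # channels entering block b: 16 + (b-1) * layers_per_block * 12
  for (b in 1:3) {
    w <- m$params[[sprintf("b%d.l1.conv", b)]]$W
    expect_equal(nrow(w) / 9, 16 + (b - 1) * 2 * 12)
  }
  # transitions preserve channel count through their 1x1 convolution
  for (b in 1:2) {
    w <- m$params[[sprintf("t%d.conv", b)]]$W
    expect_equal(nrow(w), ncol(w))
  }
})

test_that("the learning rate steps down by gamma at each third", {
  cfg30 <- train_config("densenet", epochs = 30)
  expect_equal(lr_schedule(0, cfg30), 0.001)
  expect_equal(lr_schedule(10, cfg30), 0.0001)
  expect_equal(lr_schedule(20, cfg30), 0.00001)
  expect_equal(lr_schedule(29, cfg30), 0.00001)
  cfg15 <- train_config("lenet", epochs = 15)
  expect_equal(lr_schedule(4, cfg15), 0.001)
  expect_equal(lr_schedule(5, cfg15), 0.0001)
  expect_equal(lr_schedule(14, cfg15), 0.001 * 0.01)
  expect_error(lr_schedule(15, cfg15))
  expect_error(lr_schedule(-1, cfg15))
})

test_that("one epoch of training reduces the loss on a small set", {
  set.seed(3)
  x <- array(rnorm(32 * 32 * 3 * 16), c(32, 32, 3, 16))
  y <- rep(0:3, each = 4)
  m <- build_model(lenet_config(conv1_filters = 6, conv2_filters = 8,
                                fc_units = 32), seed = 5)
  init_loss <- podquant:::softmax_xent(
    podquant:::model_forward(m, x, training = FALSE)$logits, y)$loss
  fit <- train_classifier(m, list(x = x, y = y), list(x = x, y = y),
                          train_config("lenet", base_lr = 0.002, epochs = 4,
                                       batch_size = 8, seed = 5))
  expect_lt(tail(fit$history$train_loss, 1), init_loss)
  expect_equal(nrow(fit$history), 4)
  expect_true(all(c("epoch", "lr", "train_loss", "val_loss", "val_accuracy")
                  %in% names(fit$history)))
})

test_that("training is reproducible for a fixed seed", {
  set.seed(4)
  x <- array(rnorm(32 * 32 * 3 * 24), c(32, 32, 3, 24))
  y <- rep(0:3, 6)
  run <- function() train_classifier(
    build_model(densenet_config(layers_per_block = 1, growth = 4,
                                init_channels = 6), seed = 2),
    list(x = x, y = y), list(x = x, y = y),
    train_config("densenet", epochs = 2, seed = 7))
  expect_identical(run()$history, run()$history)
})

test_that("inference is deterministic and permutation-equivariant", {
  m <- build_model(lenet_config(conv1_filters = 6, conv2_filters = 8,
                                fc_units = 32), seed = 6)
  x <- array(rnorm(32 * 32 * 3 * 5), c(32, 32, 3, 5))
  xdup <- x
  xdup[, , , 2] <- x[, , , 1]
  pr <- predict_proba(m, xdup)
  expect_equal(pr[1, ], pr[2, ])
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(predict_proba(m, x[, , , perm]), predict_proba(m, x)[perm, ],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("empty splits and broken initialisation files error", {
  m <- build_model(lenet_config(), seed = 1)
  empty <- list(x = array(0, c(32, 32, 3, 0)), y = integer(0))
  data <- list(x = array(0, c(32, 32, 3, 2)), y = c(0L, 1L))
  expect_error(train_classifier(m, empty, data, train_config("lenet")))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(foo = 1), bad)
  expect_error(build_model(lenet_config(), init_file = bad), "match")
})

test_that("models survive a save/load round trip", {
  m <- build_model(densenet_config(layers_per_block = 1, growth = 4,
                                   init_channels = 6), seed = 8)
  x <- array(rnorm(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict_proba(m2, x), predict_proba(m, x))
})
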