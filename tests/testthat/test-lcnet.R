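
test_that("conv_out_len matches placement enumeration", {
  expect_identical(conv_out_len(30, 3, 2, 1), 15L)
  expect_identical(conv_out_len(15, 3, 2, 1), 8L)
  expect_identical(conv_out_len(8, 3, 2, 1), 4L)
  # same-padding identity for odd kernels
  for (k in c(1, 3, 5, 7))
    expect_identical(conv_out_len(29, k, 1, (k - 1) / 2), 29L)
  withr::with_seed(37, {
    for (rep in 1:40) {
      L <- sample(1:120, 1); k <- sample(1:5, 1)
      s <- sample(1:3, 1); p <- sample(0:2, 1)
      if (L + 2 * p < k) next
      expect_identical(conv_out_len(L, k, s, p),
                       as.integer(conv_len_oracle(L, k, s, p)))
    }
  })
  expect_error(conv_out_len(2, 5, 1, 0), "output length")
})

test_that("channel shuffle is the reshape-transpose permutation", {
  x <- array(0, c(4, 2, 2, 1))
  for (c in 1:4) x[c, , , ] <- c
  y <- channel_shuffle(x, groups = 2)
  expect_identical(as.numeric(y[, 1, 1, 1]), c(1, 3, 2, 4))

  # shuffling with the swapped group shape inverts the permutation
  withr::with_seed(41, xr <- array(rnorm(16 * 5 * 5 * 2), c(16, 5, 5, 2)))
  expect_equal(channel_shuffle(channel_shuffle(xr, 2), 8), xr)
  # per-channel value sets preserved
  expect_identical(sort(as.vector(channel_shuffle(xr, 4))),
                   sort(as.vector(xr)))
  expect_error(channel_shuffle(xr, 3), "divisible")
})

test_that("the hybrid network walks through the documented shapes", {
  for (nb in c(30L, 15L)) {
    m <- build_model(arch_config("hybrid_lcnet", n_bands = nb), seed = 1)
    aud <- shape_audit(m)
    # stem: spectral 30 -> 15 -> 8 (or 15 -> 8 -> 4), pooled to 2, then
    # merged into 64 channels at 28 x 28
    expect_identical(aud$out_shape[aud$type == "stem3d"], "64x28x28")
    # units: 128 @ 14 x 14 and 256 @ 7 x 7
    expect_identical(aud$out_shape[aud$type == "unit_down"],
                     c("128x14x14", "256x7x7"))
    expect_identical(aud$out_shape[aud$type == "unit_basic"],
                     c("128x14x14", "256x7x7"))
    # actual forward pass shapes agree with the symbolic walk
    x <- array(runif(nb * 112 * 112), c(1, nb, 112, 112, 1))
    st <- m$net$layers[[1]]
    y <- hyperleaf:::nn_forward(st, x, training = FALSE)
    expect_identical(dim(y)[1:3], c(64L, 28L, 28L))
    full <- hyperleaf:::nn_forward(m$net, x, training = FALSE)
    expect_identical(dim(full), c(1L, 6L))
  }
  # spectral depths before pooling, from the arithmetic itself
  expect_identical(conv_out_len(conv_out_len(30, 3, 2, 1), 3, 2, 1), 8L)
  expect_identical(conv_out_len(conv_out_len(15, 3, 2, 1), 3, 2, 1), 4L)
  expect_error(build_model(arch_config("hybrid_lcnet", n_bands = 7)),
               "N >= 8")
})

test_that("parameter counts equal the analytic layer-sum for all five", {
  for (a in c("hybrid_lcnet", "lcnet3d", "lcnet2d", "shufflenetv2_2d",
              "shufflenetv2_3d")) {
    m <- build_model(arch_config(a, n_bands = 30), seed = 1)
    eff <- count_parameters(m)  # errors internally on any mismatch
    expect_identical(eff$params, eff$params_analytic)
    aud <- shape_audit(m)
    expect_identical(sum(aud$params), eff$params)
  }
  # hand-checkable pieces: a bias-free 3x3x3 conv 1 -> 16 and a BN over 64
  expect_identical(hyperleaf:::nn_analytic_params(
    hyperleaf:::layer_conv3d(1, 16)), 432)
  expect_identical(hyperleaf:::nn_analytic_params(
    hyperleaf:::layer_bn(64)), 128)
})

test_that("FLOP accounting follows the 2 x MAC convention", {
  # 1x1 conv 256 -> 512 on a 7x7 map
  l <- hyperleaf:::layer_conv2d(256, 512, k = 1, stride = 1, pad = 0)
  r <- hyperleaf:::nn_shape(l, c(256, 7, 7))
  expect_identical(2 * r$macs, 2 * 256 * 512 * 49)
  # doubling the spatial area doubles conv FLOPs, parameters unchanged
  r2 <- hyperleaf:::nn_shape(l, c(256, 7, 14))
  expect_identical(r2$macs, 2 * r$macs)
  expect_identical(hyperleaf:::nn_analytic_params(l), 256 * 512)
  # hybrid strictly cheaper than the all-3d variant on the same input
  fh <- count_flops(build_model(arch_config("hybrid_lcnet", n_bands = 30)))
  f3 <- count_flops(build_model(arch_config("lcnet3d", n_bands = 30)))
  expect_lt(fh$flops, f3$flops)
  expect_match(fh$convention, "2 x MAC")
})

test_that("the fused fast path equals the generic layer path", {
  cfg <- arch_config("hybrid_lcnet", n_bands = 15, n_classes = 6,
                     dropout = 0)  # dropout off: deterministic comparison
  mf <- build_model(cfg, seed = 4, fuse = TRUE)
  mg <- build_model(cfg, seed = 4, fuse = FALSE)
  expect_identical(count_parameters(mf)$params,
                   count_parameters(mg)$params)
  withr::with_seed(5, {
    xb <- array(runif(2 * 15 * 112 * 112), c(1, 15, 112, 112, 2))
  })
  yf <- hyperleaf:::nn_forward(mf$net, xb, training = FALSE)
  yg <- hyperleaf:::nn_forward(mg$net, xb, training = FALSE)
  expect_lt(max(abs(yf - yg)), 1e-3)
  # training-mode batch statistics agree too
  yft <- hyperleaf:::nn_forward(mf$net, xb, training = TRUE)
  ygt <- hyperleaf:::nn_forward(mg$net, xb, training = TRUE)
  expect_lt(max(abs(yft - ygt)), 1e-3)
})

test_that("analytic gradients match finite differences through the net", {
  cfg <- arch_config("hybrid_lcnet", n_bands = 8, n_classes = 3)
  m <- build_model(cfg, seed = 2)
  withr::with_seed(6, {
    xb <- array(runif(2 * 8 * 112 * 112), c(1, 8, 112, 112, 2))
  })
  y <- c(1L, 3L)
  h <- hyperleaf:::nn_param_handles(m$net)
  loss_of <- function() {
    set.seed(1)  # freeze dropout
    hyperleaf:::ce_loss_grad(
      hyperleaf:::nn_forward(m$net, xb, training = TRUE), y)
  }
  lg <- loss_of()
  hyperleaf:::nn_backward(m$net, lg$grad)
  withr::with_seed(8, picks <- sample(length(h), 4))
  for (i in picks) {
    l <- h[[i]]$layer; f <- h[[i]]$field
    W <- get(f, envir = l)
    g <- get(paste0("g", f), envir = l)
    k <- withr::with_seed(i, sample(length(W), 1))
    eps <- 1e-3
    W2 <- W; W2[k] <- W2[k] + eps; assign(f, W2, envir = l)
    lp <- loss_of()$loss
    W2[k] <- W2[k] - 2 * eps; assign(f, W2, envir = l)
    lm <- loss_of()$loss
    assign(f, W, envir = l)
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(g[k] - fd), 0.02 * max(1, abs(fd)) + 2e-3)
  }
})

test_that("the learning-rate schedule halves every 20 epochs", {
  cfg <- train_config()
  expect_identical(lr_at_epoch(1, cfg), 0.001)
  expect_identical(lr_at_epoch(20, cfg), 0.001)
  expect_identical(lr_at_epoch(21, cfg), 0.0005)
  expect_identical(lr_at_epoch(41, cfg), 0.00025)
  expect_identical(lr_at_epoch(200, cfg), 0.001 * 0.5^9)
})

test_that("training is seeded, checkpointed, and learns a separable set", {
  set.seed(99)
  data <- cnn_image_set(n_per_class = 6, n_bands = 15, seed = 2)
  tr <- which(seq_along(data$y) %% 3 != 0)
  va <- which(seq_along(data$y) %% 3 == 0)
  tc <- train_config(epochs = 3, batch = 8, seed = 11)

  run <- function() {
    m <- build_model(arch_config("hybrid_lcnet", n_bands = 15), seed = 11)
    train_cnn(m, data$x[tr], data$y[tr], data$x[va], data$y[va], tc)
  }
  f1 <- run(); f2 <- run()
  expect_equal(f1$history, f2$history)                # determinism
  expect_identical(f1$history$lr, rep(0.001, 3))
  expect_identical(nrow(f1$history), 3L)
  expect_lt(f1$history$train_loss[3], f1$history$train_loss[1])
  expect_identical(f1$best_val_acc, max(f1$history$val_acc))
  # the returned checkpoint reproduces its validation accuracy: weights
  # and BN running statistics must be restored together
  preds <- predict(f1$model, data$x[va], batch = 8)
  expect_identical(length(preds), length(va))
  expect_equal(mean(preds == data$y[va]), f1$best_val_acc)
  expect_error(train_cnn(build_model(arch_config("hybrid_lcnet", 15)),
                         list(), integer(0), data$x[va], data$y[va], tc),
               "empty")
})

test_that("repeated splits keep the test fold fixed and report mean ± sd", {
  set.seed(123)
  data <- cnn_scene_set(n_per_class = 8, n_bands = 15, seed = 5)
  test_idx <- which(seq_along(data$y) %% 4 == 0)
  tc <- train_config(epochs = 2, batch = 8, n_repeats = 2)
  res <- repeat_experiment("hybrid_lcnet",
                           list(x = data$x, y = data$y,
                                test_idx = test_idx),
                           train_config = tc, seed = 31)
  expect_identical(dim(res$accuracies), c(2L, 1L))
  expect_match(res$stats$cell, "±")
  expect_true(all(res$accuracies >= 0 & res$accuracies <= 1))
  # with a single repetition the sd is zero
  tc1 <- train_config(epochs = 1, batch = 8, n_repeats = 1)
  res1 <- repeat_experiment("hybrid_lcnet",
                            list(x = data$x, y = data$y,
                                 test_idx = test_idx),
                            train_config = tc1, seed = 32)
  expect_identical(res1$stats$sd, 0)
})
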