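#' Architecture configuration
#'
#' Pins one of the five network families for `112 x 112 x N` hyperspectral
#' inputs (N spectral bands, typically the 15 or 30 bands kept by SPA or
#' CARS selection):
#'
#' * `hybrid_lcnet` — two 3-d stem convolutions (3x3x3, strides 2,
#'   channels 1 -> 16 -> 32), adaptive average pooling of the spectral
#'   axis to depth 2, reshape to a 64-channel 2-d map at 28x28, then four
#'   ShuffleNetV2 units (down 64->128, basic 128, down 128->256, basic
#'   256), a 1x1 conv to 512, global average pooling, dropout and a linear
#'   classifier.
#' * `lcnet3d` — same stem and pooling, but the four units and the head
#'   stay 3-d (3x3x3 depthwise, 1x1x1 pointwise, spatial-only strides).
#' * `lcnet2d` — bands-as-channels 2-d counterpart: stem 3x3 convs
#'   N -> 16 -> 64 (strides 2), then the same four 2-d units and head.
#' * `shufflenetv2_2d` / `shufflenetv2_3d` — ShuffleNetV2 at width 0.25:
#'   first conv to 24 channels, 3x3 max-pool, stages of (32, 64, 128)
#'   channels with (4, 8, 4) repeats, head conv to 1024.
#'
#' @param arch_id one of `"hybrid_lcnet"`, `"lcnet3d"`, `"lcnet2d"`,
#'   `"shufflenetv2_2d"`, `"shufflenetv2_3d"`.
#' @param n_bands spectral bands N (15 or 30 in the reference protocol;
#'   any `>= 8` is accepted for 3-d stems).
#' @param n_classes number of classes (default 6).
#' @param width_mult width multiplier tag for the ShuffleNetV2 variants
#'   (informational; the pinned channel plan corresponds to 0.25).
#' @param dropout dropout probability before the classifier.
#' @return A list of class `arch_config`.
#' @export
arch_config <- function(arch_id = c("hybrid_lcnet", "lcnet3d", "lcnet2d",
                                    "shufflenetv2_2d", "shufflenetv2_3d"),
                        n_bands = 30L, n_classes = 6L, width_mult = 0.25,
                        dropout = 0.2) {
  arch_id <- match.arg(arch_id)
  n_bands <- as.integer(n_bands)
  assert_that(n_bands >= 1, "n_bands must be positive")
  if (arch_id %in% c("hybrid_lcnet", "lcnet3d", "shufflenetv2_3d"))
    assert_that(n_bands >= 8, "3-d stems need N >= 8 bands (got %d)", n_bands)
  structure(list(arch_id = arch_id, n_bands = n_bands,
                 n_classes = as.integer(n_classes),
                 width_mult = width_mult, dropout = dropout,
                 input_size = 112L),
            class = "arch_config")
}

#' Training protocol configuration
#'
#' The reference protocol: Adam with default moments, initial learning
#' rate 0.001 halved every 20 epochs, cross-entropy loss, batch size 64,
#' 200 epochs, 5 repeats. Desk-scale runs shrink `epochs` and `batch`.
#'
#' @param lr0 initial learning rate.
#' @param lr_decay multiplicative decay factor.
#' @param lr_step epochs between decays.
#' @param epochs total epochs.
#' @param batch minibatch size.
#' @param seed integer seed.
#' @param n_repeats repeated-split count for [repeat_experiment()].
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr0 = 0.001, lr_decay = 0.5, lr_step = 20L,
                         epochs = 200L, batch = 64L, seed = 1L,
                         n_repeats = 5L) {
  assert_that(epochs >= 1 && batch >= 1 && lr0 > 0,
              "epochs, batch and lr0 must be positive")
  structure(list(lr0 = lr0, lr_decay = lr_decay, lr_step = as.integer(lr_step),
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 seed = as.integer(seed), n_repeats = as.integer(n_repeats)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Step decay: `lr0 * lr_decay^floor((epoch - 1) / lr_step)`; with the
#' defaults the rate is 0.001 for epochs 1-20, 0.0005 for 21-40, 0.00025
#' for 41-60, and so on.
#'
#' @param epoch 1-based epoch number.
#' @param config a [train_config()].
#' @return The learning rate.
#' @export
lr_at_epoch <- function(epoch, config = train_config()) {
  config$lr0 * config$lr_decay^((epoch - 1) %/% config$lr_step)
}

# The four modified ShuffleNetV2 units + head shared by the LcNet family.
lcnet_tail <- function(cin, dim3, n_classes, dropout, fuse = !dim3) {
  units <- list(unit_down(cin, 128L, dim3, fuse), unit_basic(128L, dim3, fuse),
                unit_down(128L, 256L, dim3, fuse), unit_basic(256L, dim3, fuse))
  head_conv <- if (fuse) list(layer_pwbr(256L, 512L))
  else list(pw_conv(256L, 512L, dim3), layer_bn(512L), layer_relu())
  c(units, head_conv,
    list(layer_global_pool(), layer_dropout(dropout),
         layer_linear(512L, n_classes)))
}

shufflenet_stages <- function(dim3, n_classes, dropout) {
  stage <- function(cin, cout, repeats) {
    c(list(unit_down(cin, cout, dim3)),
      lapply(seq_len(repeats - 1L), function(i) unit_basic(cout, dim3)))
  }
  c(stage(24L, 32L, 4L), stage(32L, 64L, 8L), stage(64L, 128L, 4L),
    list(pw_conv(128L, 1024L, dim3), layer_bn(1024L), layer_relu(),
         layer_global_pool(), layer_dropout(dropout),
         layer_linear(1024L, n_classes)))
}

#' Build a network from its architecture configuration
#'
#' Constructs the pinned architecture with seeded Kaiming initialisation
#' (unit/zero batch-norm, bias-free convolutions; the final linear layer
#' carries the only bias). The returned model exposes an ordered layer
#' list for auditing.
#'
#' @param config an [arch_config()].
#' @param seed initialisation seed.
#' @param fuse use the fused single-precision fast-path kernels (stem
#'   block, pointwise/depthwise + BN blocks) where available; disable to
#'   audit the same network through the generic one-layer-at-a-time path.
#'   Both paths share weights for a given seed and agree to float
#'   precision.
#' @return Object of class `lcnet_model` with elements `net` (the layer
#'   graph), `config`, `seed` and `input_shape` (`c(C, [D,] H, W)`).
#' @export
build_model <- function(config, seed = 1L, fuse = TRUE) {
  assert_that(inherits(config, "arch_config"), "`config` must be an arch_config")
  nb <- config$n_bands
  nc <- config$n_classes
  sz <- config$input_size
  hybrid_stem <- if (fuse) {
    function() list(layer_stem3d(16L, 32L, 2L))
  } else {
    function() list(layer_conv3d(1L, 16L, 3L, c(2L, 2L, 2L), 1L),
                    layer_bn(16L), layer_relu(),
                    layer_conv3d(16L, 32L, 3L, c(2L, 2L, 2L), 1L),
                    layer_bn(32L), layer_relu(),
                    layer_pool_spectral(2L), layer_merge_depth())
  }
  net <- with_seed(seed, switch(
    config$arch_id,
    hybrid_lcnet = layer_sequential(c(
      hybrid_stem(),
      lcnet_tail(64L, dim3 = FALSE, nc, config$dropout, fuse))),
    lcnet3d = layer_sequential(c(
      list(layer_conv3d(1L, 16L, 3L, c(2L, 2L, 2L), 1L), layer_bn(16L),
           layer_relu(),
           layer_conv3d(16L, 32L, 3L, c(2L, 2L, 2L), 1L), layer_bn(32L),
           layer_relu(),
           layer_pool_spectral(2L)),
      lcnet_tail(32L, dim3 = TRUE, nc, config$dropout))),
    lcnet2d = layer_sequential(c(
      list(layer_conv2d(nb, 16L, 3L, 2L, 1L), layer_bn(16L), layer_relu(),
           layer_conv2d(16L, 64L, 3L, 2L, 1L), layer_bn(64L), layer_relu()),
      lcnet_tail(64L, dim3 = FALSE, nc, config$dropout, fuse))),
    shufflenetv2_2d = layer_sequential(c(
      list(layer_conv2d(nb, 24L, 3L, 2L, 1L), layer_bn(24L), layer_relu(),
           layer_maxpool2d(3L, 2L, 1L)),
      shufflenet_stages(dim3 = FALSE, nc, config$dropout))),
    shufflenetv2_3d = layer_sequential(c(
      list(layer_conv3d(1L, 24L, 3L, c(2L, 2L, 2L), 1L), layer_bn(24L),
           layer_relu(),
           layer_maxpool3d(3L, c(2L, 2L, 2L), 1L)),
      shufflenet_stages(dim3 = TRUE, nc, config$dropout)))))
  net$layers[[1]]$is_first <- TRUE  # its input gradient is never needed
  input_shape <- if (config$arch_id %in% c("hybrid_lcnet", "lcnet3d",
                                           "shufflenetv2_3d"))
    c(1L, nb, sz, sz) else c(nb, sz, sz)
  structure(list(net = net, config = config, seed = seed,
                 input_shape = input_shape),
            class = "lcnet_model")
}

#' @export
print.lcnet_model <- function(x, ...) {
  eff <- count_parameters(x)
  cat(sprintf("<lcnet_model> %s, N = %d bands: %s parameters (%.2f M)\n",
              x$config$arch_id, x$config$n_bands,
              format(eff$params, big.mark = ","), eff$params_m))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sums the trainable scalars held by the model's layers and cross-checks
#' the total against an independent analytic per-layer formula (convs:
#' kernel volume x C_in x C_out, divided by C for depthwise; batch norm:
#' 2C; linear: C_in x C_out + C_out). A mismatch raises an error.
#'
#' @param model a [build_model()] result.
#' @return List with `params` (count), `params_m` (millions, 2 d.p.) and
#'   `params_analytic`.
#' @export
count_parameters <- function(model) {
  actual <- nn_count_params(model$net)
  analytic <- nn_analytic_count(model$net)
  assert_that(actual == analytic,
              "framework parameter count (%d) != analytic layer-sum (%d)",
              actual, analytic)
  list(params = actual, params_m = round(actual / 1e6, 2),
       params_analytic = analytic)
}

#' Count FLOPs for one input
#'
#' Walks the layer graph symbolically with [conv_out_len()] and sums
#' 2 x multiply-accumulates over convolution and linear layers (batch
#' norm and activations excluded). The convention is recorded in the
#' report.
#'
#' @param model a [build_model()] result.
#' @param input_shape optional `c(C, [D,] H, W)` override.
#' @return List with `flops`, `flops_g` (giga), `macs` and `convention`.
#' @export
count_flops <- function(model, input_shape = model$input_shape) {
  r <- nn_shape(model$net, input_shape)
  list(flops = 2 * r$macs, flops_g = 2 * r$macs / 1e9, macs = r$macs,
       convention = "2 x MAC, conv + linear layers only")
}

#' Symbolic shape audit
#'
#' Walks the model layer by layer with the convolution output-length
#' arithmetic and reports each top-level layer's output shape, analytic
#' parameter count and MACs.
#'
#' @param model a [build_model()] result.
#' @param input_shape optional shape override (`c(C, [D,] H, W)`).
#' @return Tibble with columns `layer`, `type`, `out_shape`, `params`,
#'   `macs`.
#' @export
shape_audit <- function(model, input_shape = model$input_shape) {
  shape <- input_shape
  rows <- list()
  for (i in seq_along(model$net$layers)) {
    l <- model$net$layers[[i]]
    r <- nn_shape(l, shape)
    shape <- r$shape
    rows[[i]] <- tibble::tibble(
      layer = i, type = l$type,
      out_shape = paste(r$shape, collapse = "x"),
      params = nn_analytic_count(l), macs = r$macs)
  }
  dplyr::bind_rows(rows)
}

# ------------------------------------------------------------- training --

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy loss and gradient for logits (n x K) and labels 1..K.
ce_loss_grad <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / n)
}

adam_step <- function(handles, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (h in handles) {
    l <- h$layer; f <- h$field
    g <- get(paste0("g", f), envir = l)
    mkey <- paste0("adam_m_", f); vkey <- paste0("adam_v_", f)
    tkey <- paste0("adam_t_", f)
    if (!exists(mkey, envir = l)) {
      assign(mkey, g * 0, envir = l)
      assign(vkey, g * 0, envir = l)
      assign(tkey, 0L, envir = l)
    }
    m <- beta1 * get(mkey, envir = l) + (1 - beta1) * g
    v <- beta2 * get(vkey, envir = l) + (1 - beta2) * g * g
    t <- get(tkey, envir = l) + 1L
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    w <- get(f, envir = l) - lr * mhat / (sqrt(vhat) + eps)
    assign(f, w, envir = l)
    assign(mkey, m, envir = l)
    assign(vkey, v, envir = l)
    assign(tkey, t, envir = l)
  }
}

# Stack a list of per-sample input arrays into one batch tensor (last axis
# = batch) on the model's input layout; reflectance clipped to [0, 2].
stack_inputs <- function(xs, input_shape) {
  n <- length(xs)
  out <- array(0, c(input_shape, n))
  m <- prod(input_shape)
  for (i in seq_len(n)) {
    v <- as.vector(xs[[i]])
    assert_that(length(v) == m, "input %d has wrong size", i)
    out[(m * (i - 1) + 1):(m * i)] <- v
  }
  out[out < 0] <- 0
  out[out > 2] <- 2
  out
}

#' Convert a leaf sample to a CNN input array
#'
#' Re-layouts an `H x W x B` cube to the model's channel-first input:
#' `(1, B, H, W)` for the 3-d stems, `(B, H, W)` for bands-as-channels
#' 2-d networks.
#'
#' @param sample a [leaf_sample()] (already padded to the input size).
#' @param dim3 logical: 3-d stem layout?
#' @return Numeric array.
#' @export
as_cnn_input <- function(sample, dim3 = TRUE) {
  arr <- aperm(sample$cube$data, c(3, 1, 2))  # (B, H, W)
  if (dim3) dim(arr) <- c(1L, dim(arr))
  arr
}

model_predict_scores <- function(model, xs, batch = 64L) {
  n <- length(xs)
  out <- NULL
  for (s in seq(1, n, by = batch)) {
    e <- min(n, s + batch - 1L)
    xb <- stack_inputs(xs[s:e], model$input_shape)
    sc <- nn_forward(model$net, xb, training = FALSE)
    out <- rbind(out, sc)
  }
  out
}

#' Train a network
#'
#' Minibatch Adam with the step-decay schedule of [train_config()],
#' cross-entropy loss, per-epoch train/validation tracking and
#' best-validation-accuracy checkpointing. Fully seeded: equal seeds give
#' identical histories.
#'
#' @param model a [build_model()] result (modified in place; the returned
#'   object carries the best checkpoint's parameters).
#' @param train_x,train_y list of input arrays (see [as_cnn_input()]) and
#'   integer labels.
#' @param val_x,val_y validation inputs and labels.
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return List with `model` (best checkpoint restored), `history`
#'   (tibble: epoch, lr, train_loss, train_acc, val_acc), `best_epoch`,
#'   `best_val_acc`.
#' @export
train_cnn <- function(model, train_x, train_y, val_x, val_y,
                      config = train_config(), verbose = FALSE) {
  assert_that(length(train_x) > 0, "empty training set")
  assert_that(length(train_x) == length(train_y),
              "inputs and labels must align")
  handles <- nn_param_handles(model$net)
  ckpt_handles <- nn_checkpoint_handles(model$net)
  n <- length(train_x)
  best <- list(acc = -Inf, epoch = 0L, state = NULL)
  hist <- vector("list", config$epochs)
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_at_epoch(epoch, config)
      ord <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0
      for (s in seq(1, n, by = config$batch)) {
        idx <- ord[s:min(n, s + config$batch - 1L)]
        xb <- stack_inputs(train_x[idx], model$input_shape)
        yb <- train_y[idx]
        logits <- nn_forward(model$net, xb, training = TRUE)
        lg <- ce_loss_grad(logits, yb)
        nn_backward(model$net, lg$grad)
        adam_step(handles, lr)
        tot_loss <- tot_loss + lg$loss * length(idx)
        tot_correct <- tot_correct +
          sum(max.col(logits, ties.method = "first") == yb)
      }
      val_scores <- model_predict_scores(model, val_x, config$batch)
      val_acc <- mean(max.col(val_scores, ties.method = "first") == val_y)
      if (val_acc > best$acc) {
        # checkpoint both the weights and the BN running statistics:
        # restoring weights alone would pair them with later-epoch
        # normalisation statistics and wreck inference
        best <- list(acc = val_acc, epoch = epoch,
                     state = lapply(ckpt_handles, function(h)
                       get(h$field, envir = h$layer)))
      }
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr, train_loss = tot_loss / n,
        train_acc = tot_correct / n, val_acc = val_acc)
      if (verbose)
        message(sprintf("epoch %3d lr %.5f loss %.4f train %.3f val %.3f",
                        epoch, lr, tot_loss / n, tot_correct / n, val_acc))
    }
  })
  # restore the best checkpoint (weights + running statistics)
  for (i in seq_along(ckpt_handles))
    assign(ckpt_handles[[i]]$field, best$state[[i]],
           envir = ckpt_handles[[i]]$layer)
  list(model = model, history = dplyr::bind_rows(hist),
       best_epoch = best$epoch, best_val_acc = best$acc)
}

#' Predict classes with a trained network
#'
#' @param object a `lcnet_model`.
#' @param newdata list of input arrays.
#' @param type `"class"` or `"score"` (softmax probabilities).
#' @param batch forward-pass batch size.
#' @param ... unused.
#' @return Integer labels or an `n x K` probability matrix.
#' @export
predict.lcnet_model <- function(object, newdata, type = c("class", "score"),
                                batch = 64L, ...) {
  type <- match.arg(type)
  sc <- model_predict_scores(object, newdata, batch)
  if (type == "score") return(softmax_rows(sc))
  max.col(sc, ties.method = "first")
}

#' Repeated-split experiment over architectures
#'
#' Keeps the held-out test fold fixed and, per repetition, re-splits the
#' remaining 80% pool into stratified 60/20 train/validation shares,
#' trains each architecture, and evaluates on the fixed test fold. Groups
#' of per-repeat accuracies are compared with [dunn_bonferroni()].
#'
#' @param arch_ids character vector of architecture ids.
#' @param data list with `x` (list of input-ready cubes as `H x W x B`
#'   [leaf_sample()]s or raw arrays), `y` labels, and `test_idx` (indices
#'   of the fixed test fold).
#' @param train_config a [train_config()] (its `n_repeats` is used).
#' @param seed integer seed.
#' @return List with `stats` (tibble: arch, metric, mean, sd, cell
#'   `mean +/- sd`), `accuracies` (per-repeat), `dunn` (test results; NULL
#'   if a single architecture).
#' @export
repeat_experiment <- function(arch_ids, data, train_config = train_config(),
                              seed = 1L) {
  test_idx <- data$test_idx
  pool_idx <- setdiff(seq_along(data$y), test_idx)
  y_pool <- data$y[pool_idx]
  n_rep <- train_config$n_repeats
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2, n_rep))
  acc <- matrix(NA_real_, n_rep, length(arch_ids),
                dimnames = list(NULL, arch_ids))
  for (r in seq_len(n_rep)) {
    # stratified 60/20 re-split of the 80% pool (3:1 within the pool)
    tr <- va <- integer(0)
    with_seed(rep_seeds[r], {
      for (cl in unique(y_pool)) {
        idx <- sample(pool_idx[y_pool == cl])
        n_tr <- round(length(idx) * 0.75)
        tr <- c(tr, idx[seq_len(n_tr)])
        va <- c(va, idx[(n_tr + 1L):length(idx)])
      }
    })
    for (a in seq_along(arch_ids)) {
      dim3 <- arch_ids[a] %in% c("hybrid_lcnet", "lcnet3d", "shufflenetv2_3d")
      to_input <- function(i) {
        xi <- data$x[[i]]
        if (inherits(xi, "leaf_sample")) return(as_cnn_input(xi, dim3))
        arr <- aperm(xi, c(3, 1, 2))  # H x W x B -> B x H x W
        if (dim3) dim(arr) <- c(1L, dim(arr))
        arr
      }
      x1 <- data$x[[1]]
      nb <- if (inherits(x1, "leaf_sample")) dim(x1$cube$data)[3] else
        dim(x1)[3]
      cfg <- arch_config(arch_ids[a], n_bands = nb,
                         n_classes = max(data$y))
      model <- build_model(cfg, seed = rep_seeds[r])
      tc <- train_config
      tc$seed <- rep_seeds[r]
      fit <- train_cnn(model, lapply(tr, to_input), data$y[tr],
                       lapply(va, to_input), data$y[va], tc)
      preds <- predict(fit$model, lapply(test_idx, to_input),
                       batch = train_config$batch)
      acc[r, a] <- mean(preds == data$y[test_idx])
    }
  }
  stats <- dplyr::bind_rows(lapply(arch_ids, function(a) {
    v <- acc[, a]
    tibble::tibble(arch = a, metric = "accuracy", mean = mean(v),
                   sd = if (length(v) > 1) stats::sd(v) else 0,
                   cell = sprintf("%.2f ± %.2f", 100 * mean(v),
                                  100 * (if (length(v) > 1) stats::sd(v) else 0)))
  }))
  dunn <- if (length(arch_ids) >= 2 && n_rep >= 3)
    dunn_bonferroni(as.list(as.data.frame(acc))) else NULL
  list(stats = stats, accuracies = acc, dunn = dunn)
}
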