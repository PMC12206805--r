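# Minimal neural-network layer framework.
#
# Layers are environments (mutable: they hold parameters, Adam state and
# the caches needed for backpropagation). Tensors are channel-first
# column-major arrays: (C, H, W, N) for 2-d feature maps and
# (C, D, H, W, N) for 3-d ones, so BLAS-backed im2col kernels (src/) can
# copy contiguous channel blocks. The framework is deliberately small: it
# supports exactly the layer vocabulary of the architectures in this
# package.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$type <- type
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

nn_forward <- function(layer, x, training = FALSE) UseMethod("nn_forward")
nn_backward <- function(layer, gy) UseMethod("nn_backward")
# named list of parameter field names carried by this layer
nn_param_fields <- function(layer) UseMethod("nn_param_fields")
#' @export
nn_param_fields.default <- function(layer) character(0)
# non-trainable state that a checkpoint must carry (BN running statistics)
nn_state_fields <- function(layer) UseMethod("nn_state_fields")
#' @export
nn_state_fields.default <- function(layer) character(0)
#' @export
nn_state_fields.nn_bn <- function(layer) c("rmean", "rvar")
#' @export
nn_state_fields.nn_stem3d <- function(layer)
  c("rmean1", "rvar1", "rmean2", "rvar2")
#' @export
nn_state_fields.nn_pwbr <- function(layer) c("rmean", "rvar")
#' @export
nn_state_fields.nn_dwbn <- function(layer) c("rmean", "rvar")
# child layers of composites
nn_children <- function(layer) UseMethod("nn_children")
#' @export
nn_children.default <- function(layer) list()
# shape walk: `shape` is c(C, spatial...) without the batch axis; returns
# list(shape = ..., macs = multiply-accumulates for one input)
nn_shape <- function(layer, shape) UseMethod("nn_shape")
#' @export
nn_shape.default <- function(layer, shape) list(shape = shape, macs = 0)
# analytic parameter count from layer metadata (not from array sizes)
nn_analytic_params <- function(layer) UseMethod("nn_analytic_params")
#' @export
nn_analytic_params.default <- function(layer) 0

kaiming_init <- function(n, fan_in) rnorm(n, 0, sqrt(2 / fan_in))

#' Output length of a strided convolution
#'
#' `floor((L + 2 * padding - kernel) / stride) + 1`, the standard output
#' extent of a convolution or pooling axis.
#'
#' @param L input length (`>= 1`).
#' @param kernel kernel size (default 3).
#' @param stride stride.
#' @param padding zero padding per side (default 1).
#' @return Integer output length; errors if it would be `< 1`.
#' @examples
#' conv_out_len(30, 3, 2, 1)  # 15
#' conv_out_len(15, 3, 2, 1)  # 8
#' @export
conv_out_len <- function(L, kernel = 3L, stride = 1L, padding = 1L) {
  assert_that(L >= 1, "input length must be >= 1")
  out <- (L + 2 * padding - kernel) %/% stride + 1L
  assert_that(out >= 1, "output length < 1 for L=%d k=%d s=%d p=%d",
              L, kernel, stride, padding)
  as.integer(out)
}

# ------------------------------------------------------------------ conv --

layer_conv2d <- function(cin, cout, k = 3L, stride = 1L, pad = 1L) {
  l <- new_layer("conv2d", cin = cin, cout = cout, k = k,
                 stride = stride, pad = pad)
  l$W <- matrix(kaiming_init(cin * k * k * cout, cin * k * k),
                cin * k * k, cout)
  l
}
#' @export
nn_param_fields.nn_conv2d <- function(layer) "W"
#' @export
nn_forward.nn_conv2d <- function(layer, x, training = FALSE) {
  layer$xdim <- dim(x)
  r <- cpp_conv2d_fw(x, dim(x), layer$W, layer$k, layer$stride, layer$pad,
                     keep_col = training)
  layer$col <- if (training) r$col else NULL
  r$y
}
#' @export
nn_backward.nn_conv2d <- function(layer, gy) {
  need_gx <- is.null(layer$is_first)
  r <- cpp_conv2d_bw(layer$col, layer$xdim, layer$W, gy, layer$k,
                     layer$stride, layer$pad, need_gx)
  layer$gW <- r$gw
  layer$col <- NULL
  if (need_gx) r$gx else NULL
}
#' @export
nn_shape.nn_conv2d <- function(layer, shape) {
  oh <- conv_out_len(shape[2], layer$k, layer$stride, layer$pad)
  ow <- conv_out_len(shape[3], layer$k, layer$stride, layer$pad)
  list(shape = c(layer$cout, oh, ow),
       macs = as.numeric(layer$k)^2 * layer$cin * layer$cout * oh * ow)
}
#' @export
nn_analytic_params.nn_conv2d <- function(layer)
  layer$k^2 * layer$cin * layer$cout

layer_conv3d <- function(cin, cout, k = 3L, stride = c(2L, 2L, 2L),
                         pad = 1L) {
  l <- new_layer("conv3d", cin = cin, cout = cout, k = k,
                 stride = as.integer(stride), pad = pad)
  l$W <- matrix(kaiming_init(cin * k^3 * cout, cin * k^3), cin * k^3, cout)
  l
}
#' @export
nn_param_fields.nn_conv3d <- function(layer) "W"
#' @export
nn_forward.nn_conv3d <- function(layer, x, training = FALSE) {
  layer$xdim <- dim(x)
  r <- cpp_conv3d_fw(x, dim(x), layer$W, layer$k, layer$stride, layer$pad,
                     keep_col = training)
  layer$col <- if (training) r$col else NULL
  r$y
}
#' @export
nn_backward.nn_conv3d <- function(layer, gy) {
  need_gx <- is.null(layer$is_first)
  r <- cpp_conv3d_bw(layer$col, layer$xdim, layer$W, gy, layer$k,
                     layer$stride, layer$pad, need_gx)
  layer$gW <- r$gw
  layer$col <- NULL
  if (need_gx) r$gx else NULL
}
#' @export
nn_shape.nn_conv3d <- function(layer, shape) {
  od <- conv_out_len(shape[2], layer$k, layer$stride[1], layer$pad)
  oh <- conv_out_len(shape[3], layer$k, layer$stride[2], layer$pad)
  ow <- conv_out_len(shape[4], layer$k, layer$stride[3], layer$pad)
  list(shape = c(layer$cout, od, oh, ow),
       macs = as.numeric(layer$k)^3 * layer$cin * layer$cout * od * oh * ow)
}
#' @export
nn_analytic_params.nn_conv3d <- function(layer)
  layer$k^3 * layer$cin * layer$cout

layer_dwconv2d <- function(c, stride = 1L, k = 3L, pad = 1L) {
  l <- new_layer("dwconv2d", c = c, k = k, stride = stride, pad = pad)
  l$W <- matrix(kaiming_init(c * k * k, k * k), c, k * k)
  l
}
#' @export
nn_param_fields.nn_dwconv2d <- function(layer) "W"
#' @export
nn_forward.nn_dwconv2d <- function(layer, x, training = FALSE) {
  layer$x <- if (training) x else NULL
  layer$xdim <- dim(x)
  cpp_dwconv2d_fw(x, dim(x), layer$W, layer$k, layer$stride, layer$pad)
}
#' @export
nn_backward.nn_dwconv2d <- function(layer, gy) {
  r <- cpp_dwconv2d_bw(layer$x, layer$xdim, layer$W, gy, layer$k,
                       layer$stride, layer$pad)
  layer$gW <- r$gw
  layer$x <- NULL
  r$gx
}
#' @export
nn_shape.nn_dwconv2d <- function(layer, shape) {
  oh <- conv_out_len(shape[2], layer$k, layer$stride, layer$pad)
  ow <- conv_out_len(shape[3], layer$k, layer$stride, layer$pad)
  list(shape = c(layer$c, oh, ow),
       macs = as.numeric(layer$k)^2 * layer$c * oh * ow)
}
#' @export
nn_analytic_params.nn_dwconv2d <- function(layer) layer$k^2 * layer$c

layer_dwconv3d <- function(c, stride = c(1L, 1L, 1L), k = 3L, pad = 1L) {
  l <- new_layer("dwconv3d", c = c, k = k, stride = as.integer(stride),
                 pad = pad)
  l$W <- matrix(kaiming_init(c * k^3, k^3), c, k^3)
  l
}
#' @export
nn_param_fields.nn_dwconv3d <- function(layer) "W"
#' @export
nn_forward.nn_dwconv3d <- function(layer, x, training = FALSE) {
  layer$x <- if (training) x else NULL
  layer$xdim <- dim(x)
  cpp_dwconv3d_fw(x, dim(x), layer$W, layer$k, layer$stride, layer$pad)
}
#' @export
nn_backward.nn_dwconv3d <- function(layer, gy) {
  r <- cpp_dwconv3d_bw(layer$x, layer$xdim, layer$W, gy, layer$k,
                       layer$stride, layer$pad)
  layer$gW <- r$gw
  layer$x <- NULL
  r$gx
}
#' @export
nn_shape.nn_dwconv3d <- function(layer, shape) {
  od <- conv_out_len(shape[2], layer$k, layer$stride[1], layer$pad)
  oh <- conv_out_len(shape[3], layer$k, layer$stride[2], layer$pad)
  ow <- conv_out_len(shape[4], layer$k, layer$stride[3], layer$pad)
  list(shape = c(layer$c, od, oh, ow),
       macs = as.numeric(layer$k)^3 * layer$c * od * oh * ow)
}
#' @export
nn_analytic_params.nn_dwconv3d <- function(layer) layer$k^3 * layer$c

# -------------------------------------------------------------------- bn --

layer_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  new_layer("bn", c = c, momentum = momentum, eps = eps,
            gamma = rep(1, c), beta = rep(0, c),
            rmean = rep(0, c), rvar = rep(1, c))
}
#' @export
nn_param_fields.nn_bn <- function(layer) c("gamma", "beta")
#' @export
nn_forward.nn_bn <- function(layer, x, training = FALSE) {
  if (training) {
    r <- cpp_bn_fw(x, layer$c, layer$gamma, layer$beta, layer$eps)
    layer$x <- x
    layer$mean <- r$mean
    layer$invstd <- r$invstd
    m <- layer$momentum
    layer$rmean <- (1 - m) * layer$rmean + m * r$mean
    layer$rvar <- (1 - m) * layer$rvar + m * r$var
    r$y
  } else {
    cpp_bn_fw_eval(x, layer$c, layer$gamma, layer$beta, layer$rmean,
                   layer$rvar, layer$eps)
  }
}
#' @export
nn_backward.nn_bn <- function(layer, gy) {
  r <- cpp_bn_bw(layer$x, layer$c, gy, layer$gamma, layer$mean,
                 layer$invstd)
  layer$ggamma <- r$ggamma
  layer$gbeta <- r$gbeta
  layer$x <- NULL
  r$gx
}
#' @export
nn_analytic_params.nn_bn <- function(layer) 2 * layer$c

# ------------------------------------------------------------ activation --

layer_relu <- function() new_layer("relu")
#' @export
nn_forward.nn_relu <- function(layer, x, training = FALSE) {
  y <- cpp_relu_fw(x)
  layer$y <- if (training) y else NULL
  y
}
#' @export
nn_backward.nn_relu <- function(layer, gy) {
  gx <- cpp_relu_bw(layer$y, gy)
  layer$y <- NULL
  gx
}

layer_dropout <- function(p = 0.2) new_layer("dropout", p = p)
#' @export
nn_forward.nn_dropout <- function(layer, x, training = FALSE) {
  if (!training || layer$p <= 0) return(x)
  keep <- (runif(length(x)) >= layer$p) / (1 - layer$p)
  layer$mask <- keep
  y <- x * keep
  dim(y) <- dim(x)
  y
}
#' @export
nn_backward.nn_dropout <- function(layer, gy) {
  if (is.null(layer$mask)) return(gy)
  gx <- gy * layer$mask
  dim(gx) <- dim(gy)
  layer$mask <- NULL
  gx
}

# --------------------------------------------------------------- pooling --

layer_maxpool2d <- function(k = 3L, stride = 2L, pad = 1L)
  new_layer("maxpool2d", k = k, stride = stride, pad = pad)
#' @export
nn_forward.nn_maxpool2d <- function(layer, x, training = FALSE) {
  r <- cpp_maxpool2d_fw(x, dim(x), layer$k, layer$stride, layer$pad)
  layer$argmax <- if (training) r$argmax else NULL
  layer$n_in <- length(x)
  layer$xdim <- dim(x)
  r$y
}
#' @export
nn_backward.nn_maxpool2d <- function(layer, gy) {
  gx <- cpp_maxpool_bw(gy, layer$argmax, layer$n_in)
  dim(gx) <- layer$xdim
  layer$argmax <- NULL
  gx
}
#' @export
nn_shape.nn_maxpool2d <- function(layer, shape)
  list(shape = c(shape[1],
                 conv_out_len(shape[2], layer$k, layer$stride, layer$pad),
                 conv_out_len(shape[3], layer$k, layer$stride, layer$pad)),
       macs = 0)

layer_maxpool3d <- function(k = 3L, stride = c(2L, 2L, 2L), pad = 1L)
  new_layer("maxpool3d", k = k, stride = as.integer(stride), pad = pad)
#' @export
nn_forward.nn_maxpool3d <- function(layer, x, training = FALSE) {
  r <- cpp_maxpool3d_fw(x, dim(x), layer$k, layer$stride, layer$pad)
  layer$argmax <- if (training) r$argmax else NULL
  layer$n_in <- length(x)
  layer$xdim <- dim(x)
  r$y
}
#' @export
nn_backward.nn_maxpool3d <- function(layer, gy) {
  gx <- cpp_maxpool_bw(gy, layer$argmax, layer$n_in)
  dim(gx) <- layer$xdim
  layer$argmax <- NULL
  gx
}
#' @export
nn_shape.nn_maxpool3d <- function(layer, shape)
  list(shape = c(shape[1],
                 conv_out_len(shape[2], layer$k, layer$stride[1], layer$pad),
                 conv_out_len(shape[3], layer$k, layer$stride[2], layer$pad),
                 conv_out_len(shape[4], layer$k, layer$stride[3], layer$pad)),
       macs = 0)

# Adaptive average pooling over the spectral (depth) axis only:
# (C, D, H, W, N) -> (C, out_d, H, W, N), segment i = [floor(i*D/out_d),
# ceil((i+1)*D/out_d)).
layer_pool_spectral <- function(out_d = 2L)
  new_layer("pool_spectral", out_d = as.integer(out_d))
spectral_segments <- function(D, out_d) {
  lapply(seq_len(out_d) - 1L, function(i)
    (floor(i * D / out_d) + 1L):ceiling((i + 1) * D / out_d))
}
#' @export
nn_forward.nn_pool_spectral <- function(layer, x, training = FALSE) {
  d <- dim(x)
  segs <- spectral_segments(d[2], layer$out_d)
  y <- array(0, c(d[1], layer$out_d, d[3], d[4], d[5]))
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    y[, i, , , ] <- Reduce(`+`, lapply(seg, function(s) x[, s, , , ])) /
      length(seg)
  }
  layer$xdim <- d
  layer$segs <- segs
  y
}
#' @export
nn_backward.nn_pool_spectral <- function(layer, gy) {
  gx <- array(0, layer$xdim)
  for (i in seq_along(layer$segs)) {
    seg <- layer$segs[[i]]
    g <- gy[, i, , , ] / length(seg)
    for (s in seg) gx[, s, , , ] <- gx[, s, , , ] + g
  }
  gx
}
#' @export
nn_shape.nn_pool_spectral <- function(layer, shape)
  list(shape = c(shape[1], layer$out_d, shape[3], shape[4]), macs = 0)

# Merge (C, D, H, W, N) -> (C * D, H, W, N): channels and pooled spectral
# depth collapse into one 2-d channel axis (the 3D->2D transition).
layer_merge_depth <- function() new_layer("merge_depth")
#' @export
nn_forward.nn_merge_depth <- function(layer, x, training = FALSE) {
  d <- dim(x)
  layer$xdim <- d
  dim(x) <- c(d[1] * d[2], d[3], d[4], d[5])
  x
}
#' @export
nn_backward.nn_merge_depth <- function(layer, gy) {
  dim(gy) <- layer$xdim
  gy
}
#' @export
nn_shape.nn_merge_depth <- function(layer, shape)
  list(shape = c(shape[1] * shape[2], shape[3], shape[4]), macs = 0)

# Global average pool over all non-channel axes: returns an (N, C) matrix.
layer_global_pool <- function() new_layer("global_pool")
#' @export
nn_forward.nn_global_pool <- function(layer, x, training = FALSE) {
  d <- dim(x)
  layer$xdim <- d
  n <- d[length(d)]
  m <- prod(d[-c(1, length(d))])
  xm <- matrix(x, nrow = d[1])  # C x (spatial * N)
  # average each consecutive block of m columns
  y <- matrix(0, n, d[1])
  for (i in seq_len(n))
    y[i, ] <- rowMeans(xm[, ((i - 1) * m + 1):(i * m), drop = FALSE])
  layer$m <- m
  y
}
#' @export
nn_backward.nn_global_pool <- function(layer, gy) {
  d <- layer$xdim
  n <- d[length(d)]
  m <- layer$m
  gx <- matrix(0, d[1], m * n)
  for (i in seq_len(n))
    gx[, ((i - 1) * m + 1):(i * m)] <- gy[i, ] / m
  dim(gx) <- d
  gx
}
#' @export
nn_shape.nn_global_pool <- function(layer, shape)
  list(shape = shape[1], macs = 0)

# ---------------------------------------------------------------- linear --

layer_linear <- function(cin, cout) {
  l <- new_layer("linear", cin = cin, cout = cout)
  l$W <- matrix(kaiming_init(cin * cout, cin), cin, cout)
  l$b <- rep(0, cout)
  l
}
#' @export
nn_param_fields.nn_linear <- function(layer) c("W", "b")
#' @export
nn_forward.nn_linear <- function(layer, x, training = FALSE) {
  layer$x <- if (training) x else NULL
  sweep(x %*% layer$W, 2, layer$b, `+`)
}
#' @export
nn_backward.nn_linear <- function(layer, gy) {
  layer$gW <- crossprod(layer$x, gy)
  layer$gb <- colSums(gy)
  gx <- gy %*% t(layer$W)
  layer$x <- NULL
  gx
}
#' @export
nn_shape.nn_linear <- function(layer, shape)
  list(shape = layer$cout, macs = as.numeric(layer$cin) * layer$cout)
#' @export
nn_analytic_params.nn_linear <- function(layer)
  layer$cin * layer$cout + layer$cout

# --------------------------------------------------------------- shuffle --

# Channel shuffle permutation: reshape (groups, C/groups), transpose,
# flatten. For C = 4, groups = 2 the channel order becomes (1, 3, 2, 4).
shuffle_perm <- function(C, groups) {
  assert_that(C %% groups == 0, "channels (%d) not divisible by groups (%d)",
              C, groups)
  as.vector(t(matrix(seq_len(C), ncol = groups)))
}

layer_shuffle <- function(groups = 2L) new_layer("shuffle", groups = groups)
#' @export
nn_forward.nn_shuffle <- function(layer, x, training = FALSE) {
  d <- dim(x)
  perm <- shuffle_perm(d[1], layer$groups)
  layer$perm <- perm
  xm <- matrix(x, nrow = d[1])
  y <- xm[perm, , drop = FALSE]
  dim(y) <- d
  y
}
#' @export
nn_backward.nn_shuffle <- function(layer, gy) {
  d <- dim(gy)
  inv <- order(layer$perm)
  gm <- matrix(gy, nrow = d[1])
  gx <- gm[inv, , drop = FALSE]
  dim(gx) <- d
  gx
}

#' Channel shuffle
#'
#' The fixed channel permutation used after grouped/branched convolutions:
#' channels are reshaped to `(groups, C/groups)`, transposed and
#' flattened, mixing information across groups. Spatial and spectral
#' content is untouched; applying the shuffle with swapped group shape
#' (`C/groups` groups) inverts it.
#'
#' @param x array whose first dimension is the channel axis.
#' @param groups number of groups (default 2); must divide the channel
#'   count.
#' @return Array of the same shape with channels permuted.
#' @export
channel_shuffle <- function(x, groups = 2L) {
  d <- dim(x)
  assert_that(!is.null(d), "x must be an array with channels first")
  perm <- shuffle_perm(d[1], groups)
  xm <- matrix(x, nrow = d[1])
  y <- xm[perm, , drop = FALSE]
  dim(y) <- d
  y
}

# ------------------------------------------------------------ sequential --

layer_sequential <- function(layers, name = "seq")
  new_layer("sequential", layers = layers, name = name)
#' @export
nn_children.nn_sequential <- function(layer) layer$layers
#' @export
nn_forward.nn_sequential <- function(layer, x, training = FALSE) {
  for (l in layer$layers) x <- nn_forward(l, x, training)
  x
}
#' @export
nn_backward.nn_sequential <- function(layer, gy) {
  for (l in rev(layer$layers)) gy <- nn_backward(l, gy)
  gy
}
#' @export
nn_shape.nn_sequential <- function(layer, shape) {
  macs <- 0
  for (l in layer$layers) {
    r <- nn_shape(l, shape)
    shape <- r$shape
    macs <- macs + r$macs
  }
  list(shape = shape, macs = macs)
}

# Parameter traversal: returns a list of (layer, field) handles.
nn_param_handles <- function(layer) {
  out <- list()
  for (f in nn_param_fields(layer))
    out[[length(out) + 1L]] <- list(layer = layer, field = f)
  for (ch in nn_children(layer)) out <- c(out, nn_param_handles(ch))
  out
}

# Checkpoint state: trainable parameters plus BN running statistics.
nn_checkpoint_handles <- function(layer) {
  out <- list()
  for (f in c(nn_param_fields(layer), nn_state_fields(layer)))
    out[[length(out) + 1L]] <- list(layer = layer, field = f)
  for (ch in nn_children(layer)) out <- c(out, nn_checkpoint_handles(ch))
  out
}

nn_count_params <- function(layer) {
  sum(vapply(nn_param_handles(layer), function(h)
    length(get(h$field, envir = h$layer)), numeric(1)))
}

nn_analytic_count <- function(layer) {
  total <- nn_analytic_params(layer)
  for (ch in nn_children(layer)) total <- total + nn_analytic_count(ch)
  total
}

# ------------------------------------------------------------ fused stem --
#
# The two 3-d stem convolutions + BN + ReLU + spectral pooling + merge of
# the hybrid network, fused into single-precision C++ kernels. Numerically
# equivalent (to float precision) to the corresponding generic layer chain
# and much faster, since the large stem activations never round-trip
# through R. Parameter draws occur in the same order as the generic
# layers, so a fused and an unfused build from one seed share weights.
layer_stem3d <- function(c1 = 16L, c2 = 32L, out_d = 2L,
                         momentum = 0.1, eps = 1e-5) {
  l <- new_layer("stem3d", c1 = c1, c2 = c2, out_d = out_d,
                 momentum = momentum, eps = eps)
  l$W1 <- matrix(kaiming_init(27 * c1, 27), 27, c1)
  l$gamma1 <- rep(1, c1); l$beta1 <- rep(0, c1)
  l$rmean1 <- rep(0, c1); l$rvar1 <- rep(1, c1)
  l$W2 <- matrix(kaiming_init(27 * c1 * c2, 27 * c1), 27 * c1, c2)
  l$gamma2 <- rep(1, c2); l$beta2 <- rep(0, c2)
  l$rmean2 <- rep(0, c2); l$rvar2 <- rep(1, c2)
  l
}
#' @export
nn_param_fields.nn_stem3d <- function(layer)
  c("W1", "gamma1", "beta1", "W2", "gamma2", "beta2")
#' @export
nn_forward.nn_stem3d <- function(layer, x, training = FALSE) {
  r <- cpp_stem3d_fw(x, dim(x), layer$W1, layer$gamma1, layer$beta1,
                     layer$rmean1, layer$rvar1,
                     layer$W2, layer$gamma2, layer$beta2,
                     layer$rmean2, layer$rvar2,
                     layer$out_d, layer$eps, training,
                     if (is.null(layer$cache)) NULL else layer$cache)
  layer$cache <- r$cache  # persistent scratch, reused across batches
  if (training) {
    m <- layer$momentum
    layer$rmean1 <- (1 - m) * layer$rmean1 + m * r$bm1
    layer$rvar1 <- (1 - m) * layer$rvar1 + m * r$bv1
    layer$rmean2 <- (1 - m) * layer$rmean2 + m * r$bm2
    layer$rvar2 <- (1 - m) * layer$rvar2 + m * r$bv2
  }
  r$y
}
#' @export
nn_backward.nn_stem3d <- function(layer, gy) {
  r <- cpp_stem3d_bw(layer$cache, gy, layer$W1, layer$gamma1, layer$beta1,
                     layer$W2, layer$gamma2, layer$beta2)
  layer$gW1 <- r$gw1; layer$ggamma1 <- r$ggamma1; layer$gbeta1 <- r$gbeta1
  layer$gW2 <- r$gw2; layer$ggamma2 <- r$ggamma2; layer$gbeta2 <- r$gbeta2
  NULL  # first layer: input gradient not needed
}
#' @export
nn_shape.nn_stem3d <- function(layer, shape) {
  d1 <- vapply(shape[2:4], conv_out_len, 1L, kernel = 3L, stride = 2L,
               padding = 1L)
  d2 <- vapply(d1, conv_out_len, 1L, kernel = 3L, stride = 2L, padding = 1L)
  list(shape = c(layer$c2 * layer$out_d, d2[2], d2[3]),
       macs = 27 * layer$c1 * prod(d1) + 27 * layer$c1 * layer$c2 * prod(d2))
}
#' @export
nn_analytic_params.nn_stem3d <- function(layer)
  27 * layer$c1 + 2 * layer$c1 + 27 * layer$c1 * layer$c2 + 2 * layer$c2

# Fused 1x1 conv + BN (+ ReLU) on 2-d channel-first tensors.
layer_pwbr <- function(cin, cout, relu = TRUE, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("pwbr", cin = cin, cout = cout, relu = relu,
                 momentum = momentum, eps = eps)
  l$W <- matrix(kaiming_init(cin * cout, cin), cin, cout)
  l$gamma <- rep(1, cout); l$beta <- rep(0, cout)
  l$rmean <- rep(0, cout); l$rvar <- rep(1, cout)
  l
}
#' @export
nn_param_fields.nn_pwbr <- function(layer) c("W", "gamma", "beta")
#' @export
nn_forward.nn_pwbr <- function(layer, x, training = FALSE) {
  layer$xdim <- dim(x)
  r <- cpp_pwbr_fw(x, layer$cin, layer$W, layer$gamma, layer$beta,
                   layer$rmean, layer$rvar, layer$eps, layer$relu,
                   training, if (is.null(layer$cache)) NULL else layer$cache)
  layer$cache <- r$cache
  if (training) {
    m <- layer$momentum
    layer$rmean <- (1 - m) * layer$rmean + m * r$bm
    layer$rvar <- (1 - m) * layer$rvar + m * r$bv
  }
  y <- r$y
  dim(y) <- c(layer$cout, layer$xdim[-1])
  y
}
#' @export
nn_backward.nn_pwbr <- function(layer, gy) {
  r <- cpp_pwbr_bw(layer$cache, gy, layer$W, layer$gamma, layer$beta,
                   layer$relu)
  layer$gW <- r$gw; layer$ggamma <- r$ggamma; layer$gbeta <- r$gbeta
  gx <- r$gx
  dim(gx) <- layer$xdim
  gx
}
#' @export
nn_shape.nn_pwbr <- function(layer, shape)
  list(shape = c(layer$cout, shape[-1]),
       macs = as.numeric(layer$cin) * layer$cout * prod(shape[-1]))
#' @export
nn_analytic_params.nn_pwbr <- function(layer)
  layer$cin * layer$cout + 2 * layer$cout

# Fused 3x3 depthwise conv + BN (linear output, per the unit design).
layer_dwbn <- function(c, stride = 1L, k = 3L, pad = 1L, momentum = 0.1,
                       eps = 1e-5) {
  l <- new_layer("dwbn", c = c, k = k, stride = stride, pad = pad,
                 momentum = momentum, eps = eps)
  l$W <- matrix(kaiming_init(c * k * k, k * k), c, k * k)
  l$gamma <- rep(1, c); l$beta <- rep(0, c)
  l$rmean <- rep(0, c); l$rvar <- rep(1, c)
  l
}
#' @export
nn_param_fields.nn_dwbn <- function(layer) c("W", "gamma", "beta")
#' @export
nn_forward.nn_dwbn <- function(layer, x, training = FALSE) {
  layer$xdim <- dim(x)
  r <- cpp_dwbn_fw(x, dim(x), layer$W, layer$k, layer$stride, layer$pad,
                   layer$gamma, layer$beta, layer$rmean, layer$rvar,
                   layer$eps, training,
                   if (is.null(layer$cache)) NULL else layer$cache)
  layer$cache <- r$cache
  if (training) {
    m <- layer$momentum
    layer$rmean <- (1 - m) * layer$rmean + m * r$bm
    layer$rvar <- (1 - m) * layer$rvar + m * r$bv
  }
  r$y
}
#' @export
nn_backward.nn_dwbn <- function(layer, gy) {
  r <- cpp_dwbn_bw(layer$cache, layer$xdim, gy, layer$W, layer$k,
                   layer$stride, layer$pad, layer$gamma)
  layer$gW <- r$gw; layer$ggamma <- r$ggamma; layer$gbeta <- r$gbeta
  r$gx
}
#' @export
nn_shape.nn_dwbn <- function(layer, shape) {
  oh <- conv_out_len(shape[2], layer$k, layer$stride, layer$pad)
  ow <- conv_out_len(shape[3], layer$k, layer$stride, layer$pad)
  list(shape = c(layer$c, oh, ow),
       macs = as.numeric(layer$k)^2 * layer$c * oh * ow)
}
#' @export
nn_analytic_params.nn_dwbn <- function(layer)
  layer$k^2 * layer$c + 2 * layer$c
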