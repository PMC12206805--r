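# ShuffleNetV2 building blocks, in 2-d and 3-d flavours.
#
# basic unit: channel split (half/half); one half passes through, the
#   other goes through 1x1 conv + BN + ReLU, 3x3 depthwise + BN, 1x1 conv
#   + BN + ReLU; halves are concatenated and channel-shuffled (groups 2).
# downsampling unit: no split; both branches are strided, so the
#   concatenation doubles the channel count while the spatial extent
#   halves; shuffle at the end.

ch_split <- function(x, h) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1])
  x1 <- xm[seq_len(h), , drop = FALSE]
  x2 <- xm[(h + 1):d[1], , drop = FALSE]
  dim(x1) <- c(h, d[-1])
  dim(x2) <- c(d[1] - h, d[-1])
  list(x1, x2)
}

ch_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- rbind(matrix(a, nrow = da[1]), matrix(b, nrow = db[1]))
  dim(y) <- c(da[1] + db[1], da[-1])
  y
}

# pointwise conv helper (1x1 or 1x1x1)
pw_conv <- function(cin, cout, dim3) {
  if (dim3) layer_conv3d(cin, cout, k = 1L, stride = c(1L, 1L, 1L), pad = 0L)
  else layer_conv2d(cin, cout, k = 1L, stride = 1L, pad = 0L)
}

dw_conv <- function(c, strided, dim3) {
  if (dim3) layer_dwconv3d(c, stride = if (strided) c(1L, 2L, 2L)
                           else c(1L, 1L, 1L))
  else layer_dwconv2d(c, stride = if (strided) 2L else 1L)
}

unit_basic <- function(C, dim3 = FALSE, fuse = !dim3) {
  h <- C %/% 2L
  branch <- if (fuse) layer_sequential(list(
    layer_pwbr(h, h), layer_dwbn(h, 1L), layer_pwbr(h, h)))
  else layer_sequential(list(
    pw_conv(h, h, dim3), layer_bn(h), layer_relu(),
    dw_conv(h, strided = FALSE, dim3), layer_bn(h),
    pw_conv(h, h, dim3), layer_bn(h), layer_relu()))
  new_layer("unit_basic", C = C, h = h, dim3 = dim3, branch = branch,
            shuffle = layer_shuffle(2L))
}
#' @export
nn_children.nn_unit_basic <- function(layer) list(layer$branch)
#' @export
nn_forward.nn_unit_basic <- function(layer, x, training = FALSE) {
  sp <- ch_split(x, layer$h)
  y2 <- nn_forward(layer$branch, sp[[2]], training)
  nn_forward(layer$shuffle, ch_concat(sp[[1]], y2), training)
}
#' @export
nn_backward.nn_unit_basic <- function(layer, gy) {
  g <- nn_backward(layer$shuffle, gy)
  gs <- ch_split(g, layer$h)
  gx2 <- nn_backward(layer$branch, gs[[2]])
  ch_concat(gs[[1]], gx2)
}
#' @export
nn_shape.nn_unit_basic <- function(layer, shape) {
  br <- nn_shape(layer$branch, c(layer$h, shape[-1]))
  list(shape = shape, macs = br$macs)
}

unit_down <- function(cin, cout, dim3 = FALSE, fuse = !dim3) {
  cb <- cout %/% 2L
  branch1 <- if (fuse) layer_sequential(list(
    layer_dwbn(cin, 2L), layer_pwbr(cin, cb)))
  else layer_sequential(list(
    dw_conv(cin, strided = TRUE, dim3), layer_bn(cin),
    pw_conv(cin, cb, dim3), layer_bn(cb), layer_relu()))
  branch2 <- if (fuse) layer_sequential(list(
    layer_pwbr(cin, cb), layer_dwbn(cb, 2L), layer_pwbr(cb, cb)))
  else layer_sequential(list(
    pw_conv(cin, cb, dim3), layer_bn(cb), layer_relu(),
    dw_conv(cb, strided = TRUE, dim3), layer_bn(cb),
    pw_conv(cb, cb, dim3), layer_bn(cb), layer_relu()))
  new_layer("unit_down", cin = cin, cout = cout, cb = cb, dim3 = dim3,
            branch1 = branch1, branch2 = branch2,
            shuffle = layer_shuffle(2L))
}
#' @export
nn_children.nn_unit_down <- function(layer)
  list(layer$branch1, layer$branch2)
#' @export
nn_forward.nn_unit_down <- function(layer, x, training = FALSE) {
  y1 <- nn_forward(layer$branch1, x, training)
  y2 <- nn_forward(layer$branch2, x, training)
  nn_forward(layer$shuffle, ch_concat(y1, y2), training)
}
#' @export
nn_backward.nn_unit_down <- function(layer, gy) {
  g <- nn_backward(layer$shuffle, gy)
  gs <- ch_split(g, layer$cb)
  nn_backward(layer$branch1, gs[[1]]) + nn_backward(layer$branch2, gs[[2]])
}
#' @export
nn_shape.nn_unit_down <- function(layer, shape) {
  b1 <- nn_shape(layer$branch1, shape)
  b2 <- nn_shape(layer$branch2, shape)
  stopifnot(all(b1$shape[-1] == b2$shape[-1]))
  list(shape = c(b1$shape[1] + b2$shape[1], b1$shape[-1]),
       macs = b1$macs + b2$macs)
}
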