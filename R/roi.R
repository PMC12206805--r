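#' Otsu threshold of a grayscale image
#'
#' Computes the threshold maximising the between-class variance of the
#' image's `nbins`-bin histogram (bins span `[min, max]` of the values).
#' Ties are resolved toward the lowest threshold. Pixels strictly above the
#' returned value form the upper class.
#'
#' @param image numeric matrix (grayscale), all values finite.
#' @param nbins number of histogram bins (default 256).
#' @return The threshold, a scalar on the image's intensity scale.
#' @export
otsu_threshold <- function(image, nbins = 256L) {
  assert_that(is.numeric(image) && all(is.finite(image)),
              "image must be finite numeric")
  assert_that(nbins >= 2, "nbins must be >= 2")
  v <- as.vector(image)
  lo <- min(v); hi <- max(v)
  assert_that(hi > lo, "degenerate histogram: constant image")
  # Histogram over nbins equal-width bins on [lo, hi].
  idx <- pmin(floor((v - lo) / (hi - lo) * nbins) + 1L, nbins)
  counts <- tabulate(idx, nbins)
  n <- length(v)
  centers <- lo + (seq_len(nbins) - 0.5) * (hi - lo) / nbins
  # Cumulative statistics; cut after bin k puts bins 1..k in the lower class.
  w0 <- cumsum(counts)[-nbins]
  w1 <- n - w0
  m0 <- cumsum(counts * centers)[-nbins]
  m1 <- sum(counts * centers) - m0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins - 1L)
  sigma_b[valid] <- (w0[valid] / n) * (w1[valid] / n) *
    (m0[valid] / w0[valid] - m1[valid] / w1[valid])^2
  k <- which.max(sigma_b)  # first maximum = lowest threshold on ties
  lo + k * (hi - lo) / nbins
}

#' Segment the leaf from the background
#'
#' Thresholds the band nearest `ref_nm` (leaves are bright in the
#' near-infrared, the background dark) with [otsu_threshold()], keeps the
#' largest 8-connected foreground component and fills its holes. Foreground
#' polarity is chosen as the side with the higher mean reflectance at
#' `ref_nm`.
#'
#' @param cube a `hyper_cube`.
#' @param ref_nm reference wavelength, default 800 nm.
#' @param nbins histogram bins for Otsu.
#' @return Binary `H x W` integer matrix (1 = leaf, 0 = background).
#' @export
segment_leaf <- function(cube, ref_nm = 800, nbins = 256L) {
  assert_that(is_cube(cube), "`cube` must be a hyper_cube")
  band <- cube$data[, , band_index(cube, ref_nm)]
  thr <- otsu_threshold(band, nbins)
  mask <- band > thr
  # Leaf is the brighter class in the NIR; flip if Otsu's upper class is not.
  if (any(mask) && any(!mask) &&
      mean(band[mask]) < mean(band[!mask])) mask <- !mask
  mask <- clean_mask(mask)
  frac <- mean(mask)
  assert_that(frac >= 0.005, "no leaf found (foreground %.2f%% of pixels)",
              100 * frac)
  mask
}

# Largest 8-connected component, holes filled. Holes are 4-connected
# background components that do not touch the image border.
clean_mask <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(m)
  lab <- cpp_label_components(m, 8L)
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    m <- matrix(as.integer(lab == which.max(sizes)), nrow(m), ncol(m))
  }
  bg <- 1L - m
  labbg <- cpp_label_components(bg, 4L)
  border <- unique(c(labbg[1, ], labbg[nrow(labbg), ],
                     labbg[, 1], labbg[, ncol(labbg)]))
  hole <- bg == 1L & !(labbg %in% border)
  m[hole] <- 1L
  m
}

#' Mean spectrum over a mask
#'
#' Per-band arithmetic mean of the reflectance over foreground pixels.
#'
#' @param cube a `hyper_cube`.
#' @param mask binary `H x W` matrix (1 = include).
#' @return Numeric vector of length B with attribute `"wavelength"`.
#' @export
extract_mean_spectrum <- function(cube, mask) {
  assert_that(is_cube(cube), "`cube` must be a hyper_cube")
  d <- dim(cube$data)
  assert_that(all(dim(mask) == d[1:2]), "mask shape must match cube")
  sel <- which(mask > 0)
  assert_that(length(sel) > 0, "empty mask")
  flat <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  out <- colMeans(flat[sel, , drop = FALSE])
  attr(out, "wavelength") <- cube$wavelength
  out
}

#' Leaf sample container
#'
#' Bundles a cube with its binary mask, class label and provenance: the
#' parent leaf id and a sub-block index (`0` = whole leaf). Sub-blocks
#' inherit `leaf_id` and `label` from their parent, which is what makes
#' leakage-free dataset partitioning possible.
#'
#' @param cube a `hyper_cube`.
#' @param mask binary `H x W` matrix.
#' @param label class id in `1..6`.
#' @param leaf_id parent leaf identifier (character or integer).
#' @param block_index integer `>= 0`; 0 means the whole leaf.
#' @return An object of class `leaf_sample`.
#' @export
leaf_sample <- function(cube, mask, label, leaf_id, block_index = 0L) {
  assert_that(is_cube(cube), "`cube` must be a hyper_cube")
  assert_that(all(dim(mask) == dim(cube$data)[1:2]),
              "mask shape must match cube")
  assert_that(label %in% 1:6, "label must be in 1..6")
  structure(list(cube = cube, mask = mask, label = as.integer(label),
                 leaf_id = as.character(leaf_id),
                 block_index = as.integer(block_index)),
            class = "leaf_sample")
}

#' @export
print.leaf_sample <- function(x, ...) {
  cat(sprintf("<leaf_sample> leaf %s block %d, class %d, %s pixels fg\n",
              x$leaf_id, x$block_index, x$label, sum(x$mask)))
  invisible(x)
}

# Bounding box of a binary mask: list(rows = c(r0, r1), cols = c(c0, c1)).
mask_bbox <- function(mask) {
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  list(rows = rr, cols = cc)
}

#' Split a whole leaf into overlapping sub-blocks
#'
#' Cuts `k` windows along the longer axis of the mask's bounding box. The
#' window length is `ceiling(L / (k - (k - 1) * overlap))` with uniformly
#' spaced starts, which keeps the pairwise overlap fraction (shared length /
#' window length) under 30% for the default `overlap = 0.25`. Each sub-block
#' carries the cropped cube and mask, the parent `leaf_id` and a
#' `block_index` in `1..k`.
#'
#' @param sample a whole-leaf [leaf_sample()] (`block_index == 0`).
#' @param k number of sub-blocks, 2..4.
#' @param overlap nominal overlap parameter in `[0, 0.3)`.
#' @return List of `k` `leaf_sample` objects.
#' @export
split_subblocks <- function(sample, k, overlap = 0.25) {
  assert_that(inherits(sample, "leaf_sample"), "`sample` must be a leaf_sample")
  assert_that(k %in% 2:4, "k must be 2, 3 or 4")
  bb <- mask_bbox(sample$mask)
  len_r <- diff(bb$rows) + 1L
  len_c <- diff(bb$cols) + 1L
  along_rows <- len_r >= len_c
  L <- if (along_rows) len_r else len_c
  assert_that(L >= k, "bounding box long axis (%d) shorter than k", L)
  geom <- subblock_windows(L, k, overlap)
  Lw <- geom$length
  starts <- geom$starts
  out <- vector("list", k)
  for (i in seq_len(k)) {
    a <- starts[i] + 1L
    b <- min(starts[i] + Lw, L)
    if (along_rows) {
      rows <- (bb$rows[1] + a - 1L):(bb$rows[1] + b - 1L)
      cols <- bb$cols[1]:bb$cols[2]
    } else {
      rows <- bb$rows[1]:bb$rows[2]
      cols <- (bb$cols[1] + a - 1L):(bb$cols[1] + b - 1L)
    }
    sub_cube <- hyper_cube(sample$cube$data[rows, cols, , drop = FALSE],
                           sample$cube$wavelength, sample$cube$interleave)
    out[[i]] <- leaf_sample(sub_cube, sample$mask[rows, cols, drop = FALSE],
                            sample$label, sample$leaf_id, block_index = i)
  }
  out
}

# Window geometry used by split_subblocks, exposed for auditing: start
# offsets (0-based) and window length along the long axis. The nominal
# window length ceiling(L / (k - (k-1)*overlap)) can, for short leaves,
# breach the 30% pairwise-overlap cap once starts are rounded to pixels;
# the length is then shrunk minimally (never below the coverage bound
# ceiling(L / k)) until the cap holds.
subblock_windows <- function(L, k, overlap = 0.25, cap = 0.30) {
  Lw <- ceiling(L / (k - (k - 1) * overlap))
  repeat {
    starts <- round((seq_len(k) - 1) * (L - Lw) / (k - 1))
    shared <- utils::head(starts, -1) + Lw - utils::tail(starts, -1)
    if (max(shared) / Lw < cap || Lw <= ceiling(L / k)) break
    Lw <- Lw - 1L
  }
  list(starts = starts, length = Lw)
}

#' Default sub-block count for a leaf
#'
#' The number of sub-blocks (2-4) grows with the leaf's long-axis length:
#' under 150 px gives 2, under 250 px gives 3, otherwise 4.
#'
#' @param sample a [leaf_sample()].
#' @return Integer in 2..4.
#' @export
choose_k_subblocks <- function(sample) {
  bb <- mask_bbox(sample$mask)
  L <- max(diff(bb$rows) + 1L, diff(bb$cols) + 1L)
  if (L < 150) 2L else if (L < 250) 3L else 4L
}

#' Zero-centred padding to a fixed spatial size
#'
#' Zeroes the background (applies the mask), crops to the mask's bounding
#' box, and centres the ROI in a `size x size` zero frame. If either ROI
#' dimension exceeds `size`, the ROI is first downscaled with
#' nearest-neighbour sampling, preserving aspect ratio, so the longer side
#' equals `size`.
#'
#' @param sample a [leaf_sample()].
#' @param size output side length in pixels (default 112).
#' @return A `leaf_sample` with `H = W = size`.
#' @export
pad_center <- function(sample, size = 112L) {
  assert_that(inherits(sample, "leaf_sample"), "`sample` must be a leaf_sample")
  arr <- sample$cube$data * as.vector(sample$mask)  # zero background
  bb <- mask_bbox(sample$mask)
  arr <- arr[bb$rows[1]:bb$rows[2], bb$cols[1]:bb$cols[2], , drop = FALSE]
  msk <- sample$mask[bb$rows[1]:bb$rows[2], bb$cols[1]:bb$cols[2], drop = FALSE]
  d <- dim(arr)
  if (max(d[1:2]) > size) {
    s <- size / max(d[1:2])
    nh <- max(1L, round(d[1] * s)); nw <- max(1L, round(d[2] * s))
    ri <- pmin(d[1], floor((seq_len(nh) - 0.5) / s) + 1L)
    ci <- pmin(d[2], floor((seq_len(nw) - 0.5) / s) + 1L)
    arr <- arr[ri, ci, , drop = FALSE]
    msk <- msk[ri, ci, drop = FALSE]
    d <- dim(arr)
  }
  out <- array(0, c(size, size, d[3]))
  om <- matrix(0L, size, size)
  r0 <- floor((size - d[1]) / 2); c0 <- floor((size - d[2]) / 2)
  out[r0 + seq_len(d[1]), c0 + seq_len(d[2]), ] <- arr
  om[r0 + seq_len(d[1]), c0 + seq_len(d[2])] <- msk
  leaf_sample(hyper_cube(out, sample$cube$wavelength,
                         sample$cube$interleave),
              om, sample$label, sample$leaf_id, sample$block_index)
}

#' Stratified leaf-level dataset partition
#'
#' Splits whole leaves into train/validation/test folds, stratified by
#' class, at the leaf level: every sub-block later inherits its parent
#' leaf's fold, so no leaf contributes pixels to two folds.
#'
#' @param samples list of whole-leaf [leaf_sample()]s (`block_index == 0`),
#'   or a data frame with columns `leaf_id` and `label`.
#' @param ratios train/validation/test proportions summing to 1.
#' @param seed integer seed; the same seed reproduces the same partition.
#' @return A list of class `dataset_partition` with character vectors
#'   `train`, `validation`, `test` of leaf ids, plus the `seed`.
#' @export
partition_dataset <- function(samples, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  assert_that(abs(sum(ratios) - 1) < 1e-8 && length(ratios) == 3,
              "ratios must be 3 proportions summing to 1")
  if (is.data.frame(samples)) {
    df <- samples[, c("leaf_id", "label")]
  } else {
    assert_that(all(vapply(samples, function(s)
      inherits(s, "leaf_sample") && s$block_index == 0L, TRUE)),
      "samples must be whole-leaf leaf_samples (block_index 0)")
    df <- data.frame(leaf_id = vapply(samples, `[[`, "", "leaf_id"),
                     label = vapply(samples, `[[`, 1L, "label"))
  }
  df <- unique(df)
  assert_that(!anyDuplicated(df$leaf_id),
              "a leaf_id appears with two different labels")
  folds <- list(train = character(), validation = character(),
                test = character())
  with_seed(seed, {
    for (cl in sort(unique(df$label))) {
      ids <- df$leaf_id[df$label == cl]
      n <- length(ids)
      assert_that(n >= 5, "class %d has only %d leaves (< 5)", cl, n)
      ids <- sample(ids)
      n_tr <- round(ratios[1] * n)
      n_va <- round(ratios[2] * n)
      if (n_tr + n_va >= n) n_va <- n - n_tr - 1L
      folds$train <- c(folds$train, ids[seq_len(n_tr)])
      folds$validation <- c(folds$validation, ids[n_tr + seq_len(n_va)])
      folds$test <- c(folds$test, ids[(n_tr + n_va + 1L):n])
    }
  })
  structure(c(folds, list(seed = seed)), class = "dataset_partition")
}

#' @export
print.dataset_partition <- function(x, ...) {
  cat(sprintf("<dataset_partition> %d train / %d validation / %d test leaves (seed %s)\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}

# The six spatial symmetries used for augmentation, acting on H x W x B
# arrays (spectral axis untouched).
augment_ops <- list(
  hflip = function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE],
  vflip = function(a) a[, rev(seq_len(dim(a)[2])), , drop = FALSE],
  rot90 = function(a) aperm(a, c(2, 1, 3))[rev(seq_len(dim(a)[2])), , ,
                                           drop = FALSE],
  rot180 = function(a) a[rev(seq_len(dim(a)[1])), rev(seq_len(dim(a)[2])), ,
                         drop = FALSE],
  rot270 = function(a) aperm(a, c(2, 1, 3))[, rev(seq_len(dim(a)[1])), ,
                                            drop = FALSE],
  transpose = function(a) aperm(a, c(2, 1, 3)))

apply_augment <- function(sample, op_name) {
  f <- augment_ops[[op_name]]
  arr <- f(sample$cube$data)
  msk_arr <- f(array(sample$mask, c(dim(sample$mask), 1L)))[, , 1]
  leaf_sample(hyper_cube(arr, sample$cube$wavelength, sample$cube$interleave),
              msk_arr, sample$label, sample$leaf_id, sample$block_index)
}

#' Offline augmentation to a per-class target count
#'
#' Expands each class to (at least) `per_class_target` samples by applying
#' symmetries drawn uniformly from {horizontal flip, vertical flip, rotate
#' 90/180/270, transpose-mirror} to randomly chosen source images (sampling
#' with replacement). Spatial dimensions only; the spectral axis and the
#' per-image value histogram are untouched. Originals are always retained.
#'
#' @param samples list of padded square [leaf_sample()]s.
#' @param per_class_target target sample count per class (default 2000).
#' @param seed integer seed.
#' @return List of `leaf_sample`s (originals first, then augmented copies).
#' @export
augment_set <- function(samples, per_class_target = 2000L, seed = 1L) {
  labels <- vapply(samples, `[[`, 1L, "label")
  out <- samples
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      need <- per_class_target - length(idx)
      if (need <= 0) next
      src <- idx[sample.int(length(idx), need, replace = TRUE)]
      ops <- sample(names(augment_ops), need, replace = TRUE)
      out <- c(out, Map(function(i, op) apply_augment(samples[[i]], op),
                        src, ops))
    }
  })
  out
}
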