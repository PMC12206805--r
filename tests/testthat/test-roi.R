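
test_that("Otsu threshold equals the exhaustive-search oracle", {
  # perfect bimodality: threshold strictly between the two levels
  img <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
  thr <- otsu_threshold(img)
  expect_gt(thr, 0.1)
  expect_lt(thr, 0.9)

  withr::with_seed(7, {
    for (rep in 1:25) {
      img <- matrix(runif(64), 8, 8)
      expect_equal(otsu_threshold(img), otsu_oracle(as.vector(img)),
                   tolerance = 1e-12)
    }
  })
  expect_error(otsu_threshold(matrix(0.3, 5, 5)), "degenerate")
})

test_that("leaf segmentation keeps the largest bright component", {
  # band at 800 nm is the indicator of a square -> mask is that square
  arr <- array(0, c(40, 40, 3))
  arr[10:30, 12:28, 2] <- 1
  cube <- hyper_cube(arr + 0.01, c(700, 800, 900))
  m <- segment_leaf(cube)
  truth <- matrix(0L, 40, 40); truth[10:30, 12:28] <- 1L
  expect_identical(m, truth)

  # two blobs, one much larger: only the larger is retained
  arr2 <- array(0.01, c(60, 60, 1))
  arr2[5:40, 5:40, 1] <- 1     # large
  arr2[50:52, 50:52, 1] <- 1   # small
  cube2 <- hyper_cube(arr2, 800)
  m2 <- segment_leaf(cube2)
  expect_identical(sum(m2[50:52, 50:52]), 0L)
  expect_identical(sum(m2), 36L * 36L)
})

test_that("segmentation recovers simulated ground-truth masks", {
  cfg <- sim_config(wavelength = seq(400, 1000, length.out = 12),
                    size = 128L)
  withr::with_seed(21, {
    for (s in sample.int(10000, 10)) {
      sm <- simulate_leaf(sample(1:6, 1), cfg, seed = s)
      m <- segment_leaf(sm$cube)
      jac <- sum(m & sm$mask) / sum(m | sm$mask)
      expect_gte(jac, 0.95)
    }
  })
})

test_that("mean spectrum extraction is the arithmetic mean over the mask", {
  cube <- tiny_cube(3, 3, 2, seed = 5)
  # single pixel
  m1 <- matrix(0L, 3, 3); m1[2, 3] <- 1L
  expect_equal(as.numeric(extract_mean_spectrum(cube, m1)),
               cube$data[2, 3, ])
  # constant cube
  const <- hyper_cube(array(0.37, c(3, 3, 2)), cube$wavelength)
  expect_equal(as.numeric(extract_mean_spectrum(const, matrix(1L, 3, 3))),
               c(0.37, 0.37))
  # brute-force hand sum over the full mask
  oracle <- sapply(1:2, function(b) sum(cube$data[, , b]) / 9)
  expect_equal(as.numeric(extract_mean_spectrum(cube, matrix(1L, 3, 3))),
               oracle)
  expect_error(extract_mean_spectrum(cube, matrix(0L, 3, 3)), "empty")
})

test_that("sub-block windows follow the stated geometry", {
  # L = 100, k = 2, overlap 0.25: windows of length 58, shared 16
  w <- hyperleaf:::subblock_windows(100, 2, 0.25)
  expect_identical(w$length, 58)
  shared <- w$starts[1] + w$length - w$starts[2]
  expect_equal(shared, 16)
  expect_lt(shared / w$length, 0.30)

  # property: pairwise overlap < 0.30 and full coverage for all L, k
  for (L in seq(50, 300, by = 13)) {
    for (k in 2:4) {
      w <- hyperleaf:::subblock_windows(L, k, 0.25)
      starts <- w$starts; Lw <- w$length
      covered <- rep(FALSE, L)
      for (s in starts) covered[(s + 1):min(s + Lw, L)] <- TRUE
      expect_true(all(covered), label = sprintf("coverage L=%d k=%d", L, k))
      for (i in seq_len(k - 1)) {
        ov <- max(0, starts[i] + Lw - starts[i + 1]) / Lw
        expect_lt(ov, 0.30)
      }
    }
  }
})

test_that("split_subblocks crops along the long axis with provenance", {
  leaf <- rect_leaf(h = 120, w = 40, r0 = 11, r1 = 110, c0 = 6, c1 = 35)
  subs <- split_subblocks(leaf, k = 2)
  expect_length(subs, 2)
  expect_identical(vapply(subs, `[[`, 0L, "block_index"), 1:2)
  expect_identical(unique(vapply(subs, `[[`, "", "leaf_id")), "L1")
  expect_identical(dim(subs[[1]]$mask)[1], 58L)  # window length for L = 100
  expect_error(split_subblocks(leaf, k = 5), "k must be")
  expect_identical(choose_k_subblocks(leaf), 2L)
  expect_identical(choose_k_subblocks(rect_leaf(h = 260, w = 40, r0 = 4,
                                                r1 = 258)), 4L)
})

test_that("zero-centred padding centres, preserves mass, and rescales", {
  leaf <- rect_leaf(h = 30, w = 30, b = 2, r0 = 11, r1 = 20, c0 = 11,
                    c1 = 20)
  padded <- pad_center(leaf, size = 112)
  expect_identical(dim(padded$cube$data)[1:2], c(112L, 112L))
  nz <- which(padded$cube$data[, , 1] != 0, arr.ind = TRUE)
  expect_identical(range(nz[, 1]), c(52L, 61L))  # centred 10-px block
  expect_identical(range(nz[, 2]), c(52L, 61L))
  # padding adds zeros: per-band sum preserved when no rescale occurs
  expect_equal(sum(padded$cube$data[, , 1]),
               sum(leaf$cube$data[, , 1] * leaf$mask))

  big <- rect_leaf(h = 200, w = 50, b = 2, r0 = 1, r1 = 200, c0 = 1,
                   c1 = 50)
  shrunk <- pad_center(big, size = 112)
  nz <- which(shrunk$mask == 1L, arr.ind = TRUE)
  expect_identical(diff(range(nz[, 1])) + 1L, 112L)  # 200 -> 112
  expect_identical(diff(range(nz[, 2])) + 1L, 28L)   # 50 -> 28, aspect kept
})

test_that("leaf-level partition is stratified, seeded and leak-free", {
  counts <- c(90L, 90L, 79L, 81L, 90L, 92L)
  df <- data.frame(leaf_id = sprintf("leaf_%03d", seq_len(sum(counts))),
                   label = rep(1:6, times = counts))
  part <- partition_dataset(df, seed = 7)
  expect_identical(sort(c(part$train, part$validation, part$test)),
                   sort(df$leaf_id))
  expect_length(intersect(part$train, part$test), 0)
  expect_length(intersect(part$train, part$validation), 0)
  for (cl in 1:6) {
    ids <- df$leaf_id[df$label == cl]
    n <- length(ids)
    expect_lte(abs(sum(part$train %in% ids) - 0.6 * n), 1)
    expect_lte(abs(sum(part$validation %in% ids) - 0.2 * n), 1)
    expect_lte(abs(sum(part$test %in% ids) - 0.2 * n), 1)
  }
  expect_identical(partition_dataset(df, seed = 7), part)  # determinism
  expect_false(identical(partition_dataset(df, seed = 8)$train, part$train))
  tiny <- data.frame(leaf_id = letters[1:10],
                     label = c(rep(1, 7), rep(2, 3)))
  expect_error(partition_dataset(tiny), "only .* leaves|< 5|has only")
})

test_that("augmentation is count-exact and spectrum-preserving", {
  leaves <- lapply(1:3, function(i)
    pad_center(rect_leaf(h = 30, w = 24, b = 3, r0 = 6, r1 = 25, c0 = 4,
                         c1 = 21, label = (i %% 2) + 1,
                         leaf_id = paste0("L", i)), size = 48))
  # make contents distinctive
  for (i in seq_along(leaves))
    leaves[[i]]$cube$data <- leaves[[i]]$cube$data *
      array(runif(length(leaves[[i]]$cube$data)), dim(leaves[[i]]$cube$data))

  aug <- augment_set(leaves, per_class_target = 10, seed = 3)
  labs <- vapply(aug, `[[`, 0L, "label")
  expect_identical(as.integer(table(labs)), c(10L, 10L))
  expect_identical(aug[seq_along(leaves)], leaves)  # originals retained

  # spatial symmetries preserve each band's sum and the value histogram
  src_ids <- vapply(aug, `[[`, "", "leaf_id")
  for (j in (length(leaves) + 1):length(aug)) {
    parent <- leaves[[match(src_ids[j], vapply(leaves, `[[`, "", "leaf_id"))]]
    for (b in 1:3)
      expect_equal(sum(aug[[j]]$cube$data[, , b]),
                   sum(parent$cube$data[, , b]))
    expect_equal(sort(as.vector(aug[[j]]$cube$data)),
                 sort(as.vector(parent$cube$data)))
    expect_identical(dim(aug[[j]]$cube$data)[3], 3L)  # spectral axis intact
  }

  # rotating by 90 degrees four times is the identity
  ops <- hyperleaf:::augment_ops
  a <- leaves[[1]]$cube$data
  expect_identical(ops$rot90(ops$rot90(ops$rot90(ops$rot90(a)))), a)
})
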