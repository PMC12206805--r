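# Shared fixture builders. Everything is generated in code at test time.

# Small random cube with a float32-representable payload (so ENVI
# round-trips are bit-exact) and a 4-decimal-exact wavelength axis.
tiny_cube <- function(h = 4, w = 5, b = 3, seed = 1) {
  withr::with_seed(seed, {
    vals <- round(runif(h * w * b), 4)
  })
  # push through float32 once so the values are exactly representable
  tmp <- tempfile()
  con <- file(tmp, "wb")
  writeBin(vals, con, size = 4L, endian = "little")
  close(con)
  con <- file(tmp, "rb")
  vals <- readBin(con, "numeric", n = h * w * b, size = 4L,
                  endian = "little")
  close(con)
  unlink(tmp)
  hyper_cube(array(vals, c(h, w, b)),
             seq(450, 450 + 50 * (b - 1), by = 50))
}

# Whole-leaf sample with a rectangular mask, for geometry tests.
rect_leaf <- function(h = 60, w = 40, b = 4, r0 = 11, r1 = 50, c0 = 6,
                      c1 = 35, label = 1, leaf_id = "L1") {
  mask <- matrix(0L, h, w)
  mask[r0:r1, c0:c1] <- 1L
  arr <- array(0.5, c(h, w, b))
  leaf_sample(hyper_cube(arr, seq(500, 500 + 10 * (b - 1), by = 10)),
              mask, label, leaf_id)
}

# Separable spectra tables (train/val/test) from the default simulator.
separable_tables <- function(n_per_class = 50, seed = 3, preprocess = snv) {
  tab <- preprocess(simulate_spectra(n_per_class, sim_config(), seed = seed))
  n <- length(tab$y)
  withr::with_seed(seed + 1000, {
    tr <- va <- te <- integer(0)
    for (cl in sort(unique(tab$y))) {
      i <- sample(which(tab$y == cl))
      k <- length(i)
      n_tr <- round(0.6 * k); n_va <- round(0.2 * k)
      tr <- c(tr, i[seq_len(n_tr)])
      va <- c(va, i[n_tr + seq_len(n_va)])
      te <- c(te, i[(n_tr + n_va + 1):k])
    }
  })
  st <- function(i) spectra_table(tab$X[i, ], tab$wavelength, tab$y[i])
  list(train = st(tr), val = st(va), test = st(te), full = tab)
}

# CNN image set on a b-band axis: list(x = list of (1,b,s,s) arrays, y).
cnn_image_set <- function(n_per_class, n_bands = 15, seed = 1) {
  cfg <- sim_config(wavelength = seq(400, 1000, length.out = n_bands),
                    size = 112L)
  seeds <- withr::with_seed(seed, sample.int(2^30, 6 * n_per_class))
  y <- rep(1:6, each = n_per_class)
  x <- lapply(seq_along(y), function(i) {
    as_cnn_input(simulate_leaf(y[i], cfg, seed = seeds[i]), dim3 = TRUE)
  })
  list(x = x, y = y)
}

# Same scenes, kept as H x W x B cubes (repeat_experiment re-layouts them).
cnn_scene_set <- function(n_per_class, n_bands = 15, seed = 1) {
  cfg <- sim_config(wavelength = seq(400, 1000, length.out = n_bands),
                    size = 112L)
  seeds <- withr::with_seed(seed, sample.int(2^30, 6 * n_per_class))
  y <- rep(1:6, each = n_per_class)
  x <- lapply(seq_along(y), function(i)
    simulate_leaf(y[i], cfg, seed = seeds[i])$cube$data)
  list(x = x, y = y)
}
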