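#' Class spectral profiles for the leaf simulator
#'
#' Six classes mirror a composite-disease design on lemon leaves: healthy,
#' virus-infected only, nitrogen-deficient, nitrogen-deficient + virus,
#' pesticide-damaged, and pesticide-damaged + virus. Each class perturbs a
#' common green-leaf reflectance template in two windows: an additive
#' `visible_offset` on 500-680 nm (chlorophyll absorption region: stressed
#' leaves with less chlorophyll reflect more there) and an additive
#' `nir_offset` on 750-1000 nm (virus-infected tissue reflects less on the
#' NIR plateau). Optional narrow Gaussian `bumps` allow planting localised
#' informative bands for selector-recovery experiments.
#'
#' The default offsets keep the two stated contrasts — classes 1-2 lowest in
#' the visible, virus-bearing classes (2, 4, 6) depressed in the NIR — while
#' giving all six classes pairwise-distinct templates so that the default
#' configuration is fully separable.
#'
#' @param visible_offset numeric length 6, added reflectance on 500-680 nm.
#' @param nir_offset numeric length 6, added reflectance on 750-1000 nm.
#' @param jitter_sd per-pixel Gaussian noise sd (length 1 or 6).
#' @param bumps optional list of 6 data frames with columns `center`, `amp`,
#'   `sd` (nm / reflectance / nm) of planted Gaussian features, or `NULL`.
#' @return A list of 6 class profiles (class `class_profiles`).
#' @export
class_profiles <- function(visible_offset = c(0, 0, 0.04, 0.05, 0.065, 0.075),
                           nir_offset = c(0, -0.06, 0, -0.06, 0, -0.06),
                           jitter_sd = 0.02,
                           bumps = NULL) {
  assert_that(length(visible_offset) == 6 && length(nir_offset) == 6,
              "offsets must have length 6")
  jitter_sd <- rep_len(jitter_sd, 6)
  profs <- lapply(1:6, function(k) {
    list(class_id = k, visible_offset = visible_offset[k],
         nir_offset = nir_offset[k], jitter_sd = jitter_sd[k],
         bumps = if (is.null(bumps)) NULL else bumps[[k]])
  })
  structure(profs, class = "class_profiles")
}

# Baseline green-leaf reflectance: low blue, green peak near 550 nm,
# chlorophyll trough near 680 nm, logistic red edge 680-750 nm, NIR plateau.
baseline_reflectance <- function(wavelength) {
  s <- 1 / (1 + exp(-(wavelength - 715) / 12))       # red edge
  vis <- 0.05 + 0.10 * exp(-(wavelength - 550)^2 / (2 * 32^2)) +
    0.01 * exp(-(wavelength - 450)^2 / (2 * 60^2))
  vis * (1 - s) + 0.48 * s
}

# Smooth indicator of [lo, hi] with raised-cosine edges of half-width `w` nm.
smooth_window <- function(wavelength, lo, hi, w = 15) {
  rise <- function(x) ifelse(x <= -w, 0, ifelse(x >= w, 1,
                                                0.5 * (1 + sin(pi * x / (2 * w)))))
  rise(wavelength - lo) * rise(hi - wavelength)
}

#' Class template reflectance spectrum
#'
#' Builds the noiseless template for one class: the baseline green-leaf
#' curve plus the class's smoothly windowed visible (500-680 nm) and NIR
#' (750-1000 nm) offsets and any planted Gaussian bumps.
#'
#' @param class_id class id 1..6.
#' @param wavelength wavelength axis (nm).
#' @param profiles a [class_profiles()] list.
#' @return Numeric template spectrum in `[0, 1]` (errors otherwise).
#' @export
class_reflectance <- function(class_id, wavelength,
                              profiles = class_profiles()) {
  wavelength <- validate_axis(wavelength)
  p <- profiles[[class_id]]
  r <- baseline_reflectance(wavelength) +
    p$visible_offset * smooth_window(wavelength, 500, 680) +
    p$nir_offset * smooth_window(wavelength, 750, 1000)
  if (!is.null(p$bumps)) {
    for (i in seq_len(nrow(p$bumps)))
      r <- r + p$bumps$amp[i] *
        exp(-(wavelength - p$bumps$center[i])^2 / (2 * p$bumps$sd[i]^2))
  }
  assert_that(all(r >= 0 & r <= 1),
              "class %d template leaves [0, 1]; shrink the offsets", class_id)
  r
}

#' Simulator configuration
#'
#' @param wavelength wavelength axis; default 761 uniform points on
#'   400-1000 nm (the working axis). Use
#'   `seq(305, 1090, length.out = 995)` for a full-sensor axis.
#' @param size image side length in pixels (square scenes).
#' @param counts per-class leaf counts; the default 90/90/79/81/90/92
#'   totals 522 leaves.
#' @param profiles a [class_profiles()] list.
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(wavelength = seq(400, 1000, length.out = 761),
                       size = 160L,
                       counts = c(90L, 90L, 79L, 81L, 90L, 92L),
                       profiles = class_profiles(),
                       seed = 1L) {
  assert_that(length(counts) == 6 && all(counts >= 1),
              "counts must be 6 positive integers")
  structure(list(wavelength = validate_axis(wavelength),
                 size = as.integer(size), counts = as.integer(counts),
                 profiles = profiles, seed = as.integer(seed)),
            class = "sim_config")
}

# Smooth multiplicative brightness field (+/- 10%), mean 1 over the mask.
brightness_field <- function(h, w, mask) {
  gx <- matrix(seq(0, 1, length.out = h), h, w)
  gy <- matrix(seq(0, 1, length.out = w), h, w, byrow = TRUE)
  f <- 0
  for (i in 1:3) {
    fr <- runif(2, 0.5, 2.5); ph <- runif(2, 0, 2 * pi)
    f <- f + sin(2 * pi * fr[1] * gx + ph[1]) * cos(2 * pi * fr[2] * gy + ph[2])
  }
  f <- f / max(abs(f)) * 0.10
  field <- 1 + f
  field / mean(field[mask > 0])
}

#' Simulate one hyperspectral leaf scene
#'
#' Draws an elliptical leaf (random axis ratio 1.4-2.6, random orientation,
#' sinusoidal boundary perturbation) on a dark background (reflectance
#' ~0.02 plus noise). Foreground spectra are the class template modulated by
#' a smooth spatial brightness field (+/- 10%, mean 1 over the leaf) with
#' per-pixel Gaussian jitter. The ground-truth mask is returned with the
#' sample.
#'
#' @param class_id class id 1..6.
#' @param config a [sim_config()].
#' @param seed integer seed for this leaf.
#' @param leaf_id identifier stored in the sample.
#' @return A [leaf_sample()] whose `mask` is the ground truth.
#' @export
simulate_leaf <- function(class_id, config = sim_config(), seed = 1L,
                          leaf_id = sprintf("leaf_%d_%d", class_id, seed)) {
  sz <- config$size
  assert_that(sz >= 64, "size must be >= 64")
  wl <- config$wavelength
  template <- class_reflectance(class_id, wl, config$profiles)
  jitter_sd <- config$profiles[[class_id]]$jitter_sd
  with_seed(seed, {
    # Elliptical mask with wavy boundary.
    cx <- sz / 2 + runif(1, -sz * 0.05, sz * 0.05)
    cy <- sz / 2 + runif(1, -sz * 0.05, sz * 0.05)
    a <- sz * runif(1, 0.30, 0.42)            # semi-major (pixels)
    ratio <- runif(1, 1.4, 2.6)
    b <- a / ratio
    th <- runif(1, 0, pi)
    n_wave <- sample(3:6, 1); w_amp <- runif(1, 0.02, 0.06)
    w_ph <- runif(1, 0, 2 * pi)
    xs <- matrix(seq_len(sz) - cx, sz, sz)
    ys <- matrix(seq_len(sz) - cy, sz, sz, byrow = TRUE)
    u <- xs * cos(th) + ys * sin(th)
    v <- -xs * sin(th) + ys * cos(th)
    ang <- atan2(v / b, u / a)
    rr <- (u / a)^2 + (v / b)^2
    mask <- (rr <= (1 + w_amp * sin(n_wave * ang + w_ph))^2) * 1L
    storage.mode(mask) <- "integer"

    field <- brightness_field(sz, sz, mask)
    B <- length(wl)
    # foreground: template x field + jitter; background: 0.02 + noise
    arr <- array(rnorm(sz * sz * B, 0, jitter_sd), c(sz, sz, B))
    fg <- as.vector(mask) > 0
    base_fg <- outer(as.vector(field)[fg], template)     # n_fg x B
    flat <- matrix(arr, sz * sz, B)
    flat[fg, ] <- flat[fg, ] + base_fg
    flat[!fg, ] <- flat[!fg, ] * 0.25 + 0.02
    flat[flat < 0] <- 0
    arr <- array(flat, c(sz, sz, B))
  })
  leaf_sample(hyper_cube(arr, wl), mask, class_id, leaf_id)
}

#' Simulate a full leaf dataset
#'
#' Honours the per-class counts of the configuration and returns the
#' samples (each carrying its ground-truth mask and label) together with
#' the generator's discriminative-band ground truth.
#'
#' @param config a [sim_config()].
#' @return List with `samples` (list of [leaf_sample()]),
#'   `labels` (integer vector) and `discriminative` (see
#'   [discriminative_bands()]).
#' @export
simulate_dataset <- function(config = sim_config()) {
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max %/% 2,
                                sum(config$counts)))
  labels <- rep(1:6, times = config$counts)
  samples <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    samples[[i]] <- simulate_leaf(labels[i], config, seed = seeds[i],
                                  leaf_id = sprintf("leaf_%03d", i))
  }
  list(samples = samples, labels = labels,
       discriminative = discriminative_bands(config))
}

#' Simulate mean spectra directly (no imaging)
#'
#' Fast generator of an `n x p` spectra table mimicking leaf-level mean
#' spectra: class template, multiplicative scatter (sd 3%), additive
#' baseline shift (sd 0.005) and band-wise noise (sd 0.003). This is the
#' natural fixture for the chemometric selectors and classifiers, which
#' operate on mean spectra.
#'
#' @param n_per_class leaves per class (length 1 or 6).
#' @param config a [sim_config()] (its axis and profiles are used).
#' @param seed integer seed.
#' @return A [spectra_table()].
#' @export
simulate_spectra <- function(n_per_class = 50L, config = sim_config(),
                             seed = 1L) {
  n_per_class <- rep_len(as.integer(n_per_class), 6)
  wl <- config$wavelength
  p <- length(wl)
  y <- rep(1:6, times = n_per_class)
  n <- length(y)
  templates <- vapply(1:6, class_reflectance, numeric(p),
                      wavelength = wl, profiles = config$profiles)
  X <- with_seed(seed, {
    mult <- rnorm(n, 1, 0.03)
    add <- rnorm(n, 0, 0.005)
    t(vapply(seq_len(n), function(i)
      mult[i] * templates[, y[i]] + add[i] + rnorm(p, 0, 0.003),
      numeric(p)))
  })
  spectra_table(X, wl, y)
}

#' Ground-truth discriminative wavelength windows
#'
#' Scans the class templates and reports maximal wavelength intervals on
#' which at least two class templates differ by more than `tol`
#' reflectance. With the default profiles these are (sub-windows of) the
#' 500-680 nm and 750-1000 nm offset windows; with all offsets zero the set
#' is empty.
#'
#' @param config a [sim_config()].
#' @param tol template difference threshold (reflectance units).
#' @return Tibble with columns `lo_nm`, `hi_nm`.
#' @export
discriminative_bands <- function(config = sim_config(), tol = 0.01) {
  wl <- config$wavelength
  templates <- vapply(1:6, class_reflectance, numeric(length(wl)),
                      wavelength = wl, profiles = config$profiles)
  spread <- apply(templates, 1, function(r) max(r) - min(r))
  disc <- spread > tol
  if (!any(disc)) return(tibble::tibble(lo_nm = numeric(), hi_nm = numeric()))
  r <- rle(disc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble::tibble(lo_nm = wl[starts[keep]], hi_nm = wl[ends[keep]])
}

#' Fraction of selected wavelengths inside ground-truth windows
#'
#' Scores a selector's output against the simulator's discriminative
#' windows: the fraction of selected wavelengths lying within `slack_nm` of
#' some window.
#'
#' @param selected_nm numeric vector of selected wavelengths (nm).
#' @param windows tibble from [discriminative_bands()].
#' @param slack_nm tolerance in nm (default 0).
#' @return Fraction in `[0, 1]`.
#' @export
selection_recovery <- function(selected_nm, windows, slack_nm = 0) {
  if (length(selected_nm) == 0) return(NA_real_)
  hit <- vapply(selected_nm, function(l)
    any(l >= windows$lo_nm - slack_nm & l <= windows$hi_nm + slack_nm), TRUE)
  mean(hit)
}

#' Planted-band class profiles
#'
#' Profiles whose only class signal is a set of narrow Gaussian bumps at
#' shared planted centres with class-dependent amplitudes (the broad
#' visible/NIR offsets are zero). This is the ground-truth fixture for
#' wavelength-selection recovery experiments: a selector should place its
#' picks within a few nm of the planted centres, because no other band
#' carries class information.
#'
#' Amplitudes follow a fixed 6 x n_bands design, `0.045 * ((k * j) mod 11
#' - 5) / 5` for class `k` and bump `j`, which gives every class a
#' distinct, non-degenerate signature at every planted band.
#'
#' @param centers planted band centres in nm (default: five in the
#'   chlorophyll window, five on the NIR plateau).
#' @param sd_nm Gaussian width of each bump (nm).
#' @param jitter_sd per-pixel noise sd (as in [class_profiles()]).
#' @return A [class_profiles()] list with `bumps` set.
#' @export
planted_profiles <- function(centers = c(520, 555, 590, 620, 660,
                                         780, 830, 880, 940, 980),
                             sd_nm = 5, jitter_sd = 0.02) {
  bumps <- lapply(1:6, function(k) {
    data.frame(center = centers,
               amp = 0.045 * (((k * seq_along(centers)) %% 11) - 5) / 5,
               sd = sd_nm)
  })
  class_profiles(visible_offset = rep(0, 6), nir_offset = rep(0, 6),
                 jitter_sd = jitter_sd, bumps = bumps)
}
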