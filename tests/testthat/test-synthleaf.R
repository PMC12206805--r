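test_that("class templates encode the stated disease contrasts", {
  wl <- seq(400, 1000, length.out = 761)
  profs <- class_profiles()
  tpl <- vapply(1:6, class_reflectance, numeric(761), wavelength = wl,
                profiles = profs)
  expect_true(all(tpl >= 0 & tpl <= 1))

  vis <- wl >= 510 & wl <= 670   # interior of the chlorophyll window
  nir <- wl >= 760 & wl <= 990   # interior of the NIR plateau window
  # nitrogen-deficient (3) reflects more than healthy (1) in the visible
  d31 <- tpl[, 3] - tpl[, 1]
  expect_true(all(d31[vis] > 0))
  expect_lt(max(abs(d31[nir])), 1e-6)
  # healthy (1) reflects more than virus-infected (2) on the NIR plateau
  d12 <- tpl[, 1] - tpl[, 2]
  expect_lt(max(abs(d12[vis])), 1e-6)
  expect_true(all(d12[nir] > 0))
  # all six templates pairwise distinct somewhere
  for (a in 1:5) for (b in (a + 1):6)
    expect_gt(max(abs(tpl[, a] - tpl[, b])), 0.01)
})

test_that("simulated leaves honour the generator contract", {
  cfg <- sim_config(wavelength = seq(400, 1000, length.out = 30),
                    size = 96L)
  sm <- simulate_leaf(4, cfg, seed = 77)
  tpl <- class_reflectance(4, cfg$wavelength, cfg$profiles)

  # mean spectrum over the true mask within 0.02 of the template per band
  ms <- extract_mean_spectrum(sm$cube, sm$mask)
  expect_lt(max(abs(as.numeric(ms) - tpl)), 0.02)

  # Otsu separability at 800 nm: dark background, bright leaf
  b800 <- sm$cube$data[, , band_index(sm$cube, 800)]
  expect_lt(mean(b800[sm$mask == 0]), 0.1)
  expect_gt(mean(b800[sm$mask == 1]), 0.1)

  # same seed, same cube; different seed differs
  sm2 <- simulate_leaf(4, cfg, seed = 77)
  expect_identical(sm$cube$data, sm2$cube$data)
  sm3 <- simulate_leaf(4, cfg, seed = 78)
  expect_false(identical(sm$cube$data, sm3$cube$data))
})

test_that("dataset simulation honours per-class counts and labels", {
  cfg <- sim_config(wavelength = seq(400, 1000, length.out = 8),
                    size = 64L)
  ds <- simulate_dataset(cfg)
  expect_length(ds$samples, 522)
  expect_identical(as.integer(table(ds$labels)),
                   c(90L, 90L, 79L, 81L, 90L, 92L))
  expect_true(all(ds$labels %in% 1:6))
  expect_identical(vapply(ds$samples, `[[`, 0L, "label"), ds$labels)

  # class histogram invariant under a seed change
  cfg2 <- cfg; cfg2$seed <- 99L
  ds2 <- simulate_dataset(cfg2)
  expect_identical(table(ds2$labels), table(ds$labels))
})

test_that("discriminative windows match brute-force template comparison", {
  cfg <- sim_config()
  w <- discriminative_bands(cfg, tol = 0.01)
  wl <- cfg$wavelength
  tpl <- vapply(1:6, class_reflectance, numeric(length(wl)),
                wavelength = wl, profiles = cfg$profiles)
  spread <- apply(tpl, 1, function(r) max(r) - min(r))
  in_window <- vapply(wl, function(l)
    any(l >= w$lo_nm & l <= w$hi_nm), TRUE)
  expect_identical(in_window, spread > 0.01)  # exhaustive scan oracle

  # windows confined to the two offset regions; nothing below 500 nm
  expect_true(all(w$lo_nm > 480))
  expect_true(all((w$lo_nm >= 480 & w$hi_nm <= 700) |
                  (w$lo_nm >= 730 & w$hi_nm <= 1000)))

  # all offsets zero -> empty set
  flat <- sim_config(profiles = class_profiles(
    visible_offset = rep(0, 6), nir_offset = rep(0, 6)))
  expect_identical(nrow(discriminative_bands(flat)), 0L)
})

test_that("planted profiles concentrate class signal at the bumps", {
  profs <- planted_profiles()
  cfg <- sim_config(profiles = profs)
  w <- discriminative_bands(cfg)
  centers <- profs[[1]]$bumps$center
  expect_identical(nrow(w), length(centers))
  for (ct in centers)
    expect_true(any(ct >= w$lo_nm & ct <= w$hi_nm))
  # away from every bump the templates agree
  wl <- cfg$wavelength
  far <- sapply(wl, function(l) all(abs(l - centers) > 30))
  tpl <- vapply(1:6, class_reflectance, numeric(length(wl)),
                wavelength = wl, profiles = profs)
  spread <- apply(tpl, 1, function(r) max(r) - min(r))
  expect_lt(max(spread[far]), 0.005)
})

test_that("simulated spectra carry scatter that SNV removes", {
  tab <- simulate_spectra(15, sim_config(), seed = 41)
  expect_identical(dim(tab$X), c(90L, 761L))
  expect_identical(as.integer(table(tab$y)), rep(15L, 6))
  s <- snv(tab)
  expect_equal(unname(rowMeans(s$X)), rep(0, 90), tolerance = 1e-10)
})
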