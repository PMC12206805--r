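test_that("reflectance calibration satisfies the defining identities", {
  cube <- tiny_cube(6, 7, 3)
  white <- hyper_cube(cube$data * 0 + 0.9, cube$wavelength)
  dark <- hyper_cube(cube$data * 0 + 0.1, cube$wavelength)

  expect_equal(as.array(calibrate_reflectance(dark, white, dark)),
               array(0, dim(cube)))
  expect_equal(as.array(calibrate_reflectance(white, white, dark)),
               array(1, dim(cube)))
  mid <- hyper_cube((white$data + dark$data) / 2, cube$wavelength)
  expect_equal(as.array(calibrate_reflectance(mid, white, dark)),
               array(0.5, dim(cube)))
})

test_that("calibration is invariant to common affine rescaling", {
  raw <- tiny_cube(5, 5, 4, seed = 2)
  withr::with_seed(3, {
    white <- hyper_cube(raw$data + runif(length(raw$data), 0.5, 1),
                        raw$wavelength)
    dark <- hyper_cube(raw$data * 0 + runif(length(raw$data), 0, 0.05),
                       raw$wavelength)
  })
  base <- calibrate_reflectance(raw, white, dark)
  a <- 3.7; b <- 0.2
  scaled <- calibrate_reflectance(
    hyper_cube(a * raw$data + b, raw$wavelength),
    hyper_cube(a * white$data + b, raw$wavelength),
    hyper_cube(a * dark$data + b, raw$wavelength))
  expect_equal(as.array(scaled), as.array(base), tolerance = 1e-12)
})

test_that("calibration accepts line-profile references and flags degeneracy", {
  raw <- tiny_cube(6, 4, 3)
  d <- dim(raw)
  white_prof <- matrix(0.8, d[2], d[3])
  dark_prof <- matrix(0.05, d[2], d[3])
  out <- calibrate_reflectance(raw, white_prof, dark_prof)
  manual <- (raw$data - 0.05) / 0.75
  expect_equal(as.array(out), manual)

  # a fully degenerate white == dark must error with the fraction named
  expect_error(calibrate_reflectance(raw, dark_prof, dark_prof),
               "ill-posed|degenerate")
  # shape mismatch
  expect_error(calibrate_reflectance(raw, matrix(1, 3, 3), dark_prof),
               "profile|shape")
})

test_that("band_index matches exhaustive nearest-neighbour search", {
  axis761 <- seq(400, 1000, length.out = 761)
  expect_identical(band_index(axis761, 400), 1L)
  expect_identical(band_index(axis761, 800),
                   which.min(abs(axis761 - 800)))
  expect_identical(band_index(axis761, 800), 508L)  # spacing 600/760 nm
  expect_identical(band_index(c(500, 600), 550), 1L)  # tie -> lower index

  withr::with_seed(11, {
    for (rep in 1:20) {
      axis <- sort(runif(sample(5:60, 1), 350, 1050))
      axis <- axis[!duplicated(axis)]
      target <- runif(1, min(axis) - 10, max(axis) + 10)
      oracle <- which.min(abs(axis - target))
      expect_identical(band_index(axis, target), oracle)
    }
  })
  expect_error(band_index(axis761, 1011), "outside")
})

test_that("spectral cropping honours inclusive bounds and idempotence", {
  axis <- seq(305, 1090, length.out = 995)  # full-sensor fixture
  cube <- hyper_cube(array(runif(2 * 2 * 995), c(2, 2, 995)), axis)
  cropped <- crop_spectral(cube, 400, 1000)
  expect_identical(dim(cropped)[3], sum(axis >= 400 & axis <= 1000))

  ident <- crop_spectral(cube, min(axis), max(axis))
  expect_identical(as.array(ident), as.array(cube))

  twice <- crop_spectral(cropped, 400, 1000)
  expect_identical(as.array(twice), as.array(cropped))
  expect_error(crop_spectral(cube, 2000, 2100), "no bands")
})

test_that("ENVI round-trips are bit-exact for both interleaves", {
  cube <- tiny_cube(4, 5, 3)
  for (il in c("BSQ", "BIL")) {
    hdr <- file.path(tempdir(), paste0("cube_", il, ".hdr"))
    write_envi(cube, hdr, interleave = il)
    back <- read_envi(hdr)
    expect_identical(back$data, cube$data)
    expect_identical(back$wavelength, cube$wavelength)
  }
  # both interleaves decode to the same array
  h1 <- file.path(tempdir(), "a.hdr"); h2 <- file.path(tempdir(), "b.hdr")
  write_envi(cube, h1, "BSQ"); write_envi(cube, h2, "BIL")
  expect_identical(read_envi(h1)$data, read_envi(h2)$data)
})

test_that("ENVI writer and parser enforce the declared layout", {
  one <- hyper_cube(array(c(0.5, 0.25), c(1, 1, 2)), c(500, 600))
  hdr <- file.path(tempdir(), "one.hdr")
  paths <- write_envi(one, hdr)
  expect_identical(file.size(paths$payload), 8)  # 2 float32

  # axis length mismatch refuses to write
  bad <- one; bad$wavelength <- c(500, 600, 700)
  expect_error(write_envi(bad, hdr), "refusing")

  # header band count != wavelength list length errors on read
  txt <- readLines(hdr)
  txt <- sub("bands = 2", "bands = 3", txt)
  hdr2 <- file.path(tempdir(), "bad.hdr")
  writeLines(txt, hdr2)
  file.copy(paths$payload, file.path(tempdir(), "bad.img"),
            overwrite = TRUE)
  expect_error(read_envi(hdr2), "wavelength list length|truncated")

  # missing wavelength field
  txt2 <- readLines(hdr)
  txt2 <- txt2[!grepl("^wavelength", txt2)]
  hdr3 <- file.path(tempdir(), "nowl.hdr")
  writeLines(txt2, hdr3)
  file.copy(paths$payload, file.path(tempdir(), "nowl.img"),
            overwrite = TRUE)
  expect_error(read_envi(hdr3), "wavelength")
})
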