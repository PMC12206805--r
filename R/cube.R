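#' Hyperspectral cube container
#'
#' A `hyper_cube` wraps an `H x W x B` reflectance array together with its
#' wavelength axis (band centre wavelengths, nm) and an interleave hint used
#' when the cube is written back to ENVI format. Reflectance is dimensionless
#' and nominally lies in `[0, ~1.2]` after white/dark calibration.
#'
#' @param data numeric `H x W x B` array (rows x columns x bands).
#' @param wavelength numeric vector of band centre wavelengths in nm;
#'   strictly increasing, finite, positive, with length equal to the band
#'   count of `data`.
#' @param interleave storage hint for ENVI output, `"BSQ"` or `"BIL"`.
#' @return An object of class `hyper_cube`.
#' @examples
#' cube <- hyper_cube(array(runif(4 * 5 * 3), c(4, 5, 3)), c(450, 550, 650))
#' dim(cube)
#' @export
hyper_cube <- function(data, wavelength, interleave = c("BSQ", "BIL")) {
  interleave <- toupper(match.arg(toupper(interleave[1]), c("BSQ", "BIL")))
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3-d array (H x W x B)")
  wavelength <- validate_axis(wavelength)
  d <- dim(data)
  assert_that(d[1] >= 1 && d[2] >= 1, "cube must have H >= 1 and W >= 1")
  assert_that(d[3] == length(wavelength),
              "band count (%d) must equal wavelength axis length (%d)",
              d[3], length(wavelength))
  structure(list(data = data, wavelength = wavelength,
                 interleave = interleave),
            class = "hyper_cube")
}

# Wavelength axis validation: strictly increasing, finite, positive.
validate_axis <- function(wavelength) {
  wavelength <- as.numeric(wavelength)
  assert_that(length(wavelength) >= 1, "wavelength axis must be non-empty")
  assert_that(all(is.finite(wavelength)) && all(wavelength > 0),
              "wavelength axis must be finite and positive")
  if (length(wavelength) > 1)
    assert_that(all(diff(wavelength) > 0),
                "wavelength axis must be strictly increasing")
  wavelength
}

#' @export
dim.hyper_cube <- function(x) dim(x$data)

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelength), max(x$wavelength),
              x$interleave))
  invisible(x)
}

#' @export
as.array.hyper_cube <- function(x, ...) x$data

is_cube <- function(x) inherits(x, "hyper_cube")

# Accepts a hyper_cube, a 3-d array, or a W x B line profile (line-scan white
# reference broadcast over image rows); returns an H x W x B array.
as_reference_array <- function(ref, h, w, b, what) {
  if (is_cube(ref)) ref <- ref$data
  if (is.matrix(ref)) {
    assert_that(nrow(ref) == w && ncol(ref) == b,
                "%s profile must be W x B (%d x %d), got %d x %d",
                what, w, b, nrow(ref), ncol(ref))
    return(aperm(array(rep(ref, each = h), c(h, w, b)), c(1, 2, 3)))
  }
  assert_that(is.array(ref) && length(dim(ref)) == 3L,
              "%s must be a cube, 3-d array or W x B profile", what)
  assert_that(all(dim(ref) == c(h, w, b)),
              "%s shape (%s) does not match raw cube (%d x %d x %d)",
              what, paste(dim(ref), collapse = " x "), h, w, b)
  ref
}

#' White/dark reflectance calibration
#'
#' Converts a raw hyperspectral scan to reflectance using a white reference
#' (scan of a diffuse reflectance standard) and a dark reference (lens-closed
#' scan of dark current): `R = (raw - dark) / (white - dark)`, element-wise.
#' Elements with a degenerate denominator (`|white - dark| < eps`) are set to
#' zero; if more than 1% of elements are degenerate the calibration is
#' considered ill-posed and an error is raised.
#'
#' The ratio form makes the result invariant to any common affine rescaling
#' of the three scans (gain/offset of the detector).
#'
#' @param raw `hyper_cube` (or 3-d array) of raw intensity.
#' @param white,dark white and dark references: a `hyper_cube`, a 3-d array
#'   matching `raw`, or a `W x B` per-band line profile broadcast across
#'   image rows (line-scan practice).
#' @param eps degeneracy tolerance on the denominator.
#' @return A `hyper_cube` of reflectance carrying `raw`'s wavelength axis,
#'   with attribute `"n_degenerate"` giving the number of zeroed elements.
#' @export
calibrate_reflectance <- function(raw, white, dark, eps = 1e-6) {
  wl <- NULL
  if (is_cube(raw)) {
    wl <- raw$wavelength
    raw_arr <- raw$data
  } else {
    assert_that(is.array(raw) && length(dim(raw)) == 3L,
                "`raw` must be a hyper_cube or 3-d array")
    raw_arr <- raw
  }
  d <- dim(raw_arr)
  w_arr <- as_reference_array(white, d[1], d[2], d[3], "white")
  d_arr <- as_reference_array(dark,  d[1], d[2], d[3], "dark")

  denom <- w_arr - d_arr
  assert_that(mean(denom > 0) >= 0.99,
              "calibration ill-posed: white > dark on only %.1f%% of elements",
              100 * mean(denom > 0))
  degen <- abs(denom) < eps
  frac <- mean(degen)
  if (frac > 0.01)
    stopf("calibration degenerate on %.2f%% of elements (> 1%% allowed)",
          100 * frac)
  out <- (raw_arr - d_arr) / denom
  if (any(degen)) out[degen] <- 0
  out[!is.finite(out)] <- 0
  if (is.null(wl)) wl <- seq_len(d[3])
  res <- hyper_cube(out, wl,
                    interleave = if (is_cube(raw)) raw$interleave else "BSQ")
  attr(res, "n_degenerate") <- sum(degen)
  res
}

#' Index of the band nearest a target wavelength
#'
#' Returns the 1-based index of the axis value nearest `target_nm`, with ties
#' resolved toward the lower index. Targets more than 10 nm outside the axis
#' range are rejected.
#'
#' @param wavelength wavelength axis (numeric, nm) or a `hyper_cube`.
#' @param target_nm target wavelength in nm.
#' @return Integer band index (1-based).
#' @examples
#' band_index(seq(400, 1000, length.out = 761), 800)
#' @export
band_index <- function(wavelength, target_nm) {
  if (is_cube(wavelength)) wavelength <- wavelength$wavelength
  wavelength <- validate_axis(wavelength)
  assert_that(target_nm >= min(wavelength) - 10 &&
              target_nm <= max(wavelength) + 10,
              "target %.1f nm outside axis range [%.1f, %.1f] +/- 10 nm",
              target_nm, min(wavelength), max(wavelength))
  which.min(abs(wavelength - target_nm))  # which.min takes the first minimum
}

#' Crop a cube or spectra matrix to a wavelength window
#'
#' Retains bands with `lo_nm <= lambda <= hi_nm` (inclusive) and crops the
#' wavelength axis consistently. The sensor's noisy spectral extremes are
#' usually dropped this way before analysis (e.g. keep 400-1000 nm).
#'
#' @param x a `hyper_cube` or an `n x p` spectra matrix with the axis given
#'   via `wavelength`.
#' @param lo_nm,hi_nm window bounds in nm, `lo_nm < hi_nm`.
#' @param wavelength axis for matrix input (ignored for cubes).
#' @return Same kind of object as `x`, spectrally cropped. For matrix input
#'   the cropped axis is attached as attribute `"wavelength"`.
#' @export
crop_spectral <- function(x, lo_nm, hi_nm, wavelength = NULL) {
  assert_that(lo_nm < hi_nm, "need lo_nm < hi_nm")
  if (is_cube(x)) {
    keep <- which(x$wavelength >= lo_nm & x$wavelength <= hi_nm)
    assert_that(length(keep) > 0, "no bands in [%g, %g] nm", lo_nm, hi_nm)
    return(hyper_cube(x$data[, , keep, drop = FALSE], x$wavelength[keep],
                      interleave = x$interleave))
  }
  assert_that(is.matrix(x), "`x` must be a hyper_cube or a matrix")
  wavelength <- validate_axis(wavelength %||% attr(x, "wavelength"))
  assert_that(length(wavelength) == ncol(x),
              "axis length (%d) must match ncol(x) (%d)",
              length(wavelength), ncol(x))
  keep <- which(wavelength >= lo_nm & wavelength <= hi_nm)
  assert_that(length(keep) > 0, "no bands in [%g, %g] nm", lo_nm, hi_nm)
  out <- x[, keep, drop = FALSE]
  attr(out, "wavelength") <- wavelength[keep]
  out
}
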