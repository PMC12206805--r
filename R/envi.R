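#' Read an ENVI-format hyperspectral cube
#'
#' Reads the classic ENVI header/binary pair: a text `.hdr` describing the
#' layout and a headerless little-endian binary payload. Supported layouts
#' are band-sequential (BSQ) and band-interleaved-by-line (BIL), IEEE float32
#' (ENVI data type 4). Header keys are case-insensitive. The header must
#' declare a `wavelength` list whose length equals the band count.
#'
#' @param header_path path to the `.hdr` file; the payload is the same path
#'   without the `.hdr` extension (or with `.dat` appended if that file is
#'   absent).
#' @return A `hyper_cube`.
#' @seealso [write_envi()]
#' @export
read_envi <- function(header_path) {
  assert_that(file.exists(header_path), "header not found: %s", header_path)
  hdr <- parse_envi_header(header_path)
  for (key in c("samples", "lines", "bands", "interleave", "data type"))
    assert_that(!is.null(hdr[[key]]), "ENVI header missing field '%s'", key)
  assert_that(!is.null(hdr[["wavelength"]]),
              "ENVI header missing 'wavelength' field")
  dtype <- as.integer(hdr[["data type"]])
  assert_that(dtype == 4L, "unsupported ENVI data type %d (only 4 = float32)",
              dtype)
  byte_order <- as.integer(hdr[["byte order"]] %||% "0")
  assert_that(byte_order == 0L, "unsupported byte order %d", byte_order)
  interleave <- toupper(trimws(hdr[["interleave"]]))
  assert_that(interleave %in% c("BSQ", "BIL"),
              "unsupported interleave '%s' (bsq or bil only)", interleave)

  w <- as.integer(hdr[["samples"]])  # samples = image columns
  h <- as.integer(hdr[["lines"]])    # lines   = image rows
  b <- as.integer(hdr[["bands"]])
  wl <- as.numeric(strsplit(gsub("[{}]", "", hdr[["wavelength"]]), ",")[[1]])
  assert_that(length(wl) == b,
              "header bands (%d) != wavelength list length (%d)", b,
              length(wl))

  bin_path <- envi_payload_path(header_path, must_exist = TRUE)
  offset <- as.integer(hdr[["header offset"]] %||% "0")
  con <- file(bin_path, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", n = offset)
  n <- as.numeric(w) * h * b
  vals <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  assert_that(length(vals) == n, "payload truncated: expected %d floats, got %d",
              n, length(vals))

  if (interleave == "BSQ") {
    # [band][line][sample], sample fastest -> array dims (W, H, B)
    arr <- aperm(array(vals, c(w, h, b)), c(2, 1, 3))
  } else {
    # BIL: [line][band][sample] -> dims (W, B, H)
    arr <- aperm(array(vals, c(w, b, h)), c(3, 1, 2))
  }
  hyper_cube(arr, wl, interleave = interleave)
}

#' Write a cube as an ENVI header/binary pair
#'
#' Emits a text `.hdr` plus a little-endian float32 binary payload in the
#' cube's interleave (BSQ or BIL). Wavelengths are serialised with four
#' decimals.
#'
#' @param cube a `hyper_cube`.
#' @param header_path output `.hdr` path; the payload drops the extension.
#' @param interleave optional override of the cube's interleave hint.
#' @return Invisibly, a list with the header and payload paths.
#' @export
write_envi <- function(cube, header_path, interleave = NULL) {
  assert_that(is_cube(cube), "`cube` must be a hyper_cube")
  interleave <- toupper(interleave %||% cube$interleave)
  assert_that(interleave %in% c("BSQ", "BIL"),
              "unsupported interleave '%s'", interleave)
  d <- dim(cube$data)
  assert_that(length(cube$wavelength) == d[3],
              "axis length (%d) != band count (%d); refusing to write",
              length(cube$wavelength), d[3])
  dir <- dirname(header_path)
  assert_that(dir.exists(dir), "directory does not exist: %s", dir)

  bin_path <- envi_payload_path(header_path, must_exist = FALSE)
  hdr <- c(
    "ENVI",
    "description = {hyperleaf exported cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    sprintf("interleave = %s", tolower(interleave)),
    "byte order = 0",
    sprintf("wavelength = {%s}",
            paste(sprintf("%.4f", cube$wavelength), collapse = ", ")))
  writeLines(hdr, header_path)

  if (interleave == "BSQ") {
    vals <- as.vector(aperm(cube$data, c(2, 1, 3)))  # sample, line, band
  } else {
    vals <- as.vector(aperm(cube$data, c(2, 3, 1)))  # sample, band, line
  }
  con <- file(bin_path, "wb")
  on.exit(close(con))
  writeBin(vals, con, size = 4L, endian = "little")
  invisible(list(header = header_path, payload = bin_path))
}

envi_payload_path <- function(header_path, must_exist) {
  base <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  if (identical(base, header_path)) base <- paste0(header_path, ".img")
  if (must_exist && !file.exists(base)) {
    alt <- paste0(base, ".dat")
    assert_that(file.exists(alt), "ENVI payload not found: %s", base)
    return(alt)
  }
  base
}

parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  hdr <- list()
  # Fields are `key = value`; brace-delimited values may span lines.
  pos <- 1L
  lines <- strsplit(txt, "\n")[[1]]
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("=", ln, fixed = TRUE)) {
      key <- tolower(trimws(sub("=.*$", "", ln)))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (grepl("\\{", val) && !grepl("\\}", val)) {
        while (i < length(lines) && !grepl("\\}", val)) {
          i <- i + 1L
          val <- paste(val, trimws(lines[i]))
        }
      }
      hdr[[key]] <- val
    }
    i <- i + 1L
  }
  hdr
}
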