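#' Read a grayscale PNG or TIFF image
#'
#' Reads an 8- or 16-bit single-channel raster file and normalizes it to the
#' internal \eqn{[0, 1]} intensity scale (division by \eqn{2^b - 1}).
#' Multi-channel files are accepted only when all color channels carry
#' identical values (a grayscale image saved as RGB), in which case they are
#' collapsed to one channel; an opaque alpha channel is dropped.
#'
#' @param path file path to a `.png`, `.tif` or `.tiff` file.
#' @param expected_format optional; one of `"png"`, `"tiff"`.  Defaults to the
#'   file extension.
#' @return An [us_image()] carrying the file's bit depth.
#' @export
read_image <- function(path, expected_format = NULL) {
  if (!file.exists(path)) {
    usnlm_abort(sprintf("File does not exist: '%s'", path), "io")
  }
  fmt <- tolower(expected_format %||% tools::file_ext(path))
  fmt <- switch(fmt,
    png = "png",
    tif = ,
    tiff = "tiff",
    usnlm_abort(
      sprintf("Unsupported image format '%s' for '%s' (use PNG or TIFF).", fmt, path),
      "format"
    )
  )
  if (fmt == "png") {
    arr <- png::readPNG(path, info = TRUE)
    bitdepth <- attr(arr, "info")$bit.depth %||% 8L
  } else {
    arr <- tiff::readTIFF(path, info = TRUE)
    bitdepth <- attr(arr, "info")$bits.per.sample %||% attr(arr, "bits.per.sample") %||% 8L
  }
  bitdepth <- if (isTRUE(bitdepth >= 16)) 16L else 8L
  px <- collapse_channels(arr, path)
  us_image(px, source_bitdepth = bitdepth)
}

# Collapse an H x W x C array to a single channel, or fail if channels differ.
collapse_channels <- function(arr, path) {
  if (is.matrix(arr)) {
    return(matrix(as.numeric(arr), nrow(arr), ncol(arr)))
  }
  if (length(dim(arr)) != 3L) {
    usnlm_abort(sprintf("Unsupported image layout in '%s'.", path), "format")
  }
  nc <- dim(arr)[3L]
  chans <- lapply(seq_len(nc), function(k) arr[, , k])
  if (nc %in% c(2L, 4L)) {
    alpha <- chans[[nc]]
    if (any(alpha != 1)) {
      usnlm_abort(
        sprintf("Image '%s' has a non-opaque alpha channel.", path),
        "format"
      )
    }
    chans <- chans[-nc]
  }
  first <- chans[[1L]]
  for (ch in chans[-1L]) {
    if (!identical(dim(ch), dim(first)) || any(ch != first)) {
      usnlm_abort(
        sprintf(
          "Image '%s' has %d non-identical channels; cannot collapse to grayscale.",
          path, length(chans)
        ),
        "format"
      )
    }
  }
  first
}

#' Write an ultrasound image to PNG or TIFF
#'
#' Quantizes the \eqn{[0, 1]} pixels to `round(p * (2^bitdepth - 1))`
#' (round-half-up) and writes them losslessly.  Reading the file back with
#' [read_image()] reproduces every pixel to within half a quantization step,
#' \eqn{1 / (2 (2^b - 1))}.  16-bit export uses TIFF; PNG export is 8-bit.
#'
#' @param img an [us_image()] or numeric matrix in \eqn{[0, 1]}.
#' @param path destination `.png`, `.tif` or `.tiff` path.
#' @param bitdepth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bitdepth = 8L) {
  img <- as_us_image(img)
  if (!bitdepth %in% c(8L, 16L)) {
    usnlm_abort("`bitdepth` must be 8 or 16.", "validation")
  }
  fmt <- switch(tolower(tools::file_ext(path)),
    png = "png",
    tif = ,
    tiff = "tiff",
    usnlm_abort(
      sprintf("Unsupported output format for '%s' (use .png/.tif/.tiff).", path),
      "format"
    )
  )
  if (fmt == "png" && bitdepth == 16L) {
    usnlm_abort(
      "16-bit export uses TIFF; write a .tif/.tiff file instead.",
      "format"
    )
  }
  maxval <- 2^bitdepth - 1
  q <- floor(as_pixel_matrix(img) * maxval + 0.5) / maxval
  tryCatch(
    {
      if (fmt == "png") {
        png::writePNG(q, path)
      } else {
        tiff::writeTIFF(q, path,
          bits.per.sample = as.integer(bitdepth),
          compression = "none"
        )
      }
    },
    error = function(e) {
      usnlm_abort(
        sprintf("Could not write '%s': %s", path, conditionMessage(e)),
        "io"
      )
    }
  )
  invisible(path)
}
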