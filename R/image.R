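#' Grayscale ultrasound image
#'
#' An `us_image` is a numeric matrix of pixel intensities on the canonical
#' internal scale \eqn{[0, 1]}, with two pieces of metadata: the bit depth of
#' the file it came from (or is destined for) and an optional, purely
#' annotative physical pixel spacing in mm/pixel.  Rows are image rows
#' (depth), columns are image columns (lateral position).
#'
#' All processing in the package happens on this \eqn{[0, 1]} scale, so that
#' the NLM bandwidth, the speckle model and the CNR/COV statistics are
#' consistent regardless of whether the source file was 8- or 16-bit.
#'
#' @param pixels numeric matrix with values in \eqn{[0, 1]}.
#' @param source_bitdepth 8 or 16; the intensity resolution of the source.
#' @param pixel_spacing optional numeric scalar, mm per pixel (annotative).
#' @return An object of class `us_image` (a classed numeric matrix).
#' @export
#' @examples
#' img <- us_image(matrix(runif(64), 8, 8))
#' dim(img)
us_image <- function(pixels, source_bitdepth = 8L, pixel_spacing = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    usnlm_abort("`pixels` must be a numeric matrix.", "validation")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    usnlm_abort("Image must have height >= 1 and width >= 1.", "validation")
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    usnlm_abort("Image pixels must be finite and non-missing.", "validation")
  }
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9) {
    usnlm_abort(
      sprintf(
        "Pixel values must lie in [0, 1]; observed range [%.4g, %.4g].",
        min(pixels), max(pixels)
      ),
      "validation"
    )
  }
  if (!source_bitdepth %in% c(8L, 16L)) {
    usnlm_abort("`source_bitdepth` must be 8 or 16.", "validation")
  }
  pixels <- clip01(pixels) # shave float fuzz within tolerance
  structure(
    pixels,
    source_bitdepth = as.integer(source_bitdepth),
    pixel_spacing = pixel_spacing,
    class = c("us_image", class(matrix()))
  )
}

#' @export
print.us_image <- function(x, ...) {
  cat(sprintf(
    "<us_image> %d x %d, %d-bit source, range [%.4f, %.4f]\n",
    nrow(x), ncol(x), attr(x, "source_bitdepth") %||% 8L, min(x), max(x)
  ))
  invisible(x)
}

#' Test for / coerce to an ultrasound image
#'
#' `as_us_image()` accepts an `us_image` (returned unchanged) or a plain
#' numeric matrix in \eqn{[0, 1]}.
#'
#' @param x object to test or coerce.
#' @param ... passed to [us_image()] when constructing from a matrix.
#' @export
is_us_image <- function(x) inherits(x, "us_image")

#' @rdname is_us_image
#' @export
as_us_image <- function(x, ...) {
  if (is_us_image(x)) x else us_image(x, ...)
}

# Strip class/attributes down to a plain numeric matrix.
as_pixel_matrix <- function(x) {
  if (is_us_image(x)) {
    matrix(as.numeric(x), nrow(x), ncol(x))
  } else if (is.matrix(x) && is.numeric(x)) {
    x
  } else {
    usnlm_abort("Expected an `us_image` or a numeric matrix.", "validation")
  }
}

# Rebuild an us_image around new pixels, keeping metadata from a template.
rewrap_image <- function(pixels, template) {
  us_image(
    pixels,
    source_bitdepth = attr(template, "source_bitdepth") %||% 8L,
    pixel_spacing = attr(template, "pixel_spacing")
  )
}
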