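#' Sliding-window median filter
#'
#' Classical speckle-reduction comparator: each output pixel is the median of
#' its \eqn{(2r+1)\times(2r+1)} neighborhood, read through reflected padding.
#' The window always holds an odd number of values, so the median is the
#' middle order statistic and no tie-averaging arises.
#'
#' @param img an [us_image()] or numeric matrix in \eqn{[0, 1]}.
#' @param window_radius integer \eqn{\ge 1}.
#' @return A filtered [us_image()].
#' @export
median_filter <- function(img, window_radius = 1L) {
  window_radius <- as.integer(window_radius)
  if (window_radius < 1L) {
    usnlm_abort("`window_radius` must be >= 1.", "validation")
  }
  img <- as_us_image(img)
  out <- median_filter_cpp(as_pixel_matrix(img), window_radius)
  rewrap_image(out, img)
}

#' Local-adaptive (Lee-type) Wiener filter
#'
#' The second classical comparator.  With local window mean \eqn{\mu_i} and
#' variance \eqn{\sigma^2_i} (reflected padding) and noise variance
#' \eqn{\nu}, the output is
#' \deqn{\hat I(i) = \mu_i + \frac{\max(\sigma^2_i - \nu, 0)}
#'   {\max(\sigma^2_i, \nu)} \, (I(i) - \mu_i):}
#' flat regions (\eqn{\sigma^2_i \le \nu}) collapse to the local mean while
#' high-variance (edge) regions pass through.  When `noise_variance` is not
#' supplied it is estimated as the mean of the local variances, the classic
#' adaptive rule.
#'
#' @param img an [us_image()] or numeric matrix in \eqn{[0, 1]}.
#' @param window_radius integer \eqn{\ge 1}.
#' @param noise_variance non-negative scalar, or `NULL` to auto-estimate.
#' @return A filtered [us_image()].
#' @export
wiener_filter <- function(img, window_radius = 1L, noise_variance = NULL) {
  window_radius <- as.integer(window_radius)
  if (window_radius < 1L) {
    usnlm_abort("`window_radius` must be >= 1.", "validation")
  }
  if (!is.null(noise_variance) &&
    (!is.numeric(noise_variance) || length(noise_variance) != 1L ||
      noise_variance < 0)) {
    usnlm_abort("`noise_variance` must be a non-negative scalar.", "validation")
  }
  img <- as_us_image(img)
  x <- as_pixel_matrix(img)
  mu <- box_mean(x, window_radius)
  m2 <- box_mean(x * x, window_radius)
  s2 <- pmax(m2 - mu * mu, 0)
  nu <- noise_variance %||% mean(s2)
  denom <- pmax(s2, nu)
  gain <- ifelse(denom > 0, pmax(s2 - nu, 0) / denom, 0)
  rewrap_image(clip01(mu + gain * (x - mu)), img)
}

#' Residual (method noise) of a denoiser
#'
#' `residual()` is the signed pixelwise difference `noisy - denoised`; for an
#' unbiased denoiser on pure noise it should be structure-free with mean
#' close to zero.  `residual_image()` maps a residual onto \eqn{[0, 1]} for
#' export, centering zero at 0.5 and scaling symmetrically by the largest
#' absolute residual.
#'
#' @param noisy,denoised images of identical dimensions.
#' @param res a residual matrix from `residual()`.
#' @return `residual()`: a plain signed numeric matrix.
#'   `residual_image()`: an [us_image()].
#' @export
residual <- function(noisy, denoised) {
  a <- as_pixel_matrix(noisy)
  b <- as_pixel_matrix(denoised)
  if (!identical(dim(a), dim(b))) {
    usnlm_abort(
      sprintf(
        "Image dimensions differ: %d x %d vs %d x %d.",
        nrow(a), ncol(a), nrow(b), ncol(b)
      ),
      "validation"
    )
  }
  a - b
}

#' @rdname residual
#' @export
residual_image <- function(res) {
  stopifnot(is.matrix(res), is.numeric(res))
  amp <- max(abs(res))
  if (amp == 0) {
    return(us_image(matrix(0.5, nrow(res), ncol(res))))
  }
  us_image(clip01(0.5 + res / (2 * amp)))
}
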