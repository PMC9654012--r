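#' Configure the non-local means denoiser
#'
#' The NLM denoiser replaces each pixel \eqn{i} by a weighted average of the
#' pixels \eqn{j} in its search window \eqn{N_i},
#' \deqn{\hat I(i) = \sum_{j \in N_i} w_{ij} I(j),}
#' with weights that decay exponentially in the dissimilarity of the image
#' patches around \eqn{i} and \eqn{j}:
#' \deqn{w_{ij} = \frac{1}{Z_i} \exp\!\left(-\frac{d_{ij}}{h^2}\right),}
#' where \eqn{d_{ij}} is the mean squared difference between the two
#' \eqn{(2r+1)\times(2r+1)} patches, \eqn{Z_i} normalizes the weights to sum
#' to one, and the bandwidth \eqn{h} is a constant multiple of the noise
#' standard deviation.  Patch distances are normalized by patch pixel count
#' so that `h` has the same meaning at every `patch_radius`.
#'
#' The weight of the center pixel itself is set by `self_weight_rule`:
#' `"max_of_neighbors"` (default, standard practice: prevents the noisy
#' center value from dominating) gives the self the largest raw weight found
#' among its neighbors; `"include"` gives it raw weight \eqn{\exp(0) = 1}.
#'
#' @param patch_radius integer \eqn{\ge 1}; the patch is
#'   \eqn{(2r+1)\times(2r+1)}.  Default 3 (7 x 7 patch).
#' @param search_radius integer \eqn{\ge} `patch_radius`; the search window is
#'   \eqn{(2R+1)\times(2R+1)}.  Default 10 (21 x 21 window).
#' @param h positive smoothing bandwidth on the internal \eqn{[0, 1]}
#'   intensity scale.
#' @param self_weight_rule `"max_of_neighbors"` or `"include"`.
#' @return An object of class `nlm_config`.
#' @seealso [smoothing_preset()] for the low/middle/high presets,
#'   [nlm_denoise()].
#' @export
nlm_config <- function(patch_radius = 3L, search_radius = 10L, h,
                       self_weight_rule = c("max_of_neighbors", "include")) {
  self_weight_rule <- match.arg(self_weight_rule)
  patch_radius <- as.integer(patch_radius)
  search_radius <- as.integer(search_radius)
  if (patch_radius < 1L) {
    usnlm_abort("`patch_radius` must be >= 1.", "validation")
  }
  if (search_radius < patch_radius) {
    usnlm_abort("`search_radius` must be >= `patch_radius`.", "validation")
  }
  if (missing(h) || !is.numeric(h) || length(h) != 1L || h <= 0) {
    usnlm_abort("`h` must be a positive scalar.", "validation")
  }
  structure(
    list(
      patch_radius = patch_radius,
      search_radius = search_radius,
      h = as.numeric(h),
      self_weight_rule = self_weight_rule
    ),
    class = "nlm_config"
  )
}

#' @export
print.nlm_config <- function(x, ...) {
  cat(sprintf(
    "<nlm_config> patch %dx%d, search %dx%d, h = %.5g, self = %s\n",
    2 * x$patch_radius + 1, 2 * x$patch_radius + 1,
    2 * x$search_radius + 1, 2 * x$search_radius + 1,
    x$h, x$self_weight_rule
  ))
  invisible(x)
}

#' Low / middle / high smoothing presets
#'
#' Maps a named smoothing level to an [nlm_config()].  The bandwidth is
#' `h = c * delta / 255` with `c` = 0.4 (low), 0.8 (middle) or 1.2 (high),
#' where `delta` is the noise standard deviation expressed on the 8-bit
#' 0–255 display scale (default 20).  Patch radius 3, search radius 10,
#' self-weight rule `"max_of_neighbors"`.
#'
#' @param level `"low"`, `"middle"` or `"high"`.
#' @param delta noise standard deviation on the 0–255 scale, > 0.  For
#'   simulated speckle a good value is `255 * estimate_noise_sd(noisy)`.
#' @return An [nlm_config()] with extra fields `smoothing_level`, `delta` and
#'   `c` recording how `h` was derived.
#' @export
#' @examples
#' smoothing_preset("middle", delta = 20)$h # 0.8 * 20 / 255
smoothing_preset <- function(level = c("low", "middle", "high"), delta = 20) {
  level <- match.arg(level)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    usnlm_abort("`delta` must be a positive scalar (0-255 scale).", "validation")
  }
  c_of <- c(low = 0.4, middle = 0.8, high = 1.2)
  cfg <- nlm_config(
    patch_radius = 3L, search_radius = 10L,
    h = c_of[[level]] * delta / 255,
    self_weight_rule = "max_of_neighbors"
  )
  cfg$smoothing_level <- level
  cfg$delta <- delta
  cfg$c <- c_of[[level]]
  cfg
}

#' Mean squared distance between two image patches
#'
#' The dissimilarity entering the NLM weight: the sum of squared intensity
#' differences between the \eqn{(2r+1)\times(2r+1)} patches centered at `i`
#' and `j`, divided by the patch pixel count.  Patches crossing the border
#' read through reflected padding.  Symmetric in `i`, `j`; zero iff the
#' patches are identical.
#'
#' @param img an [us_image()] or numeric matrix.
#' @param i,j integer `(row, col)` pixel positions.
#' @param patch_radius integer \eqn{\ge 1}.
#' @return A non-negative scalar.
#' @export
patch_distance <- function(img, i, j, patch_radius = 3L) {
  x <- as_pixel_matrix(img)
  r <- as.integer(patch_radius)
  stopifnot(r >= 1L, length(i) == 2L, length(j) == 2L)
  if (any(c(i, j) < 1L) || i[1L] > nrow(x) || j[1L] > nrow(x) ||
    i[2L] > ncol(x) || j[2L] > ncol(x)) {
    usnlm_abort("`i` and `j` must lie inside the image.", "validation")
  }
  p <- pad_reflect(x, r)
  pi_ <- p[i[1L]:(i[1L] + 2L * r), i[2L]:(i[2L] + 2L * r)]
  pj_ <- p[j[1L]:(j[1L] + 2L * r), j[2L]:(j[2L] + 2L * r)]
  sum((pi_ - pj_)^2) / (2 * r + 1)^2
}

#' NLM weight map for one pixel
#'
#' Computes the full normalized weight field over the search window of a
#' single pixel — the per-pixel view of the weights the denoiser applies.
#' Window positions beyond the image border refer to reflected pixels; their
#' reflected source coordinates are reported.
#'
#' @param img an [us_image()] or numeric matrix.
#' @param i integer `(row, col)` pixel position.
#' @param cfg an [nlm_config()].
#' @return A tibble with one row per window position: `drow`, `dcol` (offset
#'   from `i`), `row`, `col` (source pixel after reflection), `distance`
#'   (patch distance; `NA` for the center) and `weight`.  Weights are in
#'   \eqn{[0, 1]} and sum to 1.
#' @export
nlm_weights <- function(img, i, cfg) {
  stopifnot(inherits(cfg, "nlm_config"), length(i) == 2L)
  x <- as_pixel_matrix(img)
  r <- cfg$patch_radius
  R <- cfg$search_radius
  pad <- r + R
  p <- pad_reflect(x, pad)
  ir <- i[1L] + pad
  ic <- i[2L] + pad
  offs <- expand.grid(dcol = -R:R, drow = -R:R)[, c("drow", "dcol")]
  np <- (2 * r + 1)^2
  pi_ <- p[(ir - r):(ir + r), (ic - r):(ic + r)]
  d <- purrr::map2_dbl(offs$drow, offs$dcol, function(dr, dc) {
    if (dr == 0 && dc == 0) {
      return(NA_real_)
    }
    pj_ <- p[(ir + dr - r):(ir + dr + r), (ic + dc - r):(ic + dc + r)]
    sum((pi_ - pj_)^2) / np
  })
  raw <- exp(-d / cfg$h^2)
  self_idx <- which(is.na(d))
  raw[self_idx] <- if (cfg$self_weight_rule == "include") {
    1
  } else {
    m <- max(raw[-self_idx])
    if (m == 0) 1 else m
  }
  tibble::tibble(
    drow = offs$drow,
    dcol = offs$dcol,
    row = reflect_index(i[1L] + offs$drow, nrow(x)),
    col = reflect_index(i[2L] + offs$dcol, ncol(x)),
    distance = d,
    weight = raw / sum(raw)
  )
}

#' Denoise an image with non-local means
#'
#' The main denoiser: each output pixel is the normalized weighted average of
#' its search window (see [nlm_config()] for the weight model).  The output
#' is a convex combination of input values, so it is bounded pixelwise by the
#' input minimum and maximum.  Implemented in C++; borders are handled with
#' reflected padding.  `nlm_denoise_bruteforce()` is an intentionally plain
#' pure-R quadruple loop with the identical contract, kept as the
#' correctness oracle for the accelerated path.
#'
#' @param img an [us_image()] or numeric matrix in \eqn{[0, 1]}.
#' @param cfg an [nlm_config()], e.g. from [smoothing_preset()].
#' @return A denoised [us_image()].
#' @export
#' @examples
#' noisy <- simulate_speckle(matrix(0.4, 48, 48), seed = 1)
#' cfg <- smoothing_preset("middle", delta = 255 * estimate_noise_sd(noisy))
#' den <- nlm_denoise(noisy, cfg)
#' c(noisy = sd(noisy), denoised = sd(den))
nlm_denoise <- function(img, cfg) {
  stopifnot(inherits(cfg, "nlm_config"))
  img <- as_us_image(img)
  out <- nlm_denoise_cpp(
    as_pixel_matrix(img),
    cfg$patch_radius, cfg$search_radius, cfg$h,
    cfg$self_weight_rule == "include"
  )
  rewrap_image(out, img)
}

#' @rdname nlm_denoise
#' @export
nlm_denoise_bruteforce <- function(img, cfg) {
  stopifnot(inherits(cfg, "nlm_config"))
  img <- as_us_image(img)
  x <- as_pixel_matrix(img)
  r <- cfg$patch_radius
  R <- cfg$search_radius
  h2 <- cfg$h^2
  np <- (2 * r + 1)^2
  include <- cfg$self_weight_rule == "include"
  pad <- r + R
  p <- pad_reflect(x, pad)
  n <- nrow(x)
  m <- ncol(x)
  out <- matrix(0, n, m)
  for (row in seq_len(n)) {
    for (col in seq_len(m)) {
      ir <- row + pad
      ic <- col + pad
      pi_ <- p[(ir - r):(ir + r), (ic - r):(ic + r)]
      wsum <- 0
      acc <- 0
      wmax <- 0
      for (dr in -R:R) {
        for (dc in -R:R) {
          if (dr == 0 && dc == 0) next
          jr <- ir + dr
          jc <- ic + dc
          d <- sum((pi_ - p[(jr - r):(jr + r), (jc - r):(jc + r)])^2) / np
          w <- exp(-d / h2)
          if (w > wmax) wmax <- w
          wsum <- wsum + w
          acc <- acc + w * p[jr, jc]
        }
      }
      wself <- if (include || wmax == 0) 1 else wmax
      out[row, col] <- (acc + wself * p[ir, ic]) / (wsum + wself)
    }
  }
  rewrap_image(out, img)
}

#' Estimate the noise standard deviation of an image
#'
#' Robust global noise estimate from the diagonal Haar detail of overlapping
#' 2 x 2 blocks, \eqn{d = (x_{11} + x_{22} - x_{12} - x_{21})/2}, whose
#' variance equals the per-pixel noise variance for i.i.d. noise and which is
#' blind to locally smooth structure.  The estimate is `mad(d)` (median
#' absolute deviation scaled for normal consistency), robust to the edges of
#' phantom targets.  Use `255 *` the result as the `delta` of
#' [smoothing_preset()].
#'
#' @param img an [us_image()] or numeric matrix.
#' @return Estimated noise standard deviation on the \eqn{[0, 1]} scale.
#' @export
estimate_noise_sd <- function(img) {
  x <- as_pixel_matrix(img)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    usnlm_abort("Need at least a 2 x 2 image to estimate noise.", "validation")
  }
  n <- nrow(x)
  m <- ncol(x)
  d <- (x[-n, -m] + x[-1, -1] - x[-n, -1] - x[-1, -m]) / 2
  mad(as.numeric(d))
}
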