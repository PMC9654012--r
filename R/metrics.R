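#' Regions of interest for image statistics
#'
#' Circular or rectangular pixel regions over which the quality-control
#' statistics are computed.  A pixel belongs to a circle ROI when its center
#' lies within `radius` of the ROI center (Euclidean distance), and to a
#' rectangle ROI when it lies within the half-sizes on both axes.
#'
#' @param center numeric `(row, col)` in pixels.
#' @param radius circle radius in pixels.
#' @param half_height,half_width rectangle half-sizes in pixels.
#' @param label optional free-text label.
#' @return An object of class `roi_spec`.
#' @export
#' @examples
#' roi_circle(c(40, 40), 8, label = "target")
roi_circle <- function(center, radius, label = NULL) {
  stopifnot(length(center) == 2L, length(radius) == 1L, radius > 0)
  structure(
    list(
      shape = "circle", center = as.numeric(center),
      radius = as.numeric(radius), label = label %||% "roi"
    ),
    class = "roi_spec"
  )
}

#' @rdname roi_circle
#' @export
roi_rect <- function(center, half_height, half_width, label = NULL) {
  stopifnot(
    length(center) == 2L, half_height > 0, half_width > 0
  )
  structure(
    list(
      shape = "rect", center = as.numeric(center),
      half_height = as.numeric(half_height),
      half_width = as.numeric(half_width), label = label %||% "roi"
    ),
    class = "roi_spec"
  )
}

#' @export
print.roi_spec <- function(x, ...) {
  if (x$shape == "circle") {
    cat(sprintf(
      "<roi_spec> circle '%s' at (%g, %g), radius %g\n",
      x$label, x$center[1L], x$center[2L], x$radius
    ))
  } else {
    cat(sprintf(
      "<roi_spec> rect '%s' at (%g, %g), half-size (%g, %g)\n",
      x$label, x$center[1L], x$center[2L], x$half_height, x$half_width
    ))
  }
  invisible(x)
}

# Logical membership mask of an ROI on an image of dimensions `dims`.
roi_mask <- function(roi, dims) {
  stopifnot(inherits(roi, "roi_spec"))
  rr <- matrix(seq_len(dims[1L]), dims[1L], dims[2L])
  cc <- matrix(seq_len(dims[2L]), dims[1L], dims[2L], byrow = TRUE)
  if (roi$shape == "circle") {
    (rr - roi$center[1L])^2 + (cc - roi$center[2L])^2 <= roi$radius^2
  } else {
    abs(rr - roi$center[1L]) <= roi$half_height &
      abs(cc - roi$center[2L]) <= roi$half_width
  }
}

roi_bounds_ok <- function(roi, dims) {
  ext <- if (roi$shape == "circle") {
    c(roi$radius, roi$radius)
  } else {
    c(roi$half_height, roi$half_width)
  }
  roi$center[1L] - ext[1L] >= 1 && roi$center[1L] + ext[1L] <= dims[1L] &&
    roi$center[2L] - ext[2L] >= 1 && roi$center[2L] + ext[2L] <= dims[2L]
}

#' ROI intensity statistics
#'
#' Mean and standard deviation of the pixels inside an ROI — the
#' \eqn{S} and \eqn{\sigma} entering CNR and COV.  The standard deviation
#' uses the population convention (divide by \eqn{n}), fixed so results are
#' bit-reproducible; with the ROI sizes used here the \eqn{n} vs \eqn{n-1}
#' distinction is immaterial.
#'
#' @param img an [us_image()] or numeric matrix.
#' @param roi an [roi_circle()] / [roi_rect()] spec, fully inside the image.
#' @param min_pixels minimum pixel count (default 9).
#' @return A one-row tibble: `label`, `mean`, `sd`, `n_pixels`.
#' @export
roi_stats <- function(img, roi, min_pixels = 9L) {
  x <- as_pixel_matrix(img)
  if (!roi_bounds_ok(roi, dim(x))) {
    usnlm_abort(
      sprintf("ROI '%s' extends outside the image.", roi$label),
      "validation"
    )
  }
  v <- x[roi_mask(roi, dim(x))]
  if (length(v) < min_pixels) {
    usnlm_abort(
      sprintf(
        "ROI '%s' contains %d pixels (< %d).",
        roi$label, length(v), min_pixels
      ),
      "validation"
    )
  }
  m <- mean(v)
  tibble::tibble(
    label = roi$label,
    mean = m,
    sd = sqrt(mean((v - m)^2)),
    n_pixels = length(v)
  )
}

#' Contrast-to-noise ratio between two ROIs
#'
#' \deqn{\mathrm{CNR} = \frac{|S_T - S_B|}
#'   {\sqrt{\sigma_T^2 + \sigma_B^2}}}
#' with \eqn{S}, \eqn{\sigma} the ROI mean and (population) standard
#' deviation.  Symmetric under swapping target and background; invariant
#' under global affine intensity maps \eqn{x \mapsto a x + b}, \eqn{a > 0}.
#'
#' @param img an [us_image()] or numeric matrix.
#' @param target_roi,background_roi disjoint [roi_circle()] / [roi_rect()]
#'   specs.
#' @return A non-negative scalar.  When both ROI standard deviations are
#'   zero the metric is undefined and a typed error
#'   (`usnlm_error_undefined_metric`) is raised.
#' @export
#' @examples
#' img <- matrix(rep(c(0.2, 0.6), each = 128), 16, 16)
#' cnr(img, roi_rect(c(8, 12), 3, 3, "t"), roi_rect(c(8, 4), 3, 3, "b"))
cnr <- function(img, target_roi, background_roi) {
  x <- as_pixel_matrix(img)
  overlap <- roi_mask(target_roi, dim(x)) & roi_mask(background_roi, dim(x))
  if (any(overlap)) {
    usnlm_abort(
      sprintf(
        "ROIs '%s' and '%s' overlap; CNR needs disjoint regions.",
        target_roi$label, background_roi$label
      ),
      "validation"
    )
  }
  st <- roi_stats(x, target_roi)
  sb <- roi_stats(x, background_roi)
  denom <- sqrt(st$sd^2 + sb$sd^2)
  if (denom == 0) {
    usnlm_abort(
      sprintf(
        "CNR undefined for ROIs '%s'/'%s': both standard deviations are zero.",
        target_roi$label, background_roi$label
      ),
      "undefined_metric"
    )
  }
  abs(st$mean - sb$mean) / denom
}

#' Coefficient of variation of an ROI
#'
#' \deqn{\mathrm{COV} = \sigma_T / S_T.}  Lower is smoother.  Invariant
#' under global scaling \eqn{x \mapsto a x} (\eqn{a > 0}) but not under
#' offsets.  Exported as `roi_cov()` so `stats::cov()` is not masked.
#'
#' @param img an [us_image()] or numeric matrix.
#' @param roi an [roi_circle()] / [roi_rect()] spec.
#' @return A non-negative scalar; a typed error
#'   (`usnlm_error_undefined_metric`) if the ROI mean is zero.
#' @export
roi_cov <- function(img, roi) {
  st <- roi_stats(img, roi)
  if (st$mean == 0) {
    usnlm_abort(
      sprintf("COV undefined for ROI '%s': mean is zero.", roi$label),
      "undefined_metric"
    )
  }
  st$sd / st$mean
}

#' Average a metric over several ROI pairs
#'
#' The multi-ROI protocol: the reported CNR (or COV) is the arithmetic mean
#' of the per-pair values over a set of target/background ROI pairs (COV
#' uses only the target ROI of each pair).
#'
#' @param img an [us_image()] or numeric matrix.
#' @param roi_pairs list of `list(target =, background =)` ROI spec pairs,
#'   e.g. from [ats_roi_pairs()].
#' @param metric `"cnr"` or `"cov"`.
#' @return The mean metric value, with the per-pair values attached as a
#'   tibble in attribute `"per_pair"` (columns `target`, `background`,
#'   `value`).
#' @export
average_metric <- function(img, roi_pairs, metric = c("cnr", "cov")) {
  metric <- match.arg(metric)
  if (length(roi_pairs) < 1L) {
    usnlm_abort("Need at least one ROI pair.", "validation")
  }
  vals <- purrr::map(roi_pairs, function(p) {
    tryCatch(
      list(
        value = if (metric == "cnr") {
          cnr(img, p$target, p$background)
        } else {
          roi_cov(img, p$target)
        },
        error = NULL
      ),
      usnlm_error_undefined_metric = function(e) {
        list(value = NA_real_, error = p$target$label)
      }
    )
  })
  bad <- purrr::compact(purrr::map(vals, "error"))
  if (length(bad)) {
    usnlm_abort(
      sprintf(
        "Metric '%s' undefined for ROI pair(s): %s.",
        metric, paste(unlist(bad), collapse = ", ")
      ),
      "undefined_metric"
    )
  }
  per_pair <- tibble::tibble(
    target = purrr::map_chr(roi_pairs, ~ .x$target$label),
    background = purrr::map_chr(roi_pairs, ~ .x$background$label),
    value = purrr::map_dbl(vals, "value")
  )
  structure(mean(per_pair$value), per_pair = per_pair)
}
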