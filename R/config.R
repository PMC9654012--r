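# YAML serialization of phantom specs and ROI sets.
#
# The on-disk dialect mirrors the in-memory types:
#   image_size: [h, w]; background_level; targets: [{shape, center, radii,
#   contrast_db}]; speckle: {sigma, seed}
#   rois: {label: {shape, center, radius | half_size}}; pairs: [{target,
#   background}] referencing roi labels.

#' Write / read a phantom configuration
#'
#' @param spec a [phantom_spec()].
#' @param path destination `.yaml` path.
#' @param speckle optional list with elements `sigma` and `seed`, stored
#'   alongside the geometry.
#' @return `write_phantom_config()` returns `path` invisibly;
#'   `read_phantom_config()` returns a list with elements `spec` (a
#'   [phantom_spec()]) and `speckle` (list or `NULL`).
#' @export
write_phantom_config <- function(spec, path, speckle = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  targets <- purrr::pmap(spec$targets, function(shape, center_row, center_col,
                                                radius_row, radius_col,
                                                contrast_db) {
    list(
      shape = shape,
      center = c(center_row, center_col),
      radii = c(radius_row, radius_col),
      contrast_db = contrast_db
    )
  })
  obj <- list(
    image_size = as.integer(spec$image_size),
    background_level = spec$background_level,
    targets = targets
  )
  if (!is.null(speckle)) {
    obj$speckle <- list(
      sigma = speckle$sigma %||% 1,
      seed = as.integer(speckle$seed)
    )
  }
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  if (!file.exists(path)) {
    usnlm_abort(sprintf("Config file does not exist: '%s'", path), "io")
  }
  obj <- yaml::read_yaml(path)
  targets <- purrr::map_dfr(obj$targets, function(t) {
    target_spec(t$shape,
      center = unlist(t$center), radii = unlist(t$radii),
      contrast_db = t$contrast_db
    )
  })
  spec <- phantom_spec(
    image_size = unlist(obj$image_size),
    background_level = obj$background_level,
    targets = if (length(obj$targets)) targets else NULL
  )
  list(spec = spec, speckle = obj$speckle)
}

roi_to_list <- function(roi) {
  out <- list(shape = roi$shape, center = as.numeric(roi$center))
  if (roi$shape == "circle") {
    out$radius <- roi$radius
  } else {
    out$half_size <- c(roi$half_height, roi$half_width)
  }
  out
}

roi_from_list <- function(x, label) {
  if (identical(x$shape, "circle")) {
    roi_circle(unlist(x$center), x$radius, label = label)
  } else {
    roi_rect(unlist(x$center),
      half_height = x$half_size[[1L]],
      half_width = x$half_size[[2L]], label = label
    )
  }
}

#' Write / read a set of labelled ROIs with target/background pairings
#'
#' @param rois named list of [roi_circle()] / [roi_rect()] specs.
#' @param pairs list of `list(target =, background =)` character pairs
#'   referencing names of `rois`.
#' @param path destination `.yaml` path.
#' @return `write_roi_config()` returns `path` invisibly;
#'   `read_roi_config()` returns a list with elements `rois` (named list of
#'   ROI specs) and `pairs` (list of `list(target =, background =)` ROI
#'   specs, resolved).
#' @export
write_roi_config <- function(rois, pairs, path) {
  stopifnot(is.list(rois), !is.null(names(rois)))
  obj <- list(
    rois = purrr::map(rois, roi_to_list),
    pairs = purrr::map(pairs, function(p) {
      list(target = p$target, background = p$background)
    })
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_roi_config
#' @export
read_roi_config <- function(path) {
  if (!file.exists(path)) {
    usnlm_abort(sprintf("ROI file does not exist: '%s'", path), "io")
  }
  obj <- yaml::read_yaml(path)
  rois <- purrr::imap(obj$rois, roi_from_list)
  pairs <- purrr::map(obj$pairs, function(p) {
    if (!p$target %in% names(rois) || !p$background %in% names(rois)) {
      usnlm_abort(
        sprintf(
          "ROI pair (%s, %s) references unknown ROI labels.",
          p$target, p$background
        ),
        "validation"
      )
    }
    list(target = rois[[p$target]], background = rois[[p$background]])
  })
  list(rois = rois, pairs = pairs)
}
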