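#' Describe a circular or elliptical phantom target
#'
#' Targets are defined by a center, per-axis radii and an amplitude contrast
#' relative to the background in dB.  Contrast is amplitude-referred, the
#' ultrasound convention: a target at `contrast_db` renders at
#' `background_level * 10^(contrast_db / 20)`.
#'
#' @param shape `"circle"` or `"ellipse"`.
#' @param center numeric `(row, col)` center in pixels.
#' @param radii numeric `(r_row, r_col)` radii in pixels (a single number is
#'   recycled for circles).
#' @param contrast_db amplitude contrast in dB, in \eqn{[-30, 30]}.
#' @return A one-row tibble describing the target.
#' @export
#' @examples
#' target_spec("circle", center = c(50, 50), radii = 12, contrast_db = -6)
target_spec <- function(shape = c("circle", "ellipse"), center, radii,
                        contrast_db) {
  shape <- match.arg(shape)
  if (length(radii) == 1L) radii <- c(radii, radii)
  stopifnot(length(center) == 2L, length(radii) == 2L, length(contrast_db) == 1L)
  if (any(radii < 2)) {
    usnlm_abort("Target radii must be >= 2 pixels.", "validation")
  }
  if (contrast_db < -30 || contrast_db > 30) {
    usnlm_abort("`contrast_db` must lie in [-30, 30].", "validation")
  }
  if (shape == "circle" && radii[1L] != radii[2L]) {
    usnlm_abort("A circle target needs equal radii.", "validation")
  }
  tibble::tibble(
    shape = shape,
    center_row = as.numeric(center[1L]),
    center_col = as.numeric(center[2L]),
    radius_row = as.numeric(radii[1L]),
    radius_col = as.numeric(radii[2L]),
    contrast_db = as.numeric(contrast_db)
  )
}

#' Describe a synthetic gray-scale phantom
#'
#' A phantom is a uniform echogenic background holding a list of circular or
#' elliptical targets of graded echogenicity, mimicking the gray-scale /
#' dynamic-range region of a multipurpose QC phantom.
#'
#' @param image_size integer `(height, width)`, both at least 32.
#' @param background_level background amplitude in \eqn{(0, 1]}.
#' @param targets a tibble of targets, usually built by binding
#'   [target_spec()] rows; later rows overpaint earlier ones where they
#'   overlap.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size, background_level = 0.35,
                         targets = NULL) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2L)
  if (any(image_size < 32L)) {
    usnlm_abort("`image_size` components must be >= 32 pixels.", "validation")
  }
  if (background_level <= 0 || background_level > 1) {
    usnlm_abort("`background_level` must lie in (0, 1].", "validation")
  }
  if (is.null(targets)) {
    targets <- target_spec("circle", c(16, 16), 2, 0)[0, ]
  }
  targets <- tibble::as_tibble(targets)
  needed <- c(
    "shape", "center_row", "center_col",
    "radius_row", "radius_col", "contrast_db"
  )
  if (!all(needed %in% names(targets))) {
    usnlm_abort(
      paste0("`targets` must have columns: ", paste(needed, collapse = ", ")),
      "validation"
    )
  }
  for (k in seq_len(nrow(targets))) {
    t <- targets[k, ]
    inside <- t$center_row - t$radius_row >= 1 &&
      t$center_row + t$radius_row <= image_size[1L] &&
      t$center_col - t$radius_col >= 1 &&
      t$center_col + t$radius_col <= image_size[2L]
    if (!inside) {
      usnlm_abort(
        sprintf(
          "Target %d (%+g dB at %g,%g) extends outside the %d x %d image.",
          k, t$contrast_db, t$center_row, t$center_col,
          image_size[1L], image_size[2L]
        ),
        "validation"
      )
    }
  }
  structure(
    list(
      image_size = image_size,
      background_level = background_level,
      targets = targets
    ),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d x %d, background %.3f, %d target(s)\n",
    x$image_size[1L], x$image_size[2L], x$background_level, nrow(x$targets)
  ))
  if (nrow(x$targets)) print(x$targets)
  invisible(x)
}

#' Render a noise-free phantom image
#'
#' Paints `background_level` everywhere, then each target in list order at
#' `background_level * 10^(contrast_db / 20)` (later targets win on overlap),
#' and clips to \eqn{[0, 1]}.
#'
#' @param spec a [phantom_spec()].
#' @return An [us_image()].
#' @export
#' @examples
#' spec <- default_ats_grayscale_spec(c(128, 192))
#' img <- render_phantom(spec)
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_size[1L]
  w <- spec$image_size[2L]
  px <- matrix(spec$background_level, h, w)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (k in seq_len(nrow(spec$targets))) {
    t <- spec$targets[k, ]
    inside <- ((rr - t$center_row) / t$radius_row)^2 +
      ((cc - t$center_col) / t$radius_col)^2 <= 1
    px[inside] <- spec$background_level * 10^(t$contrast_db / 20)
  }
  us_image(clip01(px))
}

#' Default six-target gray-scale phantom layout
#'
#' Lays out six circular targets on a 2 x 3 grid over a 0.35 background, with
#' amplitude contrasts +15, +6, +3 dB (top row) and -3, -6, -15 dB (bottom
#' row) — a graded-echogenicity set in the style of the gray-scale region of
#' a multipurpose QC phantom.  Deterministic in `image_size`.
#'
#' @param image_size integer `(height, width)`; must be large enough to hold
#'   six non-overlapping circles (roughly 64 x 96 or more).
#' @return A [phantom_spec()] with exactly six targets.
#' @export
default_ats_grayscale_spec <- function(image_size = c(256L, 384L)) {
  image_size <- as.integer(image_size)
  h <- image_size[1L]
  w <- image_size[2L]
  radius <- floor(0.8 * min(h / 6, w / 12))
  if (radius < 4L) {
    usnlm_abort(
      sprintf("Image %d x %d is too small for the six-target layout.", h, w),
      "validation"
    )
  }
  rows <- round(c(h / 3, 2 * h / 3))
  cols <- round(c(w / 6, w / 2, 5 * w / 6))
  contrasts <- c(15, 6, 3, -3, -6, -15)
  grid <- expand.grid(row = rows, col = cols)
  grid <- grid[order(grid$row, grid$col), ]
  targets <- purrr::map2_dfr(
    seq_len(6L), contrasts,
    function(k, db) {
      target_spec("circle",
        center = c(grid$row[k], grid$col[k]),
        radii = radius, contrast_db = db
      )
    }
  )
  phantom_spec(image_size, background_level = 0.35, targets = targets)
}

#' Six target/background ROI pairs for the default phantom layout
#'
#' For each target of a six-target gray-scale [phantom_spec()], returns a
#' circular ROI centered in the target and a same-sized background ROI on the
#' horizontal midline between the two target rows, directly above/below the
#' target.  These pairs drive the averaged CNR/COV protocol.
#'
#' @param spec a six-target [phantom_spec()] from
#'   [default_ats_grayscale_spec()].
#' @return A list of six `list(target =, background =)` pairs of
#'   [roi_circle()] specs.
#' @export
ats_roi_pairs <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  t <- spec$targets
  if (nrow(t) != 6L) {
    usnlm_abort("Expected a six-target phantom spec.", "validation")
  }
  mid_row <- mean(range(t$center_row))
  roi_r <- max(3, floor(0.5 * min(t$radius_row)))
  purrr::map(seq_len(6L), function(k) {
    list(
      target = roi_circle(
        center = c(t$center_row[k], t$center_col[k]),
        radius = roi_r,
        label = sprintf("target_%+gdB", t$contrast_db[k])
      ),
      background = roi_circle(
        center = c(mid_row, t$center_col[k]),
        radius = roi_r,
        label = sprintf("background_%+gdB", t$contrast_db[k])
      )
    )
  })
}

#' Render a thyroid-like test scene
#'
#' Builds a deterministic (given `seed`) scene containing an elliptical
#' "lobe" of elevated echogenicity, a darker circular "nodule" inside it and
#' a near-anechoic circular "vessel" outside it, together with matching named
#' circular ROIs.  The seed only jitters the structure centers slightly, so
#' layouts differ across seeds but the topology never does.
#'
#' @param image_size integer `(height, width)`, both at least 128.
#' @param seed integer seed.
#' @return A list with elements `image` (an [us_image()]) and `rois` (named
#'   list of [roi_circle()] specs: `lobe`, `nodule`, `vessel`).
#' @export
render_thyroid_scene <- function(image_size = c(256L, 256L), seed = 1L) {
  image_size <- as.integer(image_size)
  h <- image_size[1L]
  w <- image_size[2L]
  if (h < 128L || w < 128L) {
    usnlm_abort("`image_size` must be at least 128 x 128.", "validation")
  }
  jit <- with_fixed_seed(seed, runif(6L, -0.015, 0.015))
  lobe_c <- c(h * (0.52 + jit[1L]), w * (0.42 + jit[2L]))
  lobe_r <- c(0.30 * h, 0.30 * w)
  nod_c <- c(
    lobe_c[1L] + 0.08 * h * (1 + jit[3L]),
    lobe_c[2L] - 0.06 * w * (1 + jit[4L])
  )
  nod_r <- 0.09 * min(h, w)
  ves_c <- c(h * (0.30 + jit[5L]), w * (0.86 + jit[6L]))
  ves_r <- 0.07 * min(h, w)

  levels <- c(background = 0.22, lobe = 0.45, nodule = 0.18, vessel = 0.03)
  px <- matrix(levels[["background"]], h, w)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  in_lobe <- ((rr - lobe_c[1L]) / lobe_r[1L])^2 +
    ((cc - lobe_c[2L]) / lobe_r[2L])^2 <= 1
  px[in_lobe] <- levels[["lobe"]]
  px[(rr - nod_c[1L])^2 + (cc - nod_c[2L])^2 <= nod_r^2] <- levels[["nodule"]]
  px[(rr - ves_c[1L])^2 + (cc - ves_c[2L])^2 <= ves_r^2] <- levels[["vessel"]]

  rois <- list(
    lobe = roi_circle(
      center = c(lobe_c[1L] - 0.16 * h, lobe_c[2L] + 0.12 * w),
      radius = max(4, floor(0.085 * min(h, w))), label = "lobe"
    ),
    nodule = roi_circle(
      center = nod_c, radius = max(3, floor(0.55 * nod_r)), label = "nodule"
    ),
    vessel = roi_circle(
      center = ves_c, radius = max(3, floor(0.55 * ves_r)), label = "vessel"
    )
  )
  list(image = us_image(clip01(px)), rois = rois)
}

#' Corrupt an image with Rayleigh multiplicative speckle
#'
#' Fully developed speckle makes the local mean and standard deviation of a
#' B-mode image proportional, with Rayleigh-distributed envelope amplitude.
#' This simulator multiplies each noise-free pixel \eqn{s} by an independent
#' Rayleigh draw normalized to unit mean, \eqn{R / E[R]} with
#' \eqn{E[R] = \sigma\sqrt{\pi/2}}, then clips to \eqn{[0, 1]}.  Before
#' clipping, the output's conditional mean is \eqn{s} (the speckle is
#' unbiased) and its conditional standard deviation is
#' \eqn{s\sqrt{(4-\pi)/\pi} \approx 0.5227 s} — the scale `sigma` cancels and
#' only sets the internal draw scale.
#'
#' @param img an [us_image()] or matrix in \eqn{[0, 1]}.
#' @param sigma Rayleigh scale parameter, > 0.
#' @param seed integer seed; the same seed reproduces the field bit-for-bit.
#' @return A speckled [us_image()].
#' @export
#' @examples
#' clean <- us_image(matrix(0.4, 64, 64))
#' noisy <- simulate_speckle(clean, seed = 7)
simulate_speckle <- function(img, sigma = 1, seed) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    usnlm_abort("`sigma` must be a positive scalar.", "validation")
  }
  if (missing(seed)) {
    usnlm_abort("`seed` is required for reproducible speckle.", "validation")
  }
  img <- as_us_image(img)
  x <- as_pixel_matrix(img)
  n <- length(x)
  # Rayleigh(sigma) == Weibull(shape 2, scale sigma * sqrt(2))
  draws <- with_fixed_seed(seed, rweibull(n, shape = 2, scale = sigma * sqrt(2)))
  ratio <- matrix(draws, nrow(x), ncol(x)) / (sigma * sqrt(pi / 2))
  rewrap_image(clip01(x * ratio), img)
}
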