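test_that("render_phantom paints background and dB-scaled targets", {
  # no targets: constant background
  flat <- render_phantom(phantom_spec(c(64, 64), background_level = 0.5))
  expect_equal(as_pixel_matrix_test(flat), matrix(0.5, 64, 64))

  # 0 dB target is indistinguishable from background
  spec0 <- phantom_spec(c(64, 64), 0.5,
    targets = target_spec("circle", c(32, 32), 10, contrast_db = 0)
  )
  expect_equal(as_pixel_matrix_test(render_phantom(spec0)), matrix(0.5, 64, 64))

  # +20*log10(2) dB doubles the amplitude
  spec2 <- phantom_spec(c(64, 64), 0.4,
    targets = target_spec("circle", c(32, 32), 10, contrast_db = 20 * log10(2))
  )
  img2 <- render_phantom(spec2)
  expect_equal(img2[32, 32], 0.8, tolerance = 1e-12)
  expect_equal(img2[5, 5], 0.4)

  # later targets overpaint earlier ones
  spec_ov <- phantom_spec(c(64, 64), 0.4, targets = dplyr::bind_rows(
    target_spec("circle", c(32, 32), 12, contrast_db = 6),
    target_spec("circle", c(32, 32), 6, contrast_db = -6)
  ))
  img_ov <- render_phantom(spec_ov)
  expect_equal(img_ov[32, 32], 0.4 * 10^(-6 / 20), tolerance = 1e-12)
  expect_equal(img_ov[32, 42], 0.4 * 10^(6 / 20), tolerance = 1e-12)
})

test_that("phantom validation rejects bad geometry", {
  expect_error(phantom_spec(c(16, 64)), class = "usnlm_error_validation")
  expect_error(phantom_spec(c(64, 64), 0), class = "usnlm_error_validation")
  expect_error(
    phantom_spec(c(64, 64), 0.5,
      targets = target_spec("circle", c(5, 5), 10, contrast_db = 3)
    ),
    class = "usnlm_error_validation"
  )
  expect_error(target_spec("circle", c(5, 5), 1, 0), class = "usnlm_error_validation")
  expect_error(target_spec("circle", c(5, 5), 4, 40), class = "usnlm_error_validation")
})

test_that("default six-target layout has the graded-contrast structure", {
  spec <- default_ats_grayscale_spec(c(256, 384))
  expect_identical(nrow(spec$targets), 6L)
  expect_setequal(spec$targets$contrast_db, c(15, 6, 3, -3, -6, -15))
  img <- render_phantom(spec)

  # -15 dB disc interior sits at 0.35 * 10^(-15/20)
  t <- spec$targets[spec$targets$contrast_db == -15, ]
  mask <- (row(img) - t$center_row)^2 + (col(img) - t$center_col)^2 <=
    (t$radius_row - 1)^2
  expect_equal(mean(img[mask]), 0.35 * 10^(-15 / 20), tolerance = 1e-12)

  # mean in-target intensity strictly ordered by contrast (with +15 clipped)
  means <- vapply(seq_len(6), function(k) {
    tk <- spec$targets[k, ]
    m <- (row(img) - tk$center_row)^2 + (col(img) - tk$center_col)^2 <=
      (tk$radius_row - 1)^2
    mean(img[m])
  }, numeric(1))
  ord <- order(spec$targets$contrast_db)
  expect_true(all(diff(means[ord]) > 0))

  expect_error(default_ats_grayscale_spec(c(32, 32)),
    class = "usnlm_error_validation"
  )
})

test_that("ats_roi_pairs lie inside the image and off the targets", {
  spec <- default_ats_grayscale_spec(c(128, 192))
  img <- render_phantom(spec)
  pairs <- ats_roi_pairs(spec)
  expect_length(pairs, 6L)
  for (p in pairs) {
    st <- roi_stats(img, p$target)
    sb <- roi_stats(img, p$background)
    expect_gte(st$n_pixels, 9L)
    # background ROI really samples background: constant 0.35, sd 0
    expect_equal(sb$mean, 0.35)
    expect_equal(sb$sd, 0)
    # target ROI is entirely inside its disc: sd 0 there too
    expect_equal(st$sd, 0)
  }
})

test_that("thyroid scene has the promised topology, deterministically", {
  s1 <- render_thyroid_scene(c(160, 160), seed = 5)
  s2 <- render_thyroid_scene(c(160, 160), seed = 5)
  expect_identical(
    as_pixel_matrix_test(s1$image),
    as_pixel_matrix_test(s2$image)
  )
  s3 <- render_thyroid_scene(c(160, 160), seed = 6)
  expect_false(identical(
    as_pixel_matrix_test(s1$image),
    as_pixel_matrix_test(s3$image)
  ))

  img <- s1$image
  m_lobe <- roi_stats(img, s1$rois$lobe)$mean
  m_ves <- roi_stats(img, s1$rois$vessel)$mean
  m_nod <- roi_stats(img, s1$rois$nodule)$mean
  expect_lt(m_ves, m_lobe)
  expect_lt(m_nod, m_lobe)

  # nodule ROI pixels all carry the nodule level -> fully inside the lobe
  expect_equal(roi_stats(img, s1$rois$nodule)$sd, 0)
  expect_equal(m_nod, 0.18)

  expect_error(render_thyroid_scene(c(64, 64), seed = 1),
    class = "usnlm_error_validation"
  )
})

test_that("phantom and ROI configs round-trip through YAML", {
  d <- withr::local_tempdir()
  spec <- default_ats_grayscale_spec(c(128, 192))
  f <- file.path(d, "phantom.yaml")
  write_phantom_config(spec, f, speckle = list(sigma = 1, seed = 99L))
  back <- read_phantom_config(f)
  expect_equal(back$spec$image_size, spec$image_size)
  expect_equal(back$spec$background_level, spec$background_level)
  expect_equal(
    as.data.frame(back$spec$targets),
    as.data.frame(spec$targets)
  )
  expect_equal(back$speckle$seed, 99L)
  expect_identical(
    as_pixel_matrix_test(render_phantom(back$spec)),
    as_pixel_matrix_test(render_phantom(spec))
  )

  rois <- list(
    a = roi_circle(c(20, 20), 5, "a"),
    b = roi_rect(c(40, 40), 4, 6, "b")
  )
  fr <- file.path(d, "rois.yaml")
  write_roi_config(rois, list(list(target = "a", background = "b")), fr)
  rback <- read_roi_config(fr)
  expect_named(rback$rois, c("a", "b"))
  expect_equal(rback$rois$a$radius, 5)
  expect_equal(rback$rois$b$half_width, 6)
  expect_equal(rback$pairs[[1]]$target$label, "a")
})

test_that("speckle is multiplicative, unbiased and seed-deterministic", {
  # zero stays zero under any draw
  z <- simulate_speckle(matrix(0, 32, 32), seed = 1)
  expect_equal(as_pixel_matrix_test(z), matrix(0, 32, 32))

  # determinism
  a <- simulate_speckle(matrix(0.3, 64, 64), seed = 7)
  b <- simulate_speckle(matrix(0.3, 64, 64), seed = 7)
  expect_identical(as_pixel_matrix_test(a), as_pixel_matrix_test(b))
  expect_false(identical(
    as_pixel_matrix_test(simulate_speckle(matrix(0.3, 64, 64), seed = 8)),
    as_pixel_matrix_test(a)
  ))

  # mean preservation at a level where clipping is negligible (3-sigma band)
  s <- 0.25
  sp <- simulate_speckle(matrix(s, 256, 256), seed = 11)
  cv0 <- sqrt((4 - pi) / pi)
  se_mean <- s * cv0 / 256
  expect_lt(abs(mean(sp) - s), 3 * se_mean)

  # sigma does not enter the output law (it cancels in R / E[R])
  expect_identical(
    as_pixel_matrix_test(simulate_speckle(matrix(0.3, 16, 16), sigma = 0.5, seed = 3)),
    as_pixel_matrix_test(simulate_speckle(matrix(0.3, 16, 16), sigma = 2.0, seed = 3))
  )

  expect_error(simulate_speckle(matrix(0.3, 8, 8), sigma = 0, seed = 1),
    class = "usnlm_error_validation"
  )
  expect_error(simulate_speckle(matrix(0.3, 8, 8)),
    class = "usnlm_error_validation"
  )
})

test_that("speckle sd/mean ratio is level-independent (proportionality)", {
  cvs <- vapply(c(0.2, 0.4), function(s) {
    sp <- simulate_speckle(matrix(s, 256, 256), seed = 21)
    sd(sp) / mean(sp)
  }, numeric(1))
  expect_lt(abs(cvs[1] - cvs[2]) / cvs[1], 0.05)
})
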