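test_that("nlm_config validates its parameters", {
  expect_error(nlm_config(patch_radius = 0, h = 0.1), class = "usnlm_error_validation")
  expect_error(nlm_config(2, 1, h = 0.1), class = "usnlm_error_validation")
  expect_error(nlm_config(1, 3, h = 0), class = "usnlm_error_validation")
  expect_error(nlm_config(1, 3, h = 0.1, self_weight_rule = "center"))
})

test_that("patch_distance is a symmetric mean squared patch difference", {
  img <- random_image(9, seed = 2)
  expect_equal(patch_distance(img, c(4, 5), c(4, 5), 1), 0)
  expect_equal(patch_distance(matrix(0.7, 9, 9), c(2, 2), c(8, 5), 2), 0)

  # hand-enumerated case: lone bright pixel, patches share no support
  x5 <- matrix(0, 5, 5)
  x5[3, 3] <- 1
  expect_equal(patch_distance(x5, c(3, 3), c(1, 1), 1), 1 / 9)

  # symmetry in i, j
  expect_equal(
    patch_distance(img, c(2, 3), c(7, 8), 2),
    patch_distance(img, c(7, 8), c(2, 3), 2)
  )
})

test_that("nlm_weights realize the exponential similarity kernel", {
  cfg_inc <- nlm_config(1, 3, h = 0.2, self_weight_rule = "include")

  # constant image, include rule: exactly uniform over the window
  w <- nlm_weights(matrix(0.5, 12, 12), c(6, 6), cfg_inc)
  expect_equal(w$weight, rep(1 / 49, 49))

  # enormous h: weights approach uniform on any image
  w2 <- nlm_weights(random_image(12, seed = 4), c(6, 6), nlm_config(1, 3, h = 1e6))
  expect_lt(max(abs(w2$weight - 1 / 49)), 1e-6)

  # weights are a probability vector
  img <- random_image(12, seed = 5)
  w3 <- nlm_weights(img, c(3, 9), nlm_config(1, 3, h = 0.15))
  expect_equal(sum(w3$weight), 1, tolerance = 1e-12)
  expect_true(all(w3$weight >= 0 & w3$weight <= 1))

  # checkerboard: same-phase neighbors weigh more than opposite-phase ones
  cb <- matrix(rep_len(c(0, 1), 64), 8, 8)
  cb <- abs(cb - matrix(rep_len(c(0, 1), 64), 8, 8, byrow = TRUE)) # true checkerboard
  wcb <- nlm_weights(cb, c(4, 4), nlm_config(1, 2, h = 0.3))
  same <- wcb$weight[wcb$drow == 0 & wcb$dcol == 2]
  opp <- wcb$weight[wcb$drow == 0 & wcb$dcol == 1]
  expect_gt(same, opp)
})

test_that("accelerated NLM matches the brute-force oracle", {
  cfgs <- list(
    nlm_config(1, 3, h = 0.12),
    nlm_config(1, 3, h = 0.12, self_weight_rule = "include"),
    nlm_config(2, 4, h = 0.3)
  )
  for (seed in 1:5) {
    img <- random_image(16, seed = seed)
    for (cfg in cfgs) {
      expect_lt(
        max(abs(nlm_denoise(img, cfg) - nlm_denoise_bruteforce(img, cfg))),
        1e-10
      )
    }
  }
  # spec'd spot case: flat field with one hot pixel
  x7 <- matrix(0.2, 7, 7)
  x7[4, 4] <- 0.8
  cfg <- nlm_config(1, 2, h = 0.1)
  expect_lt(
    max(abs(nlm_denoise(x7, cfg) - nlm_denoise_bruteforce(x7, cfg))),
    1e-10
  )
})

test_that("NLM is a convex combination with the right limits", {
  img <- random_image(20, seed = 8)
  cfg <- nlm_config(1, 4, h = 0.1)
  out <- nlm_denoise(img, cfg)
  expect_gte(min(out), min(img))
  expect_lte(max(out), max(img))

  # constant in, constant out (exact at 0.5: all arithmetic scales by 2^-1)
  expect_identical(
    as_pixel_matrix_test(nlm_denoise(matrix(0.5, 15, 15), cfg)),
    matrix(0.5, 15, 15)
  )

  # h -> infinity: search-window box mean (same reflected padding)
  big <- nlm_denoise(img, nlm_config(1, 4, h = 1e6))
  expect_lt(max(abs(big - usnlm:::box_mean(img, 4))), 1e-6)

  # h -> 0 with include rule on an image of unique patches: identity
  tiny <- nlm_denoise(img, nlm_config(1, 2, h = 1e-4, self_weight_rule = "include"))
  expect_equal(as_pixel_matrix_test(tiny), img, tolerance = 1e-12)

  # single-pixel image passes through
  expect_equal(nlm_denoise(matrix(0.3, 1, 1), cfg)[1, 1], 0.3)
})

test_that("NLM commutes with horizontal and vertical flips", {
  img <- random_image(18, seed = 13)
  cfg <- nlm_config(1, 3, h = 0.15)
  out <- as_pixel_matrix_test(nlm_denoise(img, cfg))
  fliph <- function(m) m[, ncol(m):1]
  flipv <- function(m) m[nrow(m):1, ]
  expect_lt(max(abs(
    as_pixel_matrix_test(nlm_denoise(fliph(img), cfg)) - fliph(out)
  )), 1e-12)
  expect_lt(max(abs(
    as_pixel_matrix_test(nlm_denoise(flipv(img), cfg)) - flipv(out)
  )), 1e-12)
})

test_that("smoothing presets scale h as c * delta / 255 and order smoothing", {
  mid <- smoothing_preset("middle", delta = 20)
  expect_equal(mid$h, 0.8 * 20 / 255, tolerance = 1e-12)
  expect_identical(mid$patch_radius, 3L)
  expect_identical(mid$search_radius, 10L)
  expect_identical(mid$self_weight_rule, "max_of_neighbors")

  for (delta in c(5, 20, 60)) {
    hs <- vapply(
      c("low", "middle", "high"),
      function(l) smoothing_preset(l, delta)$h, numeric(1)
    )
    expect_true(all(diff(hs) > 0))
  }
  expect_error(smoothing_preset("extreme", 20))
  expect_error(smoothing_preset("low", 0), class = "usnlm_error_validation")

  # stronger smoothing leaves less flat-field variance, monotonically
  noisy <- simulate_speckle(matrix(0.4, 48, 48), seed = 31)
  delta <- 255 * 0.4 * sqrt((4 - pi) / pi) # known speckle sd on 0-255 scale
  vs <- vapply(c("low", "middle", "high"), function(l) {
    var(as.numeric(nlm_denoise(noisy, smoothing_preset(l, delta))))
  }, numeric(1))
  expect_true(all(diff(vs) < 0))
  expect_lt(vs[["middle"]], 0.5 * var(as.numeric(noisy)))
})

test_that("noise sd estimator recovers the speckle level on flat fields", {
  s <- 0.35
  noisy <- simulate_speckle(matrix(s, 128, 128), seed = 17)
  est <- estimate_noise_sd(noisy)
  truth <- s * sqrt((4 - pi) / pi)
  expect_lt(abs(est - truth) / truth, 0.15)
  expect_error(estimate_noise_sd(matrix(0.5, 1, 5)), class = "usnlm_error_validation")
})
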