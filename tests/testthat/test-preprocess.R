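test_that("aligning an image onto itself yields the identity transform", {
  sc <- generate_fa_pair(test_scenario(seed = 2))
  al <- align_pair(sc$pair$frame_1min, sc$pair$frame_1min)
  expect_lt(abs(al$transform$rotation), 0.1)
  expect_lt(max(abs(al$transform$translation)), 0.1)
  expect_equal(al$aligned, sc$pair$frame_1min, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("a known (5, 3) px shift is recovered within half a pixel", {
  p <- scenario_params(image_size = 416, seed = 11, noise_sd = 3,
                       inter_frame_shift = c(5, 3), inter_frame_rotation = 0)
  sc <- generate_fa_pair(p)
  al <- align_pair(sc$pair$frame_1min, sc$pair$frame_5min, max_rotation = 0)
  expect_lt(max(abs(al$transform$translation - c(5, 3))), 0.5)
  # the resampled frame sits back on the reference grid
  inner <- 40:380
  resid <- mean(abs(al$aligned[inner, inner] -
                    sc$pair$frame_1min[inner, inner]))
  shifted <- mean(abs(sc$pair$frame_5min[inner, inner] -
                      sc$pair$frame_1min[inner, inner]))
  expect_lt(resid, shifted)
})

test_that("a 2 degree rotation is recovered within 0.25 degrees", {
  p <- scenario_params(image_size = 416, seed = 12, noise_sd = 3,
                       inter_frame_shift = c(2, -3), inter_frame_rotation = 2)
  sc <- generate_fa_pair(p)
  al <- align_pair(sc$pair$frame_1min, sc$pair$frame_5min, max_rotation = 3)
  expect_lt(abs(al$transform$rotation - 2), 0.25)
  expect_lt(max(abs(al$transform$translation - c(2, -3))), 0.5)
})

test_that("structureless frames raise an alignment failure", {
  set.seed(1)
  a <- matrix(runif(128 * 128, 0, 255), 128, 128)
  b <- matrix(runif(128 * 128, 0, 255), 128, 128)
  expect_error(align_pair(a, b, max_rotation = 0, min_quality = 0.05),
               "alignment failure")
  expect_error(align_pair(a, matrix(0, 64, 64)), "shape")
})

test_that("rolling ball removes constant and smooth backgrounds", {
  expect_true(all(rolling_ball_subtract(matrix(40, 96, 96), 20) == 0))
  g <- matrix(seq(0, 60, length.out = 768), 768, 768, byrow = TRUE)
  expect_lt(max(rolling_ball_subtract(g, 50)), 8)
})

test_that("a bright impulse survives background subtraction intact", {
  img <- matrix(10, 128, 128)
  img[60:62, 60:62] <- 200
  out <- rolling_ball_subtract(img, 15)
  expect_gt(max(out[60:62, 60:62]), 185)
  ring <- out
  ring[55:67, 55:67] <- 0
  expect_lt(max(ring), 3)
})

test_that("shrink-and-roll approximation tracks the brute-force ball opening", {
  scene <- make_test_scene(128)
  for (rad in c(15, 20)) {
    exact <- brute_rolling_ball(scene, rad)
    approx <- rolling_ball_subtract(scene, rad)
    expect_lte(max(abs(exact - approx)), 8)
    expect_lt(mean(abs(exact - approx)), 4)
  }
})

test_that("rolling ball never brightens and is idempotent in the exact regime", {
  scene <- make_test_scene(128)
  out <- rolling_ball_subtract(scene, 20)
  expect_true(all(out <= scene))
  # radius <= 10 runs the unshrunk opening, which is idempotent up to
  # 8-bit rounding
  o1 <- rolling_ball_subtract(scene, 10)
  o2 <- rolling_ball_subtract(o1, 10)
  expect_lte(max(abs(o2 - o1)), 2)
})

test_that("centred crops follow the half-open convention and compose", {
  img <- matrix(seq_len(768 * 768), 768, 768)
  cr <- crop_centered(img, c(385, 385), 384)
  # rows 193..576: half-open window [c - s/2, c + s/2)
  expect_identical(cr, img[193:576, 193:576])

  expect_error(crop_centered(img, c(100, 100), 384), "crop out of bounds")

  nested <- crop_centered(crop_centered(img, c(385, 385), 384),
                          c(193, 193), 240)
  direct <- crop_centered(img, c(385, 385), 240)
  expect_identical(nested, direct)
})

test_that("intermeans threshold matches hand and brute-force fixed points", {
  img <- matrix(c(rep(10, 512), rep(200, 512)), 32)
  expect_identical(isodata_default_threshold(img), 105L)

  sat <- matrix(0, 16, 16)
  sat[1] <- 255
  t_sat <- isodata_default_threshold(sat)
  expect_gt(t_sat, 0)
  expect_lt(t_sat, 255)

  expect_error(isodata_default_threshold(matrix(7, 8, 8)), "degenerate")

  set.seed(33)
  for (i in 1:100) {
    img <- matrix(sample(0:255, 1024, replace = TRUE,
                         prob = stats::runif(256)^2), 32)
    fp <- intermeans_fixed_points(img)
    expect_true(isodata_default_threshold(img) %in% fp)
  }
})

test_that("binarize thresholds strictly and conserves the pixel count", {
  img <- matrix(c(0, 100, 200, 255), 2)
  expect_true(all(binarize(img, 255) == 0))
  bw <- matrix(c(0, 255, 255, 0), 2)
  expect_identical(binarize(bw, 0), bw)
  set.seed(4)
  rnd <- matrix(sample(0:255, 400, TRUE), 20)
  for (t in c(0, 63, 200)) {
    expect_equal(sum(binarize(rnd, t) == 255), sum(rnd > t))
  }
})

test_that("leakage maps clamp and have antisymmetric disjoint supports", {
  a <- matrix(c(0, 255, 255, 0), 2)
  b <- matrix(c(0, 0, 255, 255), 2)
  expect_true(all(leakage_map(a, a) == 0))
  expect_true(all(leakage_map(matrix(255, 2, 2), matrix(0, 2, 2)) == 255))
  expect_true(all(leakage_map(matrix(0, 2, 2), matrix(255, 2, 2)) == 0))
  m_ab <- leakage_map(a, b)
  m_ba <- leakage_map(b, a)
  expect_true(all(m_ab %in% c(0, 255)))
  expect_false(any(m_ab > 0 & m_ba > 0))
  expect_error(leakage_map(a, matrix(0, 3, 3)), "shape")
})
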