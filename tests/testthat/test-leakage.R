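test_that("mean gray value is the leak-pixel fraction times 255", {
  expect_equal(mean_gray_value(matrix(0, 120, 120)), 0)

  m <- matrix(0, 240, 240)
  m[seq_len(240 * 240 / 4)] <- 255
  expect_equal(mean_gray_value(m), 63.75)

  set.seed(6)
  k <- 137
  m2 <- matrix(0, 120, 120)
  m2[sample(120 * 120, k)] <- 255
  expect_equal(mean_gray_value(m2), 255 * k / 14400)

  expect_error(mean_gray_value(matrix(numeric(0), 0, 0)), "empty")
})

test_that("regions nest and share a centre", {
  rs <- region_spec()
  expect_identical(rs, c(parafoveal = 120L, perifoveal = 240L))
  expect_error(region_spec(240, 240), "nest")
})

test_that("identical frames quantify to zero leakage", {
  sc <- generate_fa_pair(test_scenario(seed = 13))
  pair <- sc$pair
  pair$frame_5min <- pair$frame_1min
  q <- quantify_eye(pair, quantify_config(max_rotation = 0))
  expect_equal(q$parafoveal_mgv, 0)
  expect_equal(q$perifoveal_mgv, 0)
})

test_that("central leakage scores high, extramacular leakage scores near zero", {
  cfg <- quantify_config(max_rotation = 0)
  central <- generate_fa_pair(test_scenario(seed = 14, n_leak_blobs = 6,
                                            blob_amp_5min = 150,
                                            blob_spread_px = 40))
  q_c <- quantify_eye(central$pair, cfg)
  expect_gt(q_c$perifoveal_mgv, 5)

  outside <- generate_fa_pair(test_scenario(seed = 14, n_leak_blobs = 6,
                                            blob_amp_5min = 150,
                                            blob_sigma_px = 14,
                                            blob_center_offset = c(160, 160),
                                            blob_spread_px = 10))
  q_o <- quantify_eye(outside$pair, cfg)
  expect_gt(sum(outside$truth$leak_mask), 3000) # plenty of whole-image leak
  expect_lt(q_o$parafoveal_mgv, 2)
  expect_lt(q_o$perifoveal_mgv, 2)
})

test_that("on clean static scenes the leakage map lives inside the true mask", {
  p <- scenario_params(image_size = 416, seed = 15, noise_sd = 0,
                       n_vessels = 0, inter_frame_shift = c(0, 0),
                       inter_frame_rotation = 0, blob_amp_1min = 30,
                       blob_amp_5min = 140)
  sc <- generate_fa_pair(p)
  cfg <- quantify_config(max_rotation = 0)

  f1 <- rolling_ball_subtract(sc$pair$frame_1min, cfg$rolling_radius_px)
  f5 <- rolling_ball_subtract(sc$pair$frame_5min, cfg$rolling_radius_px)
  c1 <- crop_centered(f1, sc$pair$fovea, 384)
  c5 <- crop_centered(f5, sc$pair$fovea, 384)
  b1 <- binarize(c1, isodata_default_threshold(c1))
  b5 <- binarize(c5, isodata_default_threshold(c5))
  support <- leakage_map(b5, b1) > 0
  mask <- crop_centered(sc$truth$leak_mask, sc$pair$fovea, 384)

  # no false positives: every flagged pixel is truly leaking
  expect_true(all(mask[support]))
  # the mask minus its sub-threshold pixels is exactly the flagged set
  t5 <- isodata_default_threshold(c5)
  expect_identical(support, mask & (c5 > t5) & !(b1 > 0))
  expect_gt(sum(support), 0)
})

test_that("annulus and shared-threshold variants stay close to the defaults", {
  sc <- generate_fa_pair(test_scenario(seed = 16, blob_amp_5min = 140))
  q_full <- quantify_eye(sc$pair, quantify_config(max_rotation = 0))
  q_ann <- quantify_eye(sc$pair,
                        quantify_config(max_rotation = 0,
                                        perifoveal_annulus = TRUE))
  expect_equal(q_ann$parafoveal_mgv, q_full$parafoveal_mgv)
  # full-square perifoveal score is a pixel-weighted mix of annulus and
  # parafoveal scores
  mixed <- (q_ann$perifoveal_mgv * (240^2 - 120^2) +
            q_full$parafoveal_mgv * 120^2) / 240^2
  expect_equal(q_full$perifoveal_mgv, mixed, tolerance = 1e-9)

  q_shared <- quantify_eye(sc$pair,
                           quantify_config(max_rotation = 0,
                                           shared_threshold = TRUE))
  expect_identical(q_shared$threshold_1min, q_shared$threshold_5min)
})

test_that("grader averaging is the per-region arithmetic mean", {
  a <- structure(list(eye_id = "e1", grader_id = "grader1",
                      parafoveal_mgv = 10, perifoveal_mgv = 30,
                      threshold_1min = 40L, threshold_5min = 41L,
                      alignment = list(rotation = 0, translation = c(0, 0))),
                 class = "leakage_result")
  b <- a
  b$grader_id <- "grader2"
  b$parafoveal_mgv <- 20
  b$perifoveal_mgv <- 10
  avg <- average_graders(a, b)
  expect_equal(avg$parafoveal_mgv, 15)
  expect_equal(avg$perifoveal_mgv, 20)
  expect_identical(avg$grader_id, "averaged")

  avg_rev <- average_graders(b, a)
  expect_equal(avg_rev$parafoveal_mgv, avg$parafoveal_mgv)
  expect_equal(average_graders(a, a)$parafoveal_mgv, a$parafoveal_mgv)

  c_other <- a
  c_other$eye_id <- "e2"
  expect_error(average_graders(a, c_other), "different eyes")
})

test_that("dual-grader averaging reduces score variance under symmetric noise", {
  set.seed(21)
  n <- 1000
  truth <- rep(25, n)
  g1 <- truth + rnorm(n, 0, 4)
  g2 <- truth + rnorm(n, 0, 4)
  expect_lt(var((g1 + g2) / 2), var(g1))
})
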