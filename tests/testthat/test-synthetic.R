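test_that("rendered ground truth is exactly consistent with the rig geometry", {
  spec <- scene_spec(seed = 3)
  sc <- render_stereo_pair(spec)
  rig <- spec$rig
  expect_equal(sc$disparity[sc$region == 0][1],
               rig$baseline_m * rig$focal_px / spec$background_depth_m)
  expect_equal(unique(sc$disparity[sc$masks[[1]]]),
               rig$baseline_m * rig$focal_px / spec$blobs[[1]]$depth_m)
  # blob at 5 m with b = 0.5, f = 1000 has 100 px ground-truth disparity
  spec2 <- scene_spec(width = 160, height = 40, rig = stereo_rig(0.5, 1000),
                      background_depth_m = 50,
                      blobs = list(list(center = c(120, 20), radius = 8, depth_m = 5)),
                      seed = 4)
  sc2 <- render_stereo_pair(spec2)
  expect_equal(unique(sc2$disparity[sc2$masks[[1]]]), 100)
  expect_error(scene_spec(rig = stereo_rig(0.5, 1000),
                          blobs = list(list(center = c(1, 1), radius = 2, depth_m = 3))),
               "disparity")
  expect_error(scene_spec(blobs = list(list(center = c(1, 1), radius = 2, depth_m = 25))),
               "smaller than the background")
})

test_that("rendering is bit-reproducible under a fixed seed", {
  a <- render_stereo_pair(scene_spec(seed = 9))
  b <- render_stereo_pair(scene_spec(seed = 9))
  expect_identical(a, b)
  c <- render_stereo_pair(scene_spec(seed = 10))
  expect_false(identical(a$pair$left, c$pair$left))
  v1 <- render_motion_video(scene_spec(seed = 9), 5)
  v2 <- render_motion_video(scene_spec(seed = 9), 5)
  expect_identical(v1, v2)
})

test_that("matching a rendered scene recovers each region's depth end to end", {
  # integer disparities: background 20 m -> 4 px, blob 5 m -> 16 px (b f = 80)
  spec <- scene_spec(width = 80, height = 60, rig = stereo_rig(0.5, 160),
                     background_depth_m = 20,
                     blobs = list(list(center = c(50, 30), radius = 10, depth_m = 5)),
                     seed = 21)
  sc <- render_stereo_pair(spec)
  vol <- build_cost_volume(sc$pair, max_disparity = 24, patch_half_height = 1)
  disp <- disparity_from_cost_volume(vol)
  depth <- disparity_to_depth(disp, spec$rig)
  # winner-take-all equals ground truth on nearly all matchable pixels whose
  # patch does not straddle a depth discontinuity
  score <- disp == sc$disparity
  ok <- sc$valid & is.finite(disp) & region_interior(sc$region, 1)
  expect_gt(mean(score[ok]), 0.99)
  # mask fusion recovers the blob depth within 2%
  d_blob <- animal_distance_mask(sc$masks[[1]], depth)
  expect_lt(abs(d_blob - 5) / 5, 0.02)
  # bbox fusion: box in which the blob fills >= 50%
  b <- spec$blobs[[1]]
  box <- c(b$center[1] - b$radius, b$center[2] - b$radius,
           b$center[1] + b$radius, b$center[2] + b$radius)
  expect_lt(abs(animal_distance_bbox(box, depth) - 5) / 5, 0.02)
})

test_that("motion videos report the exact foreground-area ratio", {
  spec <- scene_spec(width = 40, height = 30, seed = 6,
                     blobs = list(list(center = c(10, 15), radius = 5, depth_m = 5)))
  v <- render_motion_video(spec, 25, blob_velocity = c(2, 0))
  expect_length(v$frames, 25)
  expect_equal(v$ratios[1], mean(v$frames[[1]] == 1))
  # blob exits right edge: ratios eventually drop to 0
  expect_equal(v$ratios[25], 0)
  expect_true(all(diff(v$ratios[15:25]) <= 1e-12))
})

test_that("night degradation blanks texture and lowers matching confidence", {
  spec <- scene_spec(seed = 14)
  sc <- render_stereo_pair(spec)
  deg0 <- degrade_night(sc$pair, 0)
  expect_identical(deg0$pair, sc$pair)
  expect_false(any(deg0$holes))

  margins <- function(vol) {
    v <- vol$values
    m <- matrix(v, nrow = prod(dim(v)[1:2]), ncol = dim(v)[3])
    m[is.na(m)] <- Inf
    srt <- t(apply(m, 1, sort, partial = 1:2))
    out <- srt[, 2] - srt[, 1]
    out[!is.finite(out)] <- NA
    matrix(out, dim(v)[1], dim(v)[2])
  }
  inside_mean <- c(); outside_mean <- c()
  for (s in 1:5) {
    sc2 <- render_stereo_pair(scene_spec(seed = 100 + s))
    deg <- degrade_night(sc2$pair, 0.25, seed = s)
    mg <- margins(build_cost_volume(deg$pair, 12, 1))
    inside_mean <- c(inside_mean, mean(mg[deg$holes], na.rm = TRUE))
    outside_mean <- c(outside_mean, mean(mg[!deg$holes], na.rm = TRUE))
  }
  expect_true(all(inside_mean < outside_mean))

  # an animal half-covered by holes still fuses to the clean-half depth
  spec3 <- scene_spec(width = 80, height = 60, rig = stereo_rig(0.5, 160),
                      blobs = list(list(center = c(50, 30), radius = 12, depth_m = 5)),
                      seed = 15)
  sc3 <- render_stereo_pair(spec3)
  left <- sc3$pair$left; right <- sc3$pair$right
  holes <- matrix(FALSE, 60, 80); holes[1:30, ] <- TRUE   # top half textureless
  left[holes] <- 0.05; right[holes] <- 0.05
  disp <- disparity_from_cost_volume(
    build_cost_volume(rectified_pair(left, right), 24, 1))
  disp[holes] <- NaN  # ambiguous region marked invalid upstream
  depth <- disparity_to_depth(disp, spec3$rig)
  expect_lt(abs(animal_distance_mask(sc3$masks[[1]], depth) - 5) / 5, 0.02)
})

test_that("noise degrades shift recovery monotonically in expectation", {
  sds <- c(0, 0.05, 0.15, 0.4)
  acc <- sapply(sds, function(sd) {
    mean(sapply(1:6, function(s) {
      pair <- make_shifted_pair(24, 40, shift = 3, seed = 300 + s)
      set.seed(1000 + s)
      noisy <- rectified_pair(pair$left,
                              pmin(pmax(pair$right + rnorm(length(pair$right), sd = sd), 0), 1))
      d <- disparity_from_cost_volume(build_cost_volume(noisy, 6, 1))
      sc <- d[2:23, 4:40]
      mean(sc == 3, na.rm = TRUE)
    }))
  })
  expect_true(all(diff(acc) <= 1e-9))
  expect_equal(acc[1], 1)
})
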