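test_that("a constant video is all-background after burn-in", {
  set.seed(23)
  frame <- matrix(runif(30 * 40, 0, 0.5), 30, 40)
  model <- background_model()
  for (i in 1:55) {
    upd <- update_background(model, frame)
    model <- upd$model
  }
  expect_false(any(upd$foreground))
  expect_error(update_background(model, matrix(0, 3, 3)), "dimensions")
})

test_that("a sudden bright square is flagged foreground on first appearance", {
  set.seed(24)
  bg <- matrix(runif(40 * 50, 0, 0.4), 40, 50)
  model <- background_model()
  for (i in 1:60) model <- update_background(model, bg)$model
  frame <- bg
  frame[11:30, 16:35] <- 0.95
  upd <- update_background(model, frame)
  truth <- matrix(FALSE, 40, 50); truth[11:30, 16:35] <- TRUE
  expect_identical(upd$foreground, truth)
})

test_that("mixture weights stay normalized through every update", {
  set.seed(25)
  model <- background_model()
  for (i in 1:40) {
    frame <- matrix(runif(12 * 15), 12, 15)  # chaotic input forces replacements
    model <- update_background(model, frame)$model
    expect_true(all(abs(rowSums(model$w) - 1) < 1e-9))
    expect_true(all(model$var > 0))
  }
})

test_that("a persistent change is absorbed exactly when the scalar weight oracle says", {
  alpha <- 0.05  # high learning rate so absorption happens quickly
  model <- background_model(learning_rate = alpha)
  bg <- matrix(0.2, 10, 10)
  for (i in 1:30) model <- update_background(model, bg)$model
  frame <- matrix(0.9, 10, 10)  # whole-frame persistent change
  absorbed_at <- NA_integer_
  for (n in 1:500) {
    upd <- update_background(model, frame)
    model <- upd$model
    if (!any(upd$foreground)) { absorbed_at <- n; break }
  }
  expect_equal(absorbed_at, oracle_absorption_frames(alpha, 0.7))
})

test_that("foreground ratio is the plain fraction", {
  m <- matrix(FALSE, 10, 10)
  expect_equal(foreground_ratio(m), 0)
  m[1:5, 1:5] <- TRUE
  expect_equal(foreground_ratio(m), 0.25)
  expect_equal(foreground_ratio(!logical(9) |> matrix(3, 3)), 1)
  expect_error(foreground_ratio(matrix(logical(0), 0, 0)), "empty")
  expect_error(foreground_ratio(matrix(c(0, 2), 1)), "binary")
})

test_that("morphological opening removes salt noise but keeps solid regions", {
  m <- matrix(FALSE, 12, 12)
  m[4:9, 4:9] <- TRUE
  m[1, 12] <- TRUE  # isolated pixel
  o <- morphological_open(m)
  expect_false(o[1, 12])
  expect_true(all(o[5:8, 5:8]))
})

test_that("adaptive sampling follows the stated accumulate-and-reset rule", {
  # 0.04 * 3 = 0.12 >= 0.10 at frame index 2, then nothing further
  expect_equal(adaptive_sample(c(0.04, 0.04, 0.04, 0.04), tau = 0.10), 2L)
  # constant 0.05: every 2nd frame
  expect_equal(adaptive_sample(rep(0.05, 10), tau = 0.10), c(1L, 3L, 5L, 7L, 9L))
  expect_equal(adaptive_sample(rep(0, 50)), integer(0))
  expect_error(adaptive_sample(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("adaptive sampling period is ceil(tau/r) for constant ratios", {
  for (r in c(0.01, 0.025, 0.03, 0.07, 0.1, 0.33)) {
    idx <- adaptive_sample(rep(r, 200), tau = 0.10)
    period <- ceiling(0.10 / r)
    expect_equal(idx, seq(period - 1L, 199L, by = period))
  }
})

test_that("sampling is monotone in motion and inter-selection mass is bounded", {
  set.seed(26)
  for (i in 1:100) {
    ratios <- runif(sample(20:80, 1), 0, 0.45)
    tau <- 0.10
    idx <- adaptive_sample(ratios, tau = tau)
    idx2 <- adaptive_sample(pmin(2 * ratios, 1), tau = tau)
    expect_gte(length(idx2), length(idx))
    expect_true(all(diff(idx) > 0))
    # mass accumulated up to and including each selection is in [tau, tau + 1)
    prev <- 0L
    for (s in idx) {
      mass <- sum(ratios[(prev + 1L):(s + 1L)])
      expect_gte(mass, tau - 1e-9)
      expect_lt(mass, tau + 1)
      prev <- s + 1L
    }
  }
})

test_that("fixed-rate sampling does the stated arithmetic", {
  # 25 s at 30 fps sampled at 2/s: every 15th frame, 50 stills
  idx <- fixed_rate_sample(750, fps = 30, rate_hz = 2)
  expect_equal(length(idx), 50L)
  expect_equal(idx[1:3], c(0L, 15L, 30L))
  expect_equal(fixed_rate_sample(5, fps = 30, rate_hz = 30), 0:4)
  expect_equal(fixed_rate_sample(10, fps = 30, rate_hz = 2), 0L)
  expect_error(fixed_rate_sample(10, fps = 30, rate_hz = 31), "exceeds")
})

test_that("the adaptive chain selects nothing on a static video and samples motion", {
  spec <- scene_spec(width = 40, height = 30, seed = 12,
                     blobs = list(list(center = c(8, 15), radius = 5, depth_m = 5)))
  static <- render_motion_video(spec, 60, blob_velocity = c(0, 0))
  s <- sample_video_adaptive(static$frames, burn_in = 50)
  expect_equal(s$indices, integer(0))
  moving <- render_motion_video(spec, 70, blob_velocity = c(0.5, 0))
  # opening off: slow motion only exposes thin crescents each frame
  s2 <- sample_video_adaptive(moving$frames, burn_in = 50, opening = FALSE)
  expect_gt(length(s2$indices), 0)
  expect_true(all(s2$indices >= 50))
})
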