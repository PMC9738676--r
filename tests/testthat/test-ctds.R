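test_that("binning truncates and uses left-closed bins with a closed last edge", {
  ds <- distance_dataset(c(2.5, 3.0, 4.0, 4.142, 4.143, 10.9, 11.0, 11.5))
  expect_equal(ds$bin_edges[2] - ds$bin_edges[1], 8 / 7)
  n <- bin_distances(ds)
  expect_equal(sum(n), 6L)            # 2.5 and 11.5 truncated
  expect_equal(n[1], 3L)              # 3.0, 4.0 and 4.142 (< 3 + 8/7 = 4.1428..)
  expect_equal(n[2], 1L)              # 4.143
  expect_equal(n[7], 2L)              # 10.9 and the closed right edge 11.0
  expect_error(bin_distances(distance_dataset(c(1, 12))), "outside")
})

test_that("the uniform+cosine detection function matches its closed forms", {
  m0 <- detection_function("uniform", 1L, coefficients = 0)
  expect_equal(detection_g(m0, c(3, 5, 7, 11)), rep(1, 4))
  m <- detection_function("uniform", 1L, coefficients = 0.5)
  expect_equal(detection_g(m, 3), 1)            # (1 + 0.5) / 1.5
  expect_equal(detection_g(m, 11), 1 / 3)       # (1 - 0.5) / 1.5
  expect_equal(detection_g(m, 7), 1 / 1.5)      # cos(pi/2) = 0
  hn <- detection_function("half-normal", sigma = 5, left_trunc = 0, right_trunc = 20)
  expect_equal(detection_g(hn, 5), exp(-0.5))
  expect_error(detection_g(m, 2), "truncation")
  expect_error(detection_function("uniform", 1L, coefficients = -1.5), "positive")
})

test_that("uniform-g bin probabilities equal closed-form annulus areas", {
  m0 <- detection_function("uniform", 1L, coefficients = 0)
  p <- expected_bin_probabilities(m0)
  e <- seq(3, 11, length.out = 8)
  annulus <- diff(e^2) / (11^2 - 3^2)
  expect_equal(p, annulus, tolerance = 1e-6)
  expect_equal(p[1], (400 / 49) / 112, tolerance = 1e-6)
  expect_equal(sum(p), 1, tolerance = 1e-9)
})

test_that("Simpson integrals agree with a dense Riemann oracle", {
  models <- list(
    detection_function("uniform", 1L, coefficients = 0.5),
    detection_function("uniform", c(1L, 2L), coefficients = c(0.3, 0.1)),
    detection_function("half-normal", sigma = 6, left_trunc = 3, right_trunc = 11))
  for (m in models) {
    p <- expected_bin_probabilities(m)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    e <- seq(3, 11, length.out = 8)
    num <- vapply(1:7, function(k) oracle_riemann(function(r)
      r * detection_g(m, r), e[k], e[k + 1]), numeric(1))
    expect_equal(p, num / sum(num), tolerance = 1e-6)
    pbar <- average_detection_probability(m)
    expect_equal(pbar,
                 oracle_riemann(function(r) 2 * r * detection_g(m, r), 3, 11) / (121 - 9),
                 tolerance = 1e-6)
    expect_gt(pbar, 0); expect_lte(pbar, 1 + 1e-9)
  }
})

test_that("annulus-proportional counts give a1 = 0 and average probability 1", {
  ds <- distance_dataset(numeric(0) + 5)  # design only; distances unused by the fit
  e <- ds$bin_edges
  counts <- diff(e^2) / 2 * 1000
  fit <- fit_detection_function(counts, ds)
  expect_lt(abs(fit$par), 1e-4)
  expect_equal(fit$average_p, 1, tolerance = 1e-6)
  expect_true(fit$boundary)  # a = 0 sits on the g <= 1 feasibility boundary
})

test_that("simulated cosine-detection distances are recovered by the fit", {
  true <- detection_function("uniform", 1L, coefficients = 0.5)
  d <- simulate_distances(true, 5000, seed = 2024)
  expect_true(all(d >= 3 & d <= 11))
  ds <- distance_dataset(d)
  fit <- fit_detection_function(bin_distances(ds), ds)
  expect_lt(abs(fit$par - 0.5), 0.1)
  expect_equal(sum(fit$p_k), 1, tolerance = 1e-9)
  # likelihood dominance: MLE beats the generating parameters
  p_true <- expected_bin_probabilities(true, ds$bin_edges)
  expect_gte(fit$loglik, sum(bin_distances(ds) * log(p_true)) - 1e-9)
  # AIC bookkeeping
  expect_equal(fit$aic, 2 - 2 * fit$loglik)
})

test_that("the optimizer matches an exhaustive grid-search oracle", {
  true <- detection_function("uniform", 1L, coefficients = 0.35)
  d <- simulate_distances(true, 1500, seed = 77)
  ds <- distance_dataset(d)
  counts <- bin_distances(ds)
  fit <- fit_detection_function(counts, ds)
  oracle <- oracle_grid_mle(counts, ds$bin_edges, 3, 11, step = 5e-3, n_riemann = 4000)
  expect_lt(abs(fit$par - oracle$a), 5e-3)
})

test_that("simulation is reproducible and uniform-g distances follow annulus geometry", {
  m0 <- detection_function("uniform", 1L, coefficients = 0)
  expect_identical(simulate_distances(m0, 100, seed = 5),
                   simulate_distances(m0, 100, seed = 5))
  d1 <- simulate_distances(m0, 1, seed = 6)
  expect_true(d1 >= 3 && d1 <= 11)
  # under g = 1, r^2 is uniform on [w_l^2, w_r^2]
  d <- simulate_distances(m0, 10000, seed = 8)
  ks <- suppressWarnings(stats::ks.test(d^2, "punif", 9, 121))
  expect_gt(ks$p.value, 0.01)
})

test_that("multi-order and half-normal fits converge on matched simulations", {
  hn <- detection_function("half-normal", sigma = 6, left_trunc = 3, right_trunc = 11)
  d <- simulate_distances(hn, 4000, seed = 31)
  ds <- distance_dataset(d)
  fit <- fit_detection_function(bin_distances(ds), ds, key = "half-normal")
  expect_lt(abs(fit$model$sigma - 6) / 6, 0.15)
  true2 <- detection_function("uniform", c(1L, 2L), coefficients = c(0.4, 0.1))
  d2 <- simulate_distances(true2, 6000, seed = 32)
  ds2 <- distance_dataset(d2)
  fit2 <- fit_detection_function(bin_distances(ds2), ds2, adjustment_orders = c(1L, 2L))
  expect_equal(sum(fit2$p_k), 1, tolerance = 1e-9)
  g_grid <- detection_g(fit2$model, seq(3, 11, length.out = 200))
  expect_true(all(g_grid >= -1e-6 & g_grid <= 1 + 1e-6))
  expect_lt(abs(fit2$par[1] - 0.4), 0.2)
})

test_that("estimator bias shrinks as n grows (consistency, averaged over replicates)", {
  true <- detection_function("uniform", 1L, coefficients = 0.5)
  est <- function(n, seeds) vapply(seeds, function(s) {
    d <- simulate_distances(true, n, seed = s)
    ds <- distance_dataset(d)
    fit_detection_function(bin_distances(ds), ds)$par
  }, numeric(1))
  small <- est(400, 1:30)
  large <- est(8000, 101:130)
  expect_lt(abs(mean(large) - 0.5), abs(mean(small) - 0.5) + 0.02)
  expect_lt(stats::sd(large), stats::sd(small))
})
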