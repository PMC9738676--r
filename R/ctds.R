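#' Distance dataset for camera-trap distance sampling
#'
#' Holds observation distances together with the analysis design: left and
#' right truncation distances and a number of equally spaced distance
#' intervals between them. The default design is 7 intervals from 3 m to
#' 11 m: the left truncation reflects the closest distance at which animals
#' are certain to be visible given the camera mounting, and distances are
#' not re-scaled by it because animals may be present nearer the camera but
#' outside the field of view.
#'
#' @param distances_m Numeric vector of observation distances in meters
#'   (`NA` entries are dropped).
#' @param left_trunc,right_trunc Truncation distances `w_l < w_r` in m.
#' @param n_bins Number of equal-width intervals `K >= 1`.
#' @return An object of class `distance_dataset` with `distances_m`,
#'   `left_trunc`, `right_trunc`, `n_bins` and `bin_edges` (length `K + 1`).
#' @export
distance_dataset <- function(distances_m, left_trunc = 3, right_trunc = 11,
                             n_bins = 7L) {
  stopifnot(is.numeric(distances_m), left_trunc >= 0,
            left_trunc < right_trunc, n_bins >= 1L)
  distances_m <- distances_m[!is.na(distances_m)]
  structure(list(distances_m = as.numeric(distances_m),
                 left_trunc = left_trunc, right_trunc = right_trunc,
                 n_bins = as.integer(n_bins),
                 bin_edges = seq(left_trunc, right_trunc, length.out = n_bins + 1L)),
            class = "distance_dataset")
}

#' Bin observation distances into the design intervals
#'
#' Distances below the left or above the right truncation are excluded.
#' Bins are left-closed, right-open, except the last bin which is closed on
#' both sides (so an observation exactly at the right truncation counts).
#'
#' @param ds A [distance_dataset()].
#' @return Integer vector of counts `n_k`, one per bin.
#' @export
bin_distances <- function(ds) {
  stopifnot(inherits(ds, "distance_dataset"))
  d <- ds$distances_m
  d <- d[d >= ds$left_trunc & d <= ds$right_trunc]
  if (length(d) == 0L) stop("all distances fall outside the truncation range")
  e <- ds$bin_edges
  idx <- findInterval(d, e, rightmost.closed = TRUE)  # last bin closed
  tabulate(idx, nbins = ds$n_bins)
}

#' Detection-function model
#'
#' A parametric model for the detection probability `g(r)` of an animal
#' present at distance `r` inside the truncation range:
#' * uniform key with cosine adjustments:
#'   `g(r) = (1 + sum_j a_j cos(j pi r_s)) / (1 + sum_j a_j)` with the
#'   left-truncation-shifted scaled distance
#'   `r_s = (r - w_l) / (w_r - w_l)`, so that `g(w_l) = 1` by construction;
#' * half-normal: `g(r) = exp(-r^2 / (2 sigma^2))`.
#'
#' @param key `"uniform"` or `"half-normal"`.
#' @param adjustment_orders Integer vector of cosine orders `J` for the
#'   uniform key (default `1`, a single term).
#' @param coefficients Cosine coefficients `a_j`, one per order.
#' @param sigma Half-normal scale in m.
#' @param left_trunc,right_trunc Truncation range in m.
#' @return An object of class `detection_function`.
#' @export
detection_function <- function(key = c("uniform", "half-normal"),
                               adjustment_orders = 1L, coefficients = 0,
                               sigma = NULL, left_trunc = 3, right_trunc = 11) {
  key <- match.arg(key)
  stopifnot(left_trunc >= 0, left_trunc < right_trunc)
  if (key == "uniform") {
    adjustment_orders <- as.integer(adjustment_orders)
    stopifnot(length(coefficients) == length(adjustment_orders))
    if (1 + sum(coefficients) <= 0)
      stop("1 + sum(a_j) must be positive")
  } else {
    stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
    adjustment_orders <- integer(0)
    coefficients <- numeric(0)
  }
  structure(list(key = key, adjustment_orders = adjustment_orders,
                 coefficients = as.numeric(coefficients), sigma = sigma,
                 left_trunc = left_trunc, right_trunc = right_trunc),
            class = "detection_function")
}

#' Evaluate the detection function
#'
#' @param model A [detection_function()].
#' @param r Distances in m; all must lie inside the truncation range.
#' @return Detection probabilities `g(r)`.
#' @examples
#' m <- detection_function("uniform", 1L, coefficients = 0.5)
#' detection_g(m, c(3, 11))  # 1 at the left truncation, 1/3 at the right
#' @export
detection_g <- function(model, r) {
  stopifnot(inherits(model, "detection_function"))
  if (any(r < model$left_trunc - 1e-12 | r > model$right_trunc + 1e-12))
    stop("r outside the truncation range")
  if (model$key == "uniform") {
    rs <- (r - model$left_trunc) / (model$right_trunc - model$left_trunc)
    num <- 1
    for (k in seq_along(model$adjustment_orders))
      num <- num + model$coefficients[k] * cos(model$adjustment_orders[k] * pi * rs)
    num / (1 + sum(model$coefficients))
  } else {
    exp(-r^2 / (2 * model$sigma^2))
  }
}

# Composite Simpson quadrature, interval count doubled until the relative
# change is below rel_tol.
simpson_quad <- function(f, a, b, rel_tol = 1e-8, n0 = 16L, max_doublings = 16L) {
  stopifnot(b > a)
  n <- as.integer(n0)
  simp <- function(n) {
    x <- seq(a, b, length.out = n + 1L)
    y <- f(x)
    h <- (b - a) / n
    h / 3 * (y[1L] + y[n + 1L] +
               4 * sum(y[seq(2L, n, by = 2L)]) +
               2 * sum(y[seq(3L, n - 1L, by = 2L)]))
  }
  prev <- simp(n)
  for (i in seq_len(max_doublings)) {
    n <- n * 2L
    cur <- simp(n)
    if (abs(cur - prev) <= rel_tol * max(abs(cur), .Machine$double.eps))
      return(cur)
    prev <- cur
  }
  prev
}

#' Expected bin probabilities under point-transect geometry
#'
#' For a camera observing an annular field around it, the area element at
#' distance `r` grows linearly in `r`, so the probability that a detected
#' animal falls into bin `k` is
#' `p_k = int_bin r g(r) dr / int_{w_l}^{w_r} r g(r) dr`.
#' (The camera's angular field of view multiplies both integrals and
#' cancels.) Integrals use composite Simpson quadrature with relative
#' tolerance 1e-8.
#'
#' @param model A [detection_function()].
#' @param bin_edges Strictly increasing edges spanning the truncation range;
#'   defaults to 7 equal bins.
#' @return Numeric vector of probabilities summing to 1.
#' @export
expected_bin_probabilities <- function(model,
                                       bin_edges = seq(model$left_trunc,
                                                       model$right_trunc,
                                                       length.out = 8L)) {
  stopifnot(inherits(model, "detection_function"),
            all(diff(bin_edges) > 0),
            abs(bin_edges[1L] - model$left_trunc) < 1e-9,
            abs(bin_edges[length(bin_edges)] - model$right_trunc) < 1e-9)
  f <- function(r) r * detection_g(model, r)
  num <- vapply(seq_len(length(bin_edges) - 1L), function(k)
    simpson_quad(f, bin_edges[k], bin_edges[k + 1L]), numeric(1L))
  den <- sum(num)
  if (den <= 0) stop("degenerate detection function: total integral is zero")
  num / den
}

#' Average detection probability over the truncated annulus
#'
#' The area-weighted mean of `g`:
#' `P = int_{w_l}^{w_r} g(r) 2 r dr / (w_r^2 - w_l^2)`.
#'
#' @param model A [detection_function()].
#' @return Scalar in `(0, 1]`.
#' @export
average_detection_probability <- function(model) {
  stopifnot(inherits(model, "detection_function"))
  num <- simpson_quad(function(r) 2 * r * detection_g(model, r),
                      model$left_trunc, model$right_trunc)
  num / (model$right_trunc^2 - model$left_trunc^2)
}

# g evaluated on a parameter vector without constructing a model object;
# used inside the fit. Uniform key only.
g_uniform_raw <- function(a, orders, rs) {
  num <- rep(1, length(rs))
  for (k in seq_along(orders)) num <- num + a[k] * cos(orders[k] * pi * rs)
  num / (1 + sum(a))
}

#' Fit a detection function to binned distance counts
#'
#' Maximizes the binned multinomial log-likelihood
#' `l(theta) = sum_k n_k log p_k(theta)` over the detection-function
#' parameters, subject to `0 <= g(r) <= 1` checked on a 512-point grid over
#' the truncation range. For the uniform key the bin probabilities are
#' linear-fractional in the coefficients (the moment integrals are computed
#' once), so the likelihood is cheap; a single cosine order is fitted by a
#' dense feasible grid followed by local refinement, and multi-order specs
#' by multi-start Nelder-Mead with an infeasibility penalty. The
#' half-normal scale is fitted by bounded search over `log sigma`.
#'
#' @param counts Integer bin counts `n_k` (from [bin_distances()]).
#' @param ds A [distance_dataset()] supplying edges and truncations (its
#'   distances are ignored; only the design matters here).
#' @param key `"uniform"` or `"half-normal"`.
#' @param adjustment_orders Cosine orders for the uniform key (default 1).
#' @return An object of class `detection_fit`: `model` (the fitted
#'   [detection_function()]), `par`, `loglik`, `aic`, `p_k`, `n_k`,
#'   `chisq` (statistic, df, p_value), `average_p`, `boundary` (`TRUE` when
#'   the optimum sits on the feasibility boundary).
#' @export
fit_detection_function <- function(counts, ds, key = c("uniform", "half-normal"),
                                   adjustment_orders = 1L) {
  key <- match.arg(key)
  stopifnot(inherits(ds, "distance_dataset"))
  counts <- as.numeric(counts)
  if (length(counts) != ds$n_bins) stop("counts length must equal n_bins")
  if (any(counts < 0) || sum(counts) < 1) stop("need at least one counted observation")
  e <- ds$bin_edges
  wl <- ds$left_trunc; wr <- ds$right_trunc
  K <- ds$n_bins
  grid_rs <- seq(0, 1, length.out = 512L)

  if (key == "uniform") {
    orders <- as.integer(adjustment_orders)
    J <- length(orders)
    # moment integrals: p_k(a) = (A_k + sum_j a_j B_jk) / (A + sum_j a_j B_j)
    A_k <- (e[-1L]^2 - e[-(K + 1L)]^2) / 2
    B <- matrix(0, J, K)
    for (j in seq_len(J)) for (k in seq_len(K)) {
      B[j, k] <- simpson_quad(function(r)
        r * cos(orders[j] * pi * (r - wl) / (wr - wl)), e[k], e[k + 1L])
    }
    feasible <- function(a) {
      if (1 + sum(a) <= 1e-12) return(FALSE)
      g <- g_uniform_raw(a, orders, grid_rs)
      all(g >= -1e-9) && all(g <= 1 + 1e-9)
    }
    loglik <- function(a) {
      num <- A_k + as.numeric(crossprod(a, B))
      den <- sum(num)
      if (den <= 0 || any(num <= 0)) return(-Inf)
      sum(counts * log(num / den))
    }
    pen <- function(a) {
      v <- if (feasible(a)) loglik(a) else -Inf
      if (is.finite(v)) v else -1e18  # finite penalty keeps optimize() quiet
    }
    if (J == 1L) {
      grid_a <- seq(-0.999, 0.999, by = 0.002)
      vals <- vapply(grid_a, pen, numeric(1L))
      if (all(vals <= -1e17)) stop("no feasible coefficient value found")
      a0 <- grid_a[which.max(vals)]
      opt <- stats::optimize(function(a) pen(a),
                             interval = c(a0 - 0.002, a0 + 0.002),
                             maximum = TRUE, tol = 1e-9)
      par <- opt$maximum
      ll <- opt$objective
      # the feasible set may end exactly at the grid point (e.g. a = 0)
      if (ll < vals[which.max(vals)]) { par <- a0; ll <- max(vals) }
    } else {
      best <- NULL
      # fixed start set keeps the fit fully deterministic
      starts <- rbind(rep(0, J), diag(0.3, J),
                      rep(0.15, J), rep(0.45, J))
      for (s in seq_len(nrow(starts))) {
        o <- stats::optim(starts[s, ], function(a) -pen(a),
                          method = "Nelder-Mead",
                          control = list(reltol = 1e-10, maxit = 5000L))
        if (is.null(best) || o$value < best$value) best <- o
      }
      if (best$value >= 1e17) stop("optimizer failed to find a feasible optimum")
      par <- best$par
      ll <- -best$value
    }
    if (!is.finite(ll)) stop("non-convergence: log-likelihood not finite at optimum")
    # boundary = the optimum sits at the edge of the feasible coefficient set
    # (g(w_l) = 1 holds identically for this key and is not a binding constraint)
    boundary <- any(vapply(seq_along(par), function(j) {
      up <- par; up[j] <- up[j] + 1e-6
      dn <- par; dn[j] <- dn[j] - 1e-6
      !feasible(up) || !feasible(dn)
    }, logical(1L)))
    model <- detection_function("uniform", orders, coefficients = par,
                                left_trunc = wl, right_trunc = wr)
    npar <- J
  } else {
    p_of_sigma <- function(sg) {
      m <- detection_function("half-normal", sigma = sg,
                              left_trunc = wl, right_trunc = wr)
      expected_bin_probabilities(m, e)
    }
    nll <- function(logsg) {
      p <- p_of_sigma(exp(logsg))
      if (any(p <= 0)) return(Inf)
      -sum(counts * log(p))
    }
    opt <- stats::optimize(nll, interval = log(c(0.05 * wr, 50 * wr)), tol = 1e-9)
    par <- exp(opt$minimum)
    ll <- -opt$objective
    boundary <- abs(opt$minimum - log(50 * wr)) < 1e-6 ||
      abs(opt$minimum - log(0.05 * wr)) < 1e-6
    model <- detection_function("half-normal", sigma = par,
                                left_trunc = wl, right_trunc = wr)
    npar <- 1L
  }
  p_k <- expected_bin_probabilities(model, e)
  n_tot <- sum(counts)
  expct <- n_tot * p_k
  chisq_stat <- sum((counts - expct)^2 / expct)
  chisq_df <- K - 1L - npar
  structure(list(model = model, par = par, loglik = ll,
                 aic = 2 * npar - 2 * ll, p_k = p_k, n_k = counts,
                 chisq = list(statistic = chisq_stat, df = chisq_df,
                              p_value = if (chisq_df >= 1L)
                                stats::pchisq(chisq_stat, chisq_df, lower.tail = FALSE)
                              else NA_real_),
                 average_p = average_detection_probability(model),
                 boundary = boundary),
            class = "detection_fit")
}

#' @export
print.detection_fit <- function(x, ...) {
  m <- x$model
  cat(sprintf("<detection_fit> %s key", m$key))
  if (m$key == "uniform")
    cat(sprintf(", cosine order(s) %s, a = %s",
                paste(m$adjustment_orders, collapse = ","),
                paste(sprintf("%.4f", m$coefficients), collapse = ", ")))
  else cat(sprintf(", sigma = %.4f m", m$sigma))
  cat(sprintf("\n  logLik %.4f, AIC %.4f, average detection probability %.4f\n",
              x$loglik, x$aic, x$average_p))
  cat(sprintf("  chi-square GOF %.4f on %d df%s%s\n", x$chisq$statistic, x$chisq$df,
              if (is.na(x$chisq$p_value)) "" else sprintf(" (p = %.4f)", x$chisq$p_value),
              if (x$boundary) " [boundary-constrained]" else ""))
  invisible(x)
}

#' Simulate observation distances from a detection-function model
#'
#' Draws i.i.d. distances from the detection-weighted point-transect density
#' `f(r) proportional to r g(r)` on the truncation range, by rejection
#' sampling with a uniform proposal (the envelope `r g(r) <= w_r` is exact
#' because `g <= 1`). Reproducible under a fixed seed.
#'
#' @param model A [detection_function()].
#' @param n Number of draws.
#' @param seed Optional integer seed (applied via `set.seed`).
#' @return Numeric vector of `n` distances in `[w_l, w_r]`.
#' @export
simulate_distances <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "detection_function"), n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  wl <- model$left_trunc; wr <- model$right_trunc
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(64L, as.integer(2.5 * (n - length(out))))
    r <- stats::runif(m, wl, wr)
    u <- stats::runif(m)
    acc <- u <= r * detection_g(model, r) / wr
    out <- c(out, r[acc])
  }
  out[seq_len(n)]
}
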