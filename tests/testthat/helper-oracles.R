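# Independent brute-force oracles. These deliberately re-derive results with
# the dumbest possible loops so they share no code path with the package.

# Eq-style SSD cost volume via explicit loops; d is 0-based, coordinates are
# 1-based matrix indices. Returns H x W x D array with NA where the patch or
# the shifted column leaves the image.
oracle_cost_volume <- function(left, right, D, c, square = FALSE) {
  h <- nrow(left); w <- ncol(left)
  out <- array(NA_real_, c(h, w, D))
  dxs <- if (square) -c:c else 0L
  for (d in 0:(D - 1L)) for (j in seq_len(h)) for (i in seq_len(w)) {
    if (j - c < 1L || j + c > h) next
    if (i - d < 1L) next
    if (square && (i - c < 1L || i + c > w || i - d - c < 1L)) next
    s <- 0
    bad <- FALSE
    for (dj in -c:c) for (di in dxs) {
      if (i + di > w || i - d + di < 1L) { bad <- TRUE; break }
      s <- s + (left[j + dj, i + di] - right[j + dj, i - d + di])^2
    }
    if (!bad) out[j, i, d + 1L] <- s
  }
  out
}

# zero-flow temporal instability by direct summation
oracle_et_zero_flow <- function(frames) {
  total <- 0
  for (n in 2:length(frames)) {
    diffs <- c()
    for (j in seq_len(nrow(frames[[n]]))) for (i in seq_len(ncol(frames[[n]]))) {
      a <- frames[[n]][j, i]; b <- frames[[n - 1]][j, i]
      if (is.finite(a) && is.finite(b)) diffs <- c(diffs, abs(a - b))
    }
    total <- total + mean(diffs)
  }
  total / (length(frames) - 1)
}

# exhaustive block SSD search at one block (1-based corner indices)
oracle_block_displacement <- function(prev, nxt, r0, r1, c0, c1, range) {
  best <- Inf; bd <- c(0L, 0L)
  for (dy in -range:range) for (dx in -range:range) {
    pr <- (r0:r1) - dy; pc <- (c0:c1) - dx
    if (min(pr) < 1 || max(pr) > nrow(prev) || min(pc) < 1 || max(pc) > ncol(prev)) next
    ssd <- sum((nxt[r0:r1, c0:c1] - prev[pr, pc])^2)
    if (ssd < best) { best <- ssd; bd <- c(dx, dy) }
  }
  bd
}

# scalar replica of one pixel's mixture-weight dynamics after a persistent
# intensity change: returns the number of frames (counting from the change)
# until the new component is labelled background.
oracle_absorption_frames <- function(alpha, bg_threshold, max_frames = 10000L) {
  # frame 1 (the change): replacement. weights before: (1, 0, 0).
  w <- c(1, 0, 0)
  w <- (1 - alpha) * w
  w[3] <- alpha           # lowest-weight slot (ties resolved to the last)
  w <- w / sum(w)
  for (n in 2:max_frames) {
    # label uses pre-update weights: component 3 is background iff the
    # cumulative weight of strictly higher-ranked components is <= threshold
    above <- sum(w[w > w[3]])
    if (above <= bg_threshold) return(n)
    w <- (1 - alpha) * w
    w[3] <- w[3] + alpha
    w <- w / sum(w)
  }
  NA_integer_
}

# midpoint Riemann sum
oracle_riemann <- function(f, a, b, n = 1e6) {
  x <- seq(a + (b - a) / (2 * n), b - (b - a) / (2 * n), length.out = n)
  sum(f(x)) * (b - a) / n
}

# pixels whose (2c+1)-tall column patch sees a single depth region; region
# boundary pixels have no single correct disparity under a patch matcher
region_interior <- function(region, c) {
  h <- nrow(region); w <- ncol(region)
  ok <- matrix(FALSE, h, w)
  rows <- (1 + c):(h - c)
  inner <- matrix(TRUE, length(rows), w)
  for (dy in -c:c) inner <- inner & region[rows + dy, , drop = FALSE] == region[rows, , drop = FALSE]
  ok[rows, ] <- inner
  ok
}

# constant-shift stereo pair: right[, x - s] = left[, x]; dis-occluded right
# columns get fresh texture. Left columns s+1..w have a valid correspondence.
make_shifted_pair <- function(h, w, shift, seed) {
  set.seed(seed)
  left <- matrix(runif(h * w), h, w)
  right <- cbind(left[, (shift + 1):w, drop = FALSE],
                 matrix(runif(h * shift), h, shift))
  rectified_pair(left, right)
}

# grid-search MLE oracle for the single-cosine uniform key: bin expectations
# by midpoint Riemann sums, feasibility checked on its own dense grid.
oracle_grid_mle <- function(counts, edges, wl, wr, step = 1e-3, n_riemann = 2e4) {
  K <- length(edges) - 1L
  gfun <- function(a, r) {
    rs <- (r - wl) / (wr - wl)
    (1 + a * cos(pi * rs)) / (1 + a)
  }
  rs_chk <- seq(wl, wr, length.out = 1001L)
  num_k <- function(a) vapply(seq_len(K), function(k)
    oracle_riemann(function(r) r * gfun(a, r), edges[k], edges[k + 1L], n_riemann),
    numeric(1))
  grid <- seq(-0.999, 0.999, by = step)
  best_a <- NA_real_; best_ll <- -Inf
  for (a in grid) {
    g <- gfun(a, rs_chk)
    if (any(g < -1e-9) || any(g > 1 + 1e-9)) next
    nk <- num_k(a)
    p <- nk / sum(nk)
    if (any(p <= 0)) next
    ll <- sum(counts * log(p))
    if (ll > best_ll) { best_ll <- ll; best_a <- a }
  }
  list(a = best_a, loglik = best_ll)
}
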