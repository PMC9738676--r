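#' Pointwise disparity errors against rangefinder ground truth
#'
#' Compares a predicted disparity map with sparse ground-truth points whose
#' distances were measured in meters (e.g. by laser rangefinder). Both sides
#' are compared in disparity space: each ground-truth distance is converted
#' to a disparity through the rig geometry (`d = b f / z`), so errors are in
#' px and far-field error is not quadratically amplified.
#'
#' @param pred `H x W` predicted disparity matrix (`NaN` = invalid).
#' @param rig A [stereo_rig()].
#' @param points A data.frame with columns `x`, `y` (0-based pixel
#'   coordinates, `x` = column) and `distance_m` (> 0).
#' @return A data.frame with one row per point: `x`, `y`, `distance_m`,
#'   `gt_disparity`, `pred_disparity`, `error` (px, `NA` when the point
#'   falls on an invalid pixel; such points are excluded from aggregates
#'   with a warning).
#' @seealso [disparity_error_summary()]
#' @export
pointwise_errors <- function(pred, rig, points) {
  assert_rig(rig)
  stopifnot(is.matrix(pred), is.data.frame(points),
            all(c("x", "y", "distance_m") %in% names(points)))
  if (any(points$distance_m <= 0)) stop("ground-truth distances must be > 0")
  x <- as.integer(points$x); y <- as.integer(points$y)
  if (any(x < 0L | x >= ncol(pred) | y < 0L | y >= nrow(pred)))
    stop("ground-truth point outside the image")
  gt_disp <- rig$baseline_m * rig$focal_px / points$distance_m
  pd <- pred[cbind(y + 1L, x + 1L)]
  err <- pd - gt_disp
  n_missing <- sum(!is.finite(pd))
  if (n_missing > 0L)
    warning(sprintf("%d ground-truth point(s) fall on invalid pixels and are excluded", n_missing))
  data.frame(x = x, y = y, distance_m = points$distance_m,
             gt_disparity = gt_disp, pred_disparity = pd,
             error = ifelse(is.finite(pd), err, NA_real_))
}

#' Aggregate disparity errors into RMSE and EPE
#'
#' EPE (endpoint error) for scalar disparities is the mean absolute error;
#' RMSE is the root mean squared error. RMSE >= EPE always (power-mean
#' inequality), with equality exactly when all absolute errors are equal.
#'
#' @param errors Numeric vector of per-point disparity errors in px, or the
#'   data.frame returned by [pointwise_errors()] (its `error` column is
#'   used; `NA` rows are dropped).
#' @return A list with `rmse`, `epe` (px), `n_used`, `n_missing`.
#' @examples
#' disparity_error_summary(c(1, 2, 3))  # EPE 2, RMSE sqrt(14/3)
#' @export
disparity_error_summary <- function(errors) {
  if (is.data.frame(errors)) errors <- errors$error
  n_total <- length(errors)
  e <- errors[is.finite(errors)]
  if (length(e) == 0L) stop("no valid errors to aggregate")
  list(rmse = sqrt(mean(e^2)), epe = mean(abs(e)),
       n_used = length(e), n_missing = n_total - length(e))
}

#' Flow-compensated temporal stability of a disparity sequence
#'
#' For consecutive disparity frames `D(., ., n)` and per-pair optical flow
#' `(m_x, m_y)` (flow from frame `n` back to frame `n - 1`), computes the
#' mean flow-compensated absolute temporal difference
#' \deqn{E_t = \frac{1}{(N_T-1) N_P} \sum_{n=2}^{N_T} \sum_{(x,y)}
#'   |D(x,y,n) - D(x - m_x, y - m_y, n-1)|}
#' The warped coordinate is resolved by nearest-neighbour lookup (integer
#' rounding). Pixels that warp outside the frame, onto an invalid previous
#' value, or that are invalid in the current frame are skipped and the
#' per-term pixel count `N_P` is reduced accordingly (the border treatment
#' is a documented convention of this implementation).
#'
#' @param frames List of `N_T >= 2` disparity matrices (equal dimensions).
#' @param flows Optional list of `N_T - 1` flow fields; element `n` is a
#'   list with matrices `x` and `y`, the flow from frame `n + 1` to frame
#'   `n`. `NULL` means zero flow, reducing `E_t` to the mean absolute
#'   temporal difference.
#' @return The scalar temporal instability `E_t` in px (0 = perfectly
#'   stable).
#' @export
temporal_quality <- function(frames, flows = NULL) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("need at least 2 disparity frames")
  dims <- dim(frames[[1L]])
  for (f in frames) if (!is.matrix(f) || !all(dim(f) == dims))
    stop("all frames must be matrices of identical dimensions")
  if (!is.null(flows) && length(flows) != length(frames) - 1L)
    stop("need exactly one flow field per consecutive frame pair")
  h <- dims[1L]; w <- dims[2L]
  xs <- matrix(rep(0:(w - 1L), each = h), h, w)   # 0-based column index
  ys <- matrix(rep(0:(h - 1L), times = w), h, w)  # 0-based row index
  terms <- numeric(length(frames) - 1L)
  for (n in 2:length(frames)) {
    cur <- frames[[n]]; prv <- frames[[n - 1L]]
    if (is.null(flows)) {
      mx <- 0; my <- 0
    } else {
      fl <- flows[[n - 1L]]
      mx <- fl$x; my <- fl$y
      if (!all(dim(mx) == dims) || !all(dim(my) == dims))
        stop("flow field dimensions must match the frames")
    }
    wx <- round(xs - mx); wy <- round(ys - my)
    inb <- wx >= 0 & wx < w & wy >= 0 & wy < h & is.finite(wx) & is.finite(wy)
    prev_val <- rep(NaN, h * w)
    prev_val[inb] <- prv[cbind(wy[inb] + 1L, wx[inb] + 1L)]
    diff <- abs(as.numeric(cur) - prev_val)
    ok <- is.finite(diff)
    if (!any(ok)) stop(sprintf("no comparable pixels between frames %d and %d", n - 1L, n))
    terms[n - 1L] <- mean(diff[ok])
  }
  mean(terms)
}

#' Integer block-matching optical flow (fallback estimator)
#'
#' A deliberately simple flow estimator used when no external flow fields
#' are supplied to [temporal_quality()]: the image is tiled into square
#' blocks and each block of the *next* frame is matched against the
#' *previous* frame by exhaustive SSD search over integer displacements in
#' `[-range, range]^2`. The returned flow is constant within each block and
#' points from the next frame back to the previous one (the convention
#' [temporal_quality()] expects).
#'
#' @param prev_frame,next_frame Equal-size numeric matrices.
#' @param block Block edge length in px (must not exceed either image
#'   dimension).
#' @param range Search radius in px.
#' @return A list of `H x W` matrices `x` and `y`.
#' @export
fallback_flow <- function(prev_frame, next_frame, block = 16L, range = 8L) {
  stopifnot(is.matrix(prev_frame), is.matrix(next_frame),
            all(dim(prev_frame) == dim(next_frame)))
  h <- nrow(prev_frame); w <- ncol(prev_frame)
  block <- as.integer(block); range <- as.integer(range)
  if (block > h || block > w) stop("block size exceeds image dimensions")
  if (block < 1L || range < 0L) stop("block must be >= 1 and range >= 0")
  mx <- matrix(0, h, w); my <- matrix(0, h, w)
  # candidate displacements ordered by magnitude so SSD ties resolve to the
  # smallest motion (identical frames then yield zero flow)
  cand <- expand.grid(dx = -range:range, dy = -range:range)
  cand <- cand[order(cand$dx^2 + cand$dy^2, abs(cand$dy), abs(cand$dx)), ]
  row_starts <- seq(1L, h, by = block)
  col_starts <- seq(1L, w, by = block)
  for (r0 in row_starts) for (c0 in col_starts) {
    r1 <- min(r0 + block - 1L, h); c1 <- min(c0 + block - 1L, w)
    blk <- next_frame[r0:r1, c0:c1, drop = FALSE]
    best <- Inf; bdx <- 0L; bdy <- 0L
    for (k in seq_len(nrow(cand))) {
      dx <- cand$dx[k]; dy <- cand$dy[k]
      pr0 <- r0 - dy; pr1 <- r1 - dy; pc0 <- c0 - dx; pc1 <- c1 - dx
      if (pr0 < 1L || pc0 < 1L || pr1 > h || pc1 > w) next
      ssd <- sum((blk - prev_frame[pr0:pr1, pc0:pc1, drop = FALSE])^2)
      if (ssd < best) { best <- ssd; bdx <- dx; bdy <- dy }
    }
    if (!is.finite(best)) { bdx <- 0L; bdy <- 0L }
    mx[r0:r1, c0:c1] <- bdx
    my[r0:r1, c0:c1] <- bdy
  }
  list(x = mx, y = my)
}
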