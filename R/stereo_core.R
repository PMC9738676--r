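#' Rectified stereo pair
#'
#' Bundles a left and right grayscale image that have been rectified, i.e.
#' resampled so that corresponding scene points lie on the same scanline in
#' both images. Images are numeric matrices indexed `[row, column]`; in file
#' interfaces pixel coordinates are 0-based with `x` = column and `y` = row.
#'
#' @param left,right Numeric matrices of identical dimensions with finite
#'   intensities (conventionally in `[0, 1]`).
#' @return An object of class `rectified_pair`.
#' @export
rectified_pair <- function(left, right) {
  stopifnot(is.matrix(left), is.matrix(right))
  if (!all(dim(left) == dim(right)))
    stop("left and right images must have identical dimensions")
  if (nrow(left) < 1L || ncol(left) < 1L) stop("images must be non-empty")
  if (!all(is.finite(left)) || !all(is.finite(right)))
    stop("image intensities must be finite")
  structure(list(left = left, right = right), class = "rectified_pair")
}

#' Build a sum-squared-difference cost volume
#'
#' For every pixel `(i, j)` (`i` = column, `j` = row, 0-based) and every
#' candidate disparity `d` in `0 .. max_disparity - 1`, the matching cost is
#' the sum of squared intensity differences over a one-pixel-wide column
#' patch of height `2c + 1`:
#' \deqn{V(i,j,d) = \sum_{\Delta j=-c}^{c} (a(i, j+\Delta j) - b(i-d, j+\Delta j))^2}
#' where `a` is the left and `b` the right image. The right image is searched
#' leftward (`i - d`), the convention for a horizontally displaced rig.
#' Cells whose shifted column `i - d` or whose vertical patch extent leaves
#' the image are flagged invalid (`NaN`), never clamped: clamping biases the
#' winner-take-all readout near borders.
#'
#' @param pair A [rectified_pair()].
#' @param max_disparity Number of candidate disparities `D` (candidates
#'   `0 .. D-1`); must be at least 1 and no larger than the image width.
#' @param patch_half_height Patch half-height `c >= 0`.
#' @param square_window If `TRUE`, aggregate over a full `(2c+1) x (2c+1)`
#'   square window rather than the default 1-wide column patch. More robust
#'   on weakly textured input; off by default.
#' @return An object of class `cost_volume`: list with `values` (an
#'   `H x W x D` array, `NaN` = invalid cell), `max_disparity`,
#'   `patch_half_height`, `square_window`.
#' @examples
#' set.seed(1)
#' img <- matrix(runif(20 * 30), 20, 30)
#' vol <- build_cost_volume(rectified_pair(img, img), max_disparity = 4,
#'                          patch_half_height = 1)
#' all(vol$values[, , 1] == 0, na.rm = TRUE)  # identical images: zero cost at d = 0
#' @export
build_cost_volume <- function(pair, max_disparity, patch_half_height,
                              square_window = FALSE) {
  stopifnot(inherits(pair, "rectified_pair"))
  D <- as.integer(max_disparity)
  cc <- as.integer(patch_half_height)
  h <- nrow(pair$left); w <- ncol(pair$left)
  if (D < 1L) stop("max_disparity must be >= 1")
  if (cc < 0L) stop("patch_half_height must be >= 0")
  if (D > w) stop(sprintf("max_disparity (%d) exceeds image width (%d)", D, w))
  a <- pair$left; b <- pair$right
  vals <- array(NA_real_, dim = c(h, w, D))
  rowlo <- cc + 1L; rowhi <- h - cc
  collo_off <- if (square_window) cc else 0L
  for (d in 0:(D - 1L)) {
    if (d + 1L > w) break
    cols <- (d + 1L):w                       # 1-based columns with i - d >= 0
    sq <- matrix(NA_real_, h, w)
    sq[, cols] <- (a[, cols, drop = FALSE] - b[, cols - d, drop = FALSE])^2
    if (rowlo > rowhi) next
    agg <- matrix(NA_real_, h, w)
    if (!square_window) {
      acc <- matrix(0, rowhi - rowlo + 1L, w)
      for (dy in -cc:cc)
        acc <- acc + sq[(rowlo:rowhi) + dy, , drop = FALSE]
      agg[rowlo:rowhi, ] <- acc
    } else {
      collo <- collo_off + 1L; colhi <- w - collo_off
      if (collo <= colhi) {
        acc <- matrix(0, rowhi - rowlo + 1L, colhi - collo + 1L)
        for (dy in -cc:cc) for (dx in -cc:cc)
          acc <- acc + sq[(rowlo:rowhi) + dy, (collo:colhi) + dx, drop = FALSE]
        agg[rowlo:rowhi, collo:colhi] <- acc
      }
    }
    vals[, , d + 1L] <- agg
  }
  structure(list(values = vals, max_disparity = D, patch_half_height = cc,
                 square_window = isTRUE(square_window)),
            class = "cost_volume")
}

#' Winner-take-all disparity from a cost volume
#'
#' Per pixel, returns the disparity minimizing the matching cost among valid
#' cells; ties break toward the smaller disparity. With `subpixel = TRUE`, a
#' three-point parabola through the costs at `(d-1, d, d+1)` refines the
#' integer winner whenever all three cells are valid and the parabola is
#' convex. Pixels with no valid cell are `NaN`.
#'
#' @param volume A [build_cost_volume()] result.
#' @param subpixel Enable parabolic sub-pixel refinement (default `FALSE`,
#'   so integer oracles stay exact).
#' @return `H x W` numeric matrix of disparities in px; `NaN` = invalid.
#' @export
disparity_from_cost_volume <- function(volume, subpixel = FALSE) {
  stopifnot(inherits(volume, "cost_volume"))
  v <- volume$values
  h <- dim(v)[1L]; w <- dim(v)[2L]; D <- dim(v)[3L]
  m <- matrix(v, nrow = h * w, ncol = D)
  m_inf <- m
  m_inf[is.na(m_inf)] <- Inf
  if (D == 1L) {
    win <- rep.int(1L, h * w)
  } else {
    win <- max.col(-m_inf, ties.method = "first")
  }
  best <- m_inf[cbind(seq_len(h * w), win)]
  disp <- as.numeric(win - 1L)
  disp[!is.finite(best)] <- NaN
  if (isTRUE(subpixel) && D >= 3L) {
    interior <- which(is.finite(best) & win > 1L & win < D)
    if (length(interior) > 0L) {
      c0 <- m[cbind(interior, win[interior] - 1L)]
      c1 <- m[cbind(interior, win[interior])]
      c2 <- m[cbind(interior, win[interior] + 1L)]
      ok <- is.finite(c0) & is.finite(c1) & is.finite(c2)
      denom <- c0 - 2 * c1 + c2
      ok <- ok & denom > 0
      delta <- ifelse(ok, 0.5 * (c0 - c2) / denom, 0)
      disp[interior] <- disp[interior] + delta
    }
  }
  matrix(disp, nrow = h, ncol = w)
}

#' Convert disparity to metric depth (and back)
#'
#' Applies the inverse relation `z = b * f / d` between disparity `d` (px)
#' and depth `z` (m) for a calibrated rig. Zero disparity corresponds to a
#' point at infinity and maps to the invalid marker `NaN`, not `Inf`, so
#' downstream medians stay finite; invalid input propagates.
#'
#' @param disparity,depth `H x W` numeric matrices (`NaN` = invalid).
#' @param rig A [stereo_rig()].
#' @return `H x W` numeric matrix of depths in m (or disparities in px).
#' @examples
#' rig <- stereo_rig(0.5, 1000)
#' disparity_to_depth(matrix(c(100, 0), 1), rig)  # 5 m, then NaN
#' @export
disparity_to_depth <- function(disparity, rig) {
  assert_rig(rig)
  stopifnot(is.matrix(disparity) || is.numeric(disparity))
  z <- rig$baseline_m * rig$focal_px / disparity
  z[!is.finite(disparity) | disparity <= 0] <- NaN
  z
}

#' @rdname disparity_to_depth
#' @export
depth_to_disparity <- function(depth, rig) {
  assert_rig(rig)
  stopifnot(is.matrix(depth) || is.numeric(depth))
  d <- rig$baseline_m * rig$focal_px / depth
  d[!is.finite(depth) | depth <= 0] <- NaN
  d
}

#' Rectify a raw image pair through precomputed remap grids
#'
#' Resamples each raw image through its remap grid by bilinear
#' interpolation. A remap grid gives, for every output pixel, the 0-based
#' source coordinate `(x, y)` in the raw image; grids are produced by an
#' external calibration tool and read from PFM files via
#' [read_calibration()]. Output pixels whose source lands outside the raw
#' image (or on a `NaN` grid entry) are marked invalid (`NaN`).
#'
#' @param left_raw,right_raw Raw numeric image matrices.
#' @param maps List with elements `left` and `right`, each a list of
#'   matrices `x` and `y` (same dimensions; these define the output size).
#' @return A list with `left` and `right` rectified matrices (`NaN` marks
#'   unmapped pixels; construct a [rectified_pair()] after filling them).
#' @export
apply_rectification <- function(left_raw, right_raw, maps) {
  stopifnot(is.matrix(left_raw), is.matrix(right_raw))
  if (is.null(maps$left) || is.null(maps$right))
    stop("maps must contain 'left' and 'right' remap grids")
  remap1 <- function(img, grid) {
    if (is.null(grid$x) || is.null(grid$y) || !all(dim(grid$x) == dim(grid$y)))
      stop("remap grid must have matching 'x' and 'y' matrices")
    h_out <- nrow(grid$x); w_out <- ncol(grid$x)
    sx <- as.numeric(grid$x); sy <- as.numeric(grid$y)      # 0-based source coords
    h <- nrow(img); w <- ncol(img)
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    ok <- is.finite(sx) & is.finite(sy) & x0 >= 0 & y0 >= 0 & x0 + 1 <= w - 1 & y0 + 1 <= h - 1
    # exact right/bottom edge: collapse the unit cell
    edge_x <- is.finite(sx) & sx == w - 1; edge_y <- is.finite(sy) & sy == h - 1
    ok <- ok | (is.finite(sx) & is.finite(sy) & (edge_x | edge_y) &
                  sx >= 0 & sx <= w - 1 & sy >= 0 & sy <= h - 1)
    x0c <- pmin(x0, w - 2); y0c <- pmin(y0, h - 2)
    out <- rep(NaN, h_out * w_out)
    i <- which(ok)
    if (length(i) > 0L) {
      idx <- function(r, cl) img[cbind(r + 1L, cl + 1L)]
      v00 <- idx(y0c[i], x0c[i]); v01 <- idx(y0c[i], x0c[i] + 1L)
      v10 <- idx(y0c[i] + 1L, x0c[i]); v11 <- idx(y0c[i] + 1L, x0c[i] + 1L)
      fxi <- sx[i] - x0c[i]; fyi <- sy[i] - y0c[i]
      out[i] <- (1 - fyi) * ((1 - fxi) * v00 + fxi * v01) +
        fyi * ((1 - fxi) * v10 + fxi * v11)
    }
    matrix(out, h_out, w_out)
  }
  list(left = remap1(left_raw, maps$left), right = remap1(right_raw, maps$right))
}
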