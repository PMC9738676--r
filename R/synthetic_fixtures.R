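#' Synthetic stereo scene specification
#'
#' Describes a fronto-parallel test scene: an i.i.d.-noise textured
#' background plane at a far depth with circular "animal" blobs at nearer
#' depths, observed by a calibrated rig. Blobs must sit in front of the
#' background and every depth must map to a disparity smaller than the
#' image width. Defaults emulate the target use case: animals between 3 m
#' and 11 m in front of a 20 m background, at a desk-scale resolution
#' (96 x 72) with a rig (baseline 0.5 m, focal length 160 px) whose
#' disparities stay small enough for CPU matching.
#'
#' @param width,height Image size in px.
#' @param rig A [stereo_rig()].
#' @param background_depth_m Depth of the background plane in m.
#' @param blobs List of blobs, each a list with `center` (0-based `(x, y)`),
#'   `radius` (px) and `depth_m`.
#' @param seed Integer seed making every render reproducible.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 96L, height = 72L,
                       rig = stereo_rig(0.5, 160),
                       background_depth_m = 20,
                       blobs = list(list(center = c(48, 36), radius = 12,
                                         depth_m = 5)),
                       seed = 1L) {
  assert_rig(rig)
  stopifnot(width >= 1L, height >= 1L, background_depth_m > 0)
  for (b in blobs) {
    stopifnot(length(b$center) == 2L, b$radius > 0, b$depth_m > 0)
    if (b$depth_m >= background_depth_m)
      stop("blob depths must be smaller than the background depth")
    if (rig$baseline_m * rig$focal_px / b$depth_m >= width)
      stop("blob disparity reaches the image width; use a farther depth or wider image")
  }
  if (rig$baseline_m * rig$focal_px / background_depth_m >= width)
    stop("background disparity reaches the image width")
  structure(list(width = as.integer(width), height = as.integer(height),
                 rig = rig, background_depth_m = background_depth_m,
                 blobs = blobs, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Render a rectified stereo pair with ground truth
#'
#' The left image is i.i.d. uniform texture (which guarantees unique SSD
#' minima with high probability). The right image is composed by shifting
#' each constant-depth region leftward by its disparity `d = b f / z`
#' (rounded to the nearest integer pixel for rendering); nearer regions are
#' composited over farther ones, emulating occlusion, and dis-occluded
#' right-image pixels receive fresh texture. The returned ground-truth
#' disparity map holds the exact (unrounded) `b f / z` per left pixel, so it
#' is exactly consistent with the rig geometry; `valid` marks left pixels
#' whose correspondence survives occlusion and image borders (only those are
#' scored in shift-recovery tests).
#'
#' @param spec A [scene_spec()].
#' @return List with `pair` ([rectified_pair()]), `disparity` (exact
#'   ground-truth map, px), `masks` (list of logical blob masks), `valid`
#'   (logical matchability mask), `region` (integer region map, 0 =
#'   background).
#' @export
render_stereo_pair <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  rig <- spec$rig
  left <- matrix(stats::runif(h * w), h, w)
  region <- matrix(0L, h, w)
  xs <- matrix(rep(0:(w - 1L), each = h), h, w)
  ys <- matrix(rep(0:(h - 1L), times = w), h, w)
  depths <- c(spec$background_depth_m,
              vapply(spec$blobs, function(b) b$depth_m, numeric(1L)))
  # paint blobs nearest-last so overlapping nearer blobs win in the left image
  ord <- order(vapply(spec$blobs, function(b) b$depth_m, numeric(1L)),
               decreasing = TRUE)
  masks <- vector("list", length(spec$blobs))
  for (bi in ord) {
    b <- spec$blobs[[bi]]
    inside <- (xs - b$center[1L])^2 + (ys - b$center[2L])^2 <= b$radius^2
    region[inside] <- bi
  }
  for (bi in seq_along(spec$blobs)) masks[[bi]] <- region == bi
  disp_exact <- rig$baseline_m * rig$focal_px / depths[region + 1L]
  dim(disp_exact) <- c(h, w)
  disp_int <- round(disp_exact)

  right <- matrix(NA_real_, h, w)
  writer <- matrix(NA_integer_, h, w)
  # splat far-to-near so nearer content occludes farther content
  for (reg in order(depths, decreasing = TRUE) - 1L) {
    idx <- which(region == reg)
    if (length(idx) == 0L) next
    rr <- ((idx - 1L) %% h) + 1L
    cc <- ((idx - 1L) %/% h) + 1L
    tc <- cc - disp_int[idx]
    keep <- tc >= 1L
    right[cbind(rr[keep], tc[keep])] <- left[idx[keep]]
    writer[cbind(rr[keep], tc[keep])] <- reg
  }
  holes <- which(is.na(right))
  if (length(holes) > 0L) right[holes] <- stats::runif(length(holes))

  valid <- matrix(FALSE, h, w)
  idx <- seq_len(h * w)
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  tc <- cc - disp_int[idx]
  inb <- tc >= 1L
  ok <- idx[inb][writer[cbind(rr[inb], tc[inb])] == region[idx[inb]]]
  valid[ok] <- TRUE

  list(pair = rectified_pair(left, right), disparity = disp_exact,
       masks = masks, valid = valid, region = region)
}

#' Render a motion video with known foreground ratios
#'
#' A static textured background (intensities in `[0, 0.5]`) with a bright
#' constant disk (intensity 1) moving at a fixed velocity; emulates an
#' animal crossing a camera-trap scene. Returns the per-frame true
#' foreground ratio (disk area inside the frame over frame area), the
#' reference against which the adaptive sampler is tested.
#'
#' @param spec A [scene_spec()] (its first blob provides start position and
#'   radius; its seed fixes the texture).
#' @param n_frames Number of frames.
#' @param blob_velocity Length-2 numeric `(vx, vy)` in px/frame.
#' @return List with `frames` (list of matrices) and `ratios`.
#' @export
render_motion_video <- function(spec, n_frames, blob_velocity = c(1, 0)) {
  stopifnot(inherits(spec, "scene_spec"), n_frames >= 1L,
            length(blob_velocity) == 2L, length(spec$blobs) >= 1L)
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  bg <- matrix(stats::runif(h * w, 0, 0.5), h, w)
  xs <- matrix(rep(0:(w - 1L), each = h), h, w)
  ys <- matrix(rep(0:(h - 1L), times = w), h, w)
  b <- spec$blobs[[1L]]
  frames <- vector("list", n_frames)
  ratios <- numeric(n_frames)
  for (n in seq_len(n_frames)) {
    cx <- b$center[1L] + (n - 1L) * blob_velocity[1L]
    cy <- b$center[2L] + (n - 1L) * blob_velocity[2L]
    inside <- (xs - cx)^2 + (ys - cy)^2 <= b$radius^2
    f <- bg
    f[inside] <- 1
    frames[[n]] <- f
    ratios[n] <- mean(inside)
  }
  list(frames = frames, ratios = ratios)
}

#' Degrade a stereo pair into a night scene with texture holes
#'
#' Underexposed night regions carry no texture, so stereo matching there is
#' ambiguous. This generator blanks random rectangular regions to a
#' constant low intensity in both images (the same regions in both, as a
#' shared illumination deficit) until roughly `hole_fraction` of the frame
#' is covered, and returns the hole mask.
#'
#' @param pair A [rectified_pair()].
#' @param hole_fraction Target covered fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @param hole_value Constant intensity written into holes.
#' @return List with `pair` (degraded [rectified_pair()]) and `holes`
#'   (logical mask).
#' @export
degrade_night <- function(pair, hole_fraction, seed = 1L, hole_value = 0.05) {
  stopifnot(inherits(pair, "rectified_pair"),
            hole_fraction >= 0, hole_fraction < 1)
  h <- nrow(pair$left); w <- ncol(pair$left)
  holes <- matrix(FALSE, h, w)
  if (hole_fraction > 0) {
    set.seed(seed)
    target <- hole_fraction * h * w
    guard <- 0L
    while (sum(holes) < target && guard < 10000L) {
      guard <- guard + 1L
      hh <- sample(3:max(3L, h %/% 6L), 1L)
      ww <- sample(3:max(3L, w %/% 6L), 1L)
      r0 <- sample(seq_len(h - hh + 1L), 1L)
      c0 <- sample(seq_len(w - ww + 1L), 1L)
      holes[r0:(r0 + hh - 1L), c0:(c0 + ww - 1L)] <- TRUE
    }
  }
  left <- pair$left; right <- pair$right
  left[holes] <- hole_value
  right[holes] <- hole_value
  list(pair = rectified_pair(left, right), holes = holes)
}
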