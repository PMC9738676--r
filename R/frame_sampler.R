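#' Per-pixel Gaussian-mixture background model
#'
#' Classic adaptive background subtraction: each pixel's intensity history is
#' modelled by a mixture of `K` Gaussians updated online. Components that
#' persistently explain the pixel accumulate weight and are labelled
#' background; intensities matching no high-weight component are foreground
#' (moving objects). Intensities are assumed in `[0, 1]`.
#'
#' Hyperparameters follow the classic defaults of this family of methods and
#' are all exposed: `K = 3` components, learning rate 0.005, match threshold
#' 2.5 standard deviations, background weight threshold 0.7.
#'
#' @param K Number of mixture components per pixel.
#' @param learning_rate Online update rate `alpha` in (0, 1).
#' @param match_threshold Match radius in standard deviations.
#' @param background_weight_threshold Minimum cumulative weight of the
#'   top-weight components considered background.
#' @param init_variance Variance assigned to newly created components
#'   (intensity units squared).
#' @param min_variance Variance floor preventing degenerate components.
#' @return An object of class `background_model` (unfitted until the first
#'   [update_background()] call).
#' @export
background_model <- function(K = 3L, learning_rate = 0.005,
                             match_threshold = 2.5,
                             background_weight_threshold = 0.7,
                             init_variance = 0.1^2, min_variance = 0.005^2) {
  stopifnot(K >= 1L, learning_rate > 0, learning_rate < 1,
            match_threshold > 0, background_weight_threshold > 0,
            background_weight_threshold <= 1,
            init_variance > 0, min_variance > 0)
  structure(list(K = as.integer(K), learning_rate = learning_rate,
                 match_threshold = match_threshold,
                 background_weight_threshold = background_weight_threshold,
                 init_variance = init_variance, min_variance = min_variance,
                 w = NULL, mu = NULL, var = NULL, dim = NULL),
            class = "background_model")
}

#' Update the background model with one frame
#'
#' Per pixel: the incoming intensity is matched against the existing
#' components (within `match_threshold` standard deviations); among matching
#' components the highest-weight one absorbs the observation via the online
#' weight/mean/variance update. If nothing matches, the lowest-weight
#' component is replaced by a fresh one centred on the observation. Weights
#' are renormalized to sum to 1 after every update. A pixel is foreground if
#' it matched no component, or matched one outside the minimal top-weight
#' set whose cumulative weight exceeds `background_weight_threshold`.
#'
#' @param model A [background_model()].
#' @param frame Numeric matrix of intensities in `[0, 1]`; all frames must
#'   share dimensions.
#' @return A list with `model` (updated) and `foreground` (logical matrix).
#' @export
update_background <- function(model, frame) {
  stopifnot(inherits(model, "background_model"), is.matrix(frame))
  K <- model$K
  np <- length(frame)
  x <- as.numeric(frame)
  if (is.null(model$w)) {
    model$dim <- dim(frame)
    model$w <- matrix(0, np, K); model$w[, 1L] <- 1
    model$mu <- matrix(0, np, K); model$mu[, 1L] <- x
    model$var <- matrix(model$init_variance, np, K)
    return(list(model = model,
                foreground = matrix(FALSE, nrow(frame), ncol(frame))))
  }
  if (!all(dim(frame) == model$dim))
    stop("frame dimensions do not match the background model")
  w <- model$w; mu <- model$mu; v <- model$var
  alpha <- model$learning_rate
  thr2 <- model$match_threshold^2

  matched <- (x - mu)^2 <= thr2 * v & w > 0
  # choose, per pixel, the highest-weight matching component
  score <- ifelse(matched, w, -1)
  if (K == 1L) {
    chosen <- rep.int(1L, np)
  } else {
    chosen <- max.col(score, ties.method = "first")
  }
  any_match <- score[cbind(seq_len(np), chosen)] >= 0

  # background membership *before* the update decides the foreground label:
  # rank components by weight; background = minimal top-weight prefix whose
  # cumulative weight exceeds the threshold
  is_bg <- bg_membership(w, model$background_weight_threshold)
  fg <- !any_match | !is_bg[cbind(seq_len(np), chosen)]

  # weight update
  w <- (1 - alpha) * w
  idx_match <- cbind(which(any_match), chosen[any_match])
  w[idx_match] <- w[idx_match] + alpha
  # mean/variance update of the matched component (rho = alpha)
  dm <- x[any_match] - mu[idx_match]
  mu[idx_match] <- mu[idx_match] + alpha * dm
  v[idx_match] <- pmax(v[idx_match] + alpha * (dm^2 - v[idx_match]),
                       model$min_variance)
  # replacement for unmatched pixels: overwrite the lowest-weight component
  un <- which(!any_match)
  if (length(un) > 0L) {
    lowest <- if (K == 1L) rep.int(1L, length(un)) else
      max.col(-w[un, , drop = FALSE], ties.method = "last")
    idx_rep <- cbind(un, lowest)
    w[idx_rep] <- alpha
    mu[idx_rep] <- x[un]
    v[idx_rep] <- model$init_variance
  }
  w <- w / rowSums(w)
  model$w <- w; model$mu <- mu; model$var <- v
  list(model = model, foreground = matrix(fg, model$dim[1L], model$dim[2L]))
}

# For each pixel (row of w), TRUE for components in the minimal
# highest-weight prefix with cumulative weight > threshold.
bg_membership <- function(w, threshold) {
  np <- nrow(w); K <- ncol(w)
  out <- matrix(FALSE, np, K)
  ord <- w
  taken <- matrix(FALSE, np, K)
  cum <- numeric(np)
  active <- rep(TRUE, np)
  for (r in seq_len(K)) {
    masked <- ord
    masked[taken] <- -Inf
    top <- if (K == 1L) rep.int(1L, np) else max.col(masked, ties.method = "first")
    idx <- cbind(seq_len(np), top)
    out[idx] <- out[idx] | active
    cum <- cum + w[idx]
    taken[idx] <- TRUE
    active <- active & cum <= threshold
    if (!any(active)) break
  }
  out
}

#' Fraction of foreground pixels in a mask
#'
#' @param mask Logical (or 0/1) matrix; `TRUE`/1 = foreground.
#' @return Fraction in `[0, 1]`.
#' @export
foreground_ratio <- function(mask) {
  if (length(mask) == 0L) stop("empty mask")
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) stop("mask must be binary")
    mask <- mask > 0
  }
  stopifnot(is.logical(mask))
  mean(mask)
}

#' 3x3 morphological opening of a binary mask
#'
#' Erosion followed by dilation with a 3x3 structuring element; suppresses
#' single-pixel salt noise in foreground masks before the ratio is taken.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same size.
#' @export
morphological_open <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  shift_all <- function(m, combine, pad) {
    h <- nrow(m); w <- ncol(m)
    out <- m
    padded <- matrix(pad, h + 2L, w + 2L)
    padded[2:(h + 1L), 2:(w + 1L)] <- m
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      out <- combine(out, padded[(2:(h + 1L)) + dy, (2:(w + 1L)) + dx])
    }
    out
  }
  eroded <- shift_all(mask, `&`, TRUE)
  shift_all(eroded, `|`, FALSE)
}

#' Motion-adaptive frame selection from foreground ratios
#'
#' Scans frames in order, accumulating each frame's foreground ratio; when
#' the accumulator reaches the threshold `tau` the frame is selected and the
#' accumulator resets to 0. More movement therefore yields denser sampling:
#' for a constant ratio `r` the sampling period is exactly `ceiling(tau/r)`
#' frames.
#'
#' @param ratios Numeric vector of per-frame foreground ratios in `[0, 1]`,
#'   for frames `0 .. length(ratios) - 1`.
#' @param tau Accumulation threshold (> 0); default 0.10.
#' @param burn_in Number of initial frames ineligible for selection and
#'   excluded from accumulation (they only serve to initialize the
#'   background model); default 0 here, 50 in [sample_video_adaptive()].
#' @return Integer vector of selected 0-based frame indices.
#' @examples
#' adaptive_sample(rep(0.05, 10), tau = 0.10)  # every 2nd frame: 1 3 5 7 9
#' @export
adaptive_sample <- function(ratios, tau = 0.10, burn_in = 0L) {
  stopifnot(is.numeric(ratios), tau > 0, burn_in >= 0L)
  if (any(ratios < 0 | ratios > 1, na.rm = TRUE))
    stop("ratios must lie in [0, 1]")
  acc <- 0
  sel <- integer(0)
  for (i in seq_along(ratios)) {
    if (i - 1L < burn_in) next
    acc <- acc + ratios[i]
    # small slack so float accumulation (e.g. 10 x 0.01) still trips at tau
    if (acc >= tau - 1e-12) {
      sel <- c(sel, i - 1L)
      acc <- 0
    }
  }
  sel
}

#' Fixed-rate frame selection
#'
#' Selects indices `0, s, 2s, ...` with step `s = round(fps / rate_hz)`,
#' emulating sampling stills from a video at a fixed temporal rate.
#'
#' @param n_frames Total number of frames.
#' @param fps Video frame rate (frames per second).
#' @param rate_hz Desired sampling rate in 1/s; must not exceed `fps`.
#' @return Integer vector of selected 0-based frame indices.
#' @examples
#' length(fixed_rate_sample(750, fps = 30, rate_hz = 2))  # 25 s video -> 50 stills
#' @export
fixed_rate_sample <- function(n_frames, fps, rate_hz) {
  stopifnot(n_frames >= 0L, fps > 0, rate_hz > 0)
  if (rate_hz > fps) stop("sampling rate exceeds the video frame rate")
  if (n_frames == 0L) return(integer(0))
  step <- max(1L, as.integer(round(fps / rate_hz)))
  seq.int(0L, n_frames - 1L, by = step)
}

#' Adaptive sampling of a frame sequence
#'
#' Convenience wrapper running the full motion-adaptive chain on an
#' in-memory frame list: Gaussian-mixture background update per frame,
#' optional 3x3 morphological opening of the foreground mask, foreground
#' ratio, then threshold accumulation with burn-in.
#'
#' @param frames List of intensity matrices (values in `[0, 1]`).
#' @param tau Accumulation threshold; default 0.10.
#' @param burn_in Initial frames used only to initialize the background
#'   model; default 50.
#' @param opening Apply morphological opening to each mask (default `TRUE`).
#' @param model A [background_model()]; defaults to the standard settings.
#' @return List with `indices` (0-based selected frames), `ratios`
#'   (per-frame foreground ratios) and `model` (final background model).
#' @export
sample_video_adaptive <- function(frames, tau = 0.10, burn_in = 50L,
                                  opening = TRUE, model = background_model()) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  ratios <- numeric(length(frames))
  for (i in seq_along(frames)) {
    upd <- update_background(model, frames[[i]])
    model <- upd$model
    m <- upd$foreground
    if (isTRUE(opening)) m <- morphological_open(m)
    ratios[i] <- foreground_ratio(m)
  }
  list(indices = adaptive_sample(ratios, tau = tau, burn_in = burn_in),
       ratios = ratios, model = model)
}
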