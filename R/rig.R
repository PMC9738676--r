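#' Stereo rig calibration constants
#'
#' A stereo rig ties image-space disparity (px) to metric depth (m) through
#' the two calibration constants of the pinhole stereo model: the baseline
#' `b` (distance between the optical centres of the two cameras, in meters)
#' and the shared focal length `f` (in pixels). Depth and disparity are
#' inversely related, `z = b * f / d`.
#'
#' @param baseline_m Baseline `b` in meters. Must be positive.
#' @param focal_px Focal length `f` in pixels. Must be positive.
#' @param image_width,image_height Optional image dimensions in pixels
#'   (each at least 1 when given). Used for validating file inputs.
#' @return An object of class `stereo_rig`.
#' @examples
#' rig <- stereo_rig(baseline_m = 0.5, focal_px = 1000)
#' disparity_to_depth(matrix(100, 2, 2), rig)  # 5 m everywhere
#' @export
stereo_rig <- function(baseline_m, focal_px, image_width = NULL, image_height = NULL) {
  stopifnot(is.numeric(baseline_m), length(baseline_m) == 1L, is.finite(baseline_m),
            is.numeric(focal_px), length(focal_px) == 1L, is.finite(focal_px))
  if (baseline_m <= 0) stop("baseline_m must be > 0")
  if (focal_px <= 0) stop("focal_px must be > 0")
  for (d in list(image_width, image_height)) {
    if (!is.null(d) && (!is.numeric(d) || length(d) != 1L || d < 1))
      stop("image dimensions must be >= 1")
  }
  structure(
    list(baseline_m = as.numeric(baseline_m),
         focal_px = as.numeric(focal_px),
         image_width = if (is.null(image_width)) NULL else as.integer(image_width),
         image_height = if (is.null(image_height)) NULL else as.integer(image_height)),
    class = "stereo_rig")
}

#' @export
print.stereo_rig <- function(x, ...) {
  cat(sprintf("<stereo_rig> baseline %.4g m, focal length %.6g px", x$baseline_m, x$focal_px))
  if (!is.null(x$image_width)) cat(sprintf(", %d x %d px", x$image_width, x$image_height))
  cat("\n")
  invisible(x)
}

assert_rig <- function(rig) {
  if (!inherits(rig, "stereo_rig")) stop("expected a 'stereo_rig' object")
  invisible(rig)
}
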