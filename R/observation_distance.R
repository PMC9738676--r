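#' Animal detection (bounding box or instance mask)
#'
#' A detection produced by an external animal detector, referenced to a
#' frame. Exactly one of `bbox` or `mask` must be given. Bounding boxes use
#' 0-based, half-open pixel coordinates `(x_min, y_min, x_max, y_max)` with
#' `x` = column; masks are logical matrices with the image's dimensions.
#'
#' @param frame_id Character or integer frame identifier.
#' @param bbox Numeric length-4 vector `(x_min, y_min, x_max, y_max)`.
#' @param mask Logical matrix.
#' @param confidence Detector confidence in `[0, 1]`.
#' @param label Class label (default `"animal"`).
#' @return An object of class `detection` with `kind` `"bbox"` or `"mask"`.
#' @export
detection <- function(frame_id, bbox = NULL, mask = NULL, confidence = 1,
                      label = "animal") {
  if (is.null(bbox) == is.null(mask))
    stop("exactly one of 'bbox' or 'mask' must be given")
  stopifnot(confidence >= 0, confidence <= 1)
  if (!is.null(bbox)) {
    stopifnot(is.numeric(bbox), length(bbox) == 4L)
    if (bbox[1L] >= bbox[3L] || bbox[2L] >= bbox[4L])
      stop("bbox must satisfy x_min < x_max and y_min < y_max")
    if (any(bbox[1:2] < 0)) stop("bbox must lie within the image")
    kind <- "bbox"
  } else {
    stopifnot(is.logical(mask), is.matrix(mask))
    kind <- "mask"
  }
  structure(list(frame_id = as.character(frame_id), kind = kind, bbox = bbox,
                 mask = mask, confidence = confidence, label = label),
            class = "detection")
}

#' Camera-animal distance from an instance mask
#'
#' Applies the binary instance mask to the metric depth map and takes the
#' median of the valid depths underneath it. The median is robust both to
#' minority background leak at the mask boundary and to invalid depth holes
#' (underexposed night regions), which are simply excluded.
#'
#' @param det A mask-kind [detection()] (or a bare logical matrix).
#' @param depth `H x W` depth matrix in meters (`NaN` = invalid).
#' @param min_support Minimum number of valid depth pixels required; below
#'   this the distance is unreliable and `NA` is returned (not an error).
#' @return Distance in meters, or `NA_real_`.
#' @export
animal_distance_mask <- function(det, depth, min_support = 20L) {
  mask <- if (inherits(det, "detection")) {
    if (det$kind != "mask") stop("detection is not mask-kind")
    det$mask
  } else det
  stopifnot(is.logical(mask), is.matrix(mask), is.matrix(depth))
  if (!all(dim(mask) == dim(depth)))
    stop("mask and depth map dimensions differ")
  if (!any(mask)) stop("mask is empty")
  vals <- depth[mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) < min_support) return(NA_real_)
  stats::median(vals)
}

#' Camera-animal distance from a bounding box
#'
#' A box around an animal inevitably also covers background beyond it, so
#' the plain median over the box can be biased far. The default statistic is
#' therefore the 25th percentile of the valid depths inside the box (the
#' median of their lower half), which returns the animal's depth whenever
#' the animal fills at least half the box. The statistic is configurable.
#'
#' @param det A bbox-kind [detection()] (or a bare length-4 numeric vector,
#'   0-based half-open `(x_min, y_min, x_max, y_max)`).
#' @param depth `H x W` depth matrix in meters (`NaN` = invalid).
#' @param statistic `"q25"` (default) or `"median"`.
#' @param min_support Minimum number of valid depth pixels; below it `NA`.
#' @return Distance in meters, or `NA_real_`.
#' @export
animal_distance_bbox <- function(det, depth, statistic = c("q25", "median"),
                                 min_support = 20L) {
  statistic <- match.arg(statistic)
  bbox <- if (inherits(det, "detection")) {
    if (det$kind != "bbox") stop("detection is not bbox-kind")
    det$bbox
  } else det
  stopifnot(is.numeric(bbox), length(bbox) == 4L, is.matrix(depth))
  x0 <- as.integer(floor(bbox[1L])); y0 <- as.integer(floor(bbox[2L]))
  x1 <- as.integer(ceiling(bbox[3L])); y1 <- as.integer(ceiling(bbox[4L]))
  if (x0 < 0L || y0 < 0L || x1 > ncol(depth) || y1 > nrow(depth))
    stop("bbox exceeds the depth map")
  vals <- depth[(y0 + 1L):y1, (x0 + 1L):x1]
  vals <- vals[is.finite(vals)]
  if (length(vals) < min_support) return(NA_real_)
  switch(statistic,
         q25 = unname(stats::quantile(vals, 0.25, type = 7)),
         median = stats::median(vals))
}

#' Join detections with depth maps into an observation table
#'
#' One row per detection at or above the confidence cutoff. Distances come
#' from [animal_distance_mask()] or [animal_distance_bbox()] depending on
#' the detection kind; rows whose distance cannot be resolved (too few valid
#' depth pixels) are retained but flagged, so they can be excluded from the
#' distance-sampling export while staying auditable.
#'
#' @param detections List of [detection()] objects.
#' @param depth_maps Named list of depth matrices, names = frame ids.
#' @param min_confidence Detections below this confidence are dropped.
#' @param min_support,bbox_statistic Passed to the fusion functions.
#' @return A data.frame of class `observation_table` with columns
#'   `observation_id`, `frame_id`, `kind`, `label`, `confidence`,
#'   `distance_m`, `n_valid_depth_px`, `missing_distance`.
#' @export
build_observation_table <- function(detections, depth_maps,
                                    min_confidence = 0.2, min_support = 20L,
                                    bbox_statistic = "q25") {
  stopifnot(is.list(detections), is.list(depth_maps))
  ids <- vapply(detections, function(d) d$frame_id, character(1L))
  unmatched <- setdiff(unique(ids), names(depth_maps))
  if (length(unmatched) > 0L)
    stop(sprintf("no depth map for frame id(s): %s", paste(unmatched, collapse = ", ")))
  keep <- vapply(detections, function(d) d$confidence >= min_confidence, logical(1L))
  detections <- detections[keep]
  n <- length(detections)
  out <- data.frame(observation_id = seq_len(n),
                    frame_id = character(n), kind = character(n),
                    label = character(n), confidence = numeric(n),
                    distance_m = numeric(n), n_valid_depth_px = integer(n),
                    missing_distance = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    det <- detections[[i]]
    depth <- depth_maps[[det$frame_id]]
    if (det$kind == "mask") {
      vals <- depth[det$mask]
      dist <- animal_distance_mask(det, depth, min_support = min_support)
    } else {
      b <- det$bbox
      vals <- depth[(floor(b[2L]) + 1L):ceiling(b[4L]),
                    (floor(b[1L]) + 1L):ceiling(b[3L])]
      dist <- animal_distance_bbox(det, depth, statistic = bbox_statistic,
                                   min_support = min_support)
    }
    out$frame_id[i] <- det$frame_id
    out$kind[i] <- det$kind
    out$label[i] <- det$label
    out$confidence[i] <- det$confidence
    out$distance_m[i] <- dist
    out$n_valid_depth_px[i] <- sum(is.finite(vals))
    out$missing_distance[i] <- is.na(dist)
  }
  class(out) <- c("observation_table", "data.frame")
  out
}

#' Read detections from a MegaDetector-style JSON file
#'
#' Parses the common camera-trap detector interchange dialect: a JSON object
#' with an `images` array, each image carrying `file` and `detections`, each
#' detection `category`, `conf` and a normalized `bbox`
#' `[x, y, width, height]` relative to the image size. Boxes are converted
#' to absolute 0-based half-open pixel corners. Frame ids default to the
#' file name stripped of directory and extension.
#'
#' @param path Path to the JSON file.
#' @param image_width,image_height Image dimensions in px used to
#'   denormalize the boxes.
#' @return List of bbox-kind [detection()] objects.
#' @export
read_megadetector <- function(path, image_width, image_height) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(js$images)) stop("JSON lacks an 'images' array")
  out <- list()
  for (im in js$images) {
    fid <- tools::file_path_sans_ext(basename(im$file))
    for (d in im$detections) {
      bb <- as.numeric(unlist(d$bbox))
      if (length(bb) != 4L) stop(sprintf("malformed bbox in %s", im$file))
      px <- c(bb[1L] * image_width, bb[2L] * image_height,
              (bb[1L] + bb[3L]) * image_width, (bb[2L] + bb[4L]) * image_height)
      out[[length(out) + 1L]] <- detection(
        frame_id = fid, bbox = px,
        confidence = if (is.null(d$conf)) 1 else as.numeric(d$conf),
        label = if (is.null(d$category)) "animal" else as.character(d$category))
    }
  }
  out
}

#' Write / read an observation table as CSV
#'
#' UTF-8, comma-separated, header row, `.` decimal separator.
#'
#' @param x An `observation_table` (or compatible data.frame).
#' @param path CSV path.
#' @return `write_observations`: `path` invisibly; `read_observations`: the
#'   table.
#' @export
write_observations <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("observation_table", "data.frame")
  out
}
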