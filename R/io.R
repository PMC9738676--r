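#' Read a Middlebury PFM float map
#'
#' PFM (portable float map) is the de-facto interchange format for disparity
#' and depth maps. Only the little-endian dialect (negative scale) is
#' accepted; scanlines are stored bottom-to-top. Invalid pixels are `NaN`.
#'
#' @param path Path to a `.pfm` file.
#' @return A numeric `H x W` matrix for grayscale (`Pf`) files, or an
#'   `H x W x 3` array for color (`PF`) files. Row 1 is the top scanline.
#' @export
read_pfm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- pfm_tokens(con, 1L)
  if (!magic %in% c("Pf", "PF"))
    stop(sprintf("not a PFM file (magic '%s' in header line 1 of %s)", magic, path))
  tok <- c(magic, pfm_tokens(con, 3L))
  w <- suppressWarnings(as.integer(tok[2L]))
  h <- suppressWarnings(as.integer(tok[3L]))
  if (is.na(w) || is.na(h) || w < 1L || h < 1L)
    stop(sprintf("malformed PFM dimension line '%s %s' in %s", tok[2L], tok[3L], path))
  scale <- suppressWarnings(as.numeric(tok[4L]))
  if (is.na(scale) || scale == 0)
    stop(sprintf("malformed PFM scale line '%s' in %s", tok[4L], path))
  if (scale > 0)
    stop(sprintf("big-endian PFM (positive scale %g) is not supported: %s", scale, path))
  nchan <- if (magic == "PF") 3L else 1L
  n <- w * h * nchan
  vals <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  if (length(vals) != n)
    stop(sprintf("truncated PFM payload in %s: expected %d floats, got %d", path, n, length(vals)))
  if (nchan == 1L) {
    m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    m[h:1, , drop = FALSE]
  } else {
    a <- array(NA_real_, dim = c(h, w, 3L))
    for (ch in 1:3) {
      m <- matrix(vals[seq(ch, n, by = 3L)], nrow = h, ncol = w, byrow = TRUE)
      a[, , ch] <- m[h:1, , drop = FALSE]
    }
    a
  }
}

pfm_tokens <- function(con, n) {
  # header tokens are whitespace-separated; payload starts right after the
  # single whitespace byte that terminates the scale token
  out <- character(0)
  cur <- character(0)
  while (length(out) < n) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("unexpected end of file while reading PFM header")
    if (grepl("^[ \t\r\n]$", ch)) {
      if (length(cur) > 0L) {
        out <- c(out, paste(cur, collapse = ""))
        cur <- character(0)
      }
    } else {
      cur <- c(cur, ch)
    }
  }
  out
}

#' Write a Middlebury PFM float map
#'
#' Writes the little-endian dialect (scale -1). `NA` values are written as
#' `NaN`, the package-wide invalid-pixel marker.
#'
#' @param x A numeric matrix (writes a `Pf` grayscale map) or an
#'   `H x W x 3` array (writes a `PF` color map, used for flow fields).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (is.matrix(x)) {
    h <- nrow(x); w <- ncol(x)
    writeChar(sprintf("Pf\n%d %d\n-1.0\n", w, h), con, eos = NULL)
    v <- as.numeric(t(x[h:1, , drop = FALSE]))
    v[is.na(v)] <- NaN
    writeBin(v, con, size = 4L, endian = "little")
  } else if (is.array(x) && length(dim(x)) == 3L && dim(x)[3L] == 3L) {
    h <- dim(x)[1L]; w <- dim(x)[2L]
    writeChar(sprintf("PF\n%d %d\n-1.0\n", w, h), con, eos = NULL)
    v <- numeric(3L * h * w)
    for (ch in 1:3) v[seq(ch, length(v), by = 3L)] <- as.numeric(t(x[h:1, , ch]))
    v[is.na(v)] <- NaN
    writeBin(v, con, size = 4L, endian = "little")
  } else {
    stop("x must be a matrix or an H x W x 3 array")
  }
  invisible(path)
}

#' Read / write grayscale images in Netpbm PGM format
#'
#' Frames and masks are exchanged as PGM (P2 ascii or P5 binary), the plain
#' grayscale member of the Netpbm family. Pixel values are returned rescaled
#' to `[0, 1]` doubles; `write_pgm` quantizes to the given maxval.
#'
#' @param path File path.
#' @return `read_pgm`: a numeric `H x W` matrix with values in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- pgm_tokens(con, 4L)
  magic <- tok[1L]
  if (!magic %in% c("P2", "P5")) stop(sprintf("not a PGM file: %s", path))
  w <- as.integer(tok[2L]); h <- as.integer(tok[3L]); maxval <- as.integer(tok[4L])
  if (anyNA(c(w, h, maxval)) || w < 1L || h < 1L || maxval < 1L)
    stop(sprintf("malformed PGM header in %s", path))
  n <- w * h
  if (magic == "P5") {
    size <- if (maxval > 255L) 2L else 1L
    raw <- readBin(con, "integer", n = n, size = size, signed = FALSE, endian = "big")
    if (length(raw) != n) stop(sprintf("truncated PGM payload in %s", path))
  } else {
    rest <- readChar(con, file.size(path), useBytes = TRUE)
    rest <- gsub("#[^\n]*", "", rest)
    raw <- suppressWarnings(as.integer(strsplit(trimws(rest), "[ \t\r\n]+")[[1L]]))
    if (length(raw) < n || anyNA(raw[seq_len(n)]))
      stop(sprintf("malformed P2 payload in %s", path))
    raw <- raw[seq_len(n)]
  }
  matrix(raw, nrow = h, ncol = w, byrow = TRUE) / maxval
}

pgm_tokens <- function(con, n) {
  out <- character(0)
  cur <- character(0)
  in_comment <- FALSE
  while (length(out) < n) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("unexpected end of file while reading PGM header")
    if (in_comment) {
      if (ch == "\n") in_comment <- FALSE
      next
    }
    if (ch == "#") { in_comment <- TRUE; next }
    if (grepl("^[ \t\r\n]$", ch)) {
      if (length(cur) > 0L) {
        out <- c(out, paste(cur, collapse = ""))
        cur <- character(0)
      }
    } else cur <- c(cur, ch)
  }
  out
}

#' @param x Numeric matrix with values in `[0, 1]` (clamped on write).
#' @param maxval Quantization maximum, 255 (8-bit) or 65535 (16-bit).
#' @rdname read_pgm
#' @export
write_pgm <- function(x, path, maxval = 65535L) {
  stopifnot(is.matrix(x), maxval %in% c(255L, 65535L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(x), nrow(x), maxval), con, eos = NULL)
  v <- as.integer(round(pmin(pmax(as.numeric(t(x)), 0), 1) * maxval))
  writeBin(v, con, size = if (maxval > 255L) 2L else 1L, endian = "big")
  invisible(path)
}

#' Read a calibration file
#'
#' The calibration file is flat YAML (`key: value` scalars, `#` comments)
#' with keys `baseline_m`, `focal_px`, and optionally `image_width`,
#' `image_height`, plus rectification remap grids as PFM paths under
#' `rectify_left_x`, `rectify_left_y`, `rectify_right_x`, `rectify_right_y`
#' (resolved relative to the calibration file).
#'
#' @param path Path to the YAML calibration file.
#' @return A list with `rig` (a [stereo_rig()]) and `rectify` (either `NULL`
#'   or a list of remap grids, see [apply_rectification()]).
#' @export
read_calibration <- function(path) {
  kv <- read_flat_yaml(path)
  req <- c("baseline_m", "focal_px")
  missing <- setdiff(req, names(kv))
  if (length(missing) > 0)
    stop(sprintf("calibration file %s lacks required key(s): %s", path, paste(missing, collapse = ", ")))
  rig <- stereo_rig(as.numeric(kv$baseline_m), as.numeric(kv$focal_px),
                    image_width = if (is.null(kv$image_width)) NULL else as.numeric(kv$image_width),
                    image_height = if (is.null(kv$image_height)) NULL else as.numeric(kv$image_height))
  rect <- NULL
  keys <- c("rectify_left_x", "rectify_left_y", "rectify_right_x", "rectify_right_y")
  have <- keys %in% names(kv)
  if (any(have)) {
    if (!all(have))
      stop("calibration file must give all four rectify_* map paths or none")
    dir <- dirname(path)
    rd <- function(p) read_pfm(if (file.exists(p)) p else file.path(dir, p))
    rect <- list(
      left = list(x = rd(kv$rectify_left_x), y = rd(kv$rectify_left_y)),
      right = list(x = rd(kv$rectify_right_x), y = rd(kv$rectify_right_y)))
  }
  list(rig = rig, rectify = rect)
}

# Minimal flat YAML subset: one `key: value` scalar per line, '#' comments,
# blank lines. Sufficient for calibration and pipeline config files.
read_flat_yaml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L)
      stop(sprintf("cannot parse line '%s' in %s (expected 'key: value')", ln, path))
    val <- trimws(m[3L])
    val <- gsub("^['\"]|['\"]$", "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[m[2L]]] <- if (!is.na(num) && grepl("^[-+0-9.eE]+$", val)) num else val
  }
  out
}
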