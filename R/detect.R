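#' Spot-detection parameters
#'
#' Band-pass spot detection with subpixel centroid refinement. The feature
#' band is `(bandpass_low, bandpass_high)` in pixels: structures smaller than
#' `bandpass_low` (noise) and larger than `bandpass_high` (background) are
#' suppressed before local maxima are located.
#'
#' @param bandpass_low,bandpass_high Gaussian scales of the band-pass filter,
#'   pixels; `0 < bandpass_low < bandpass_high`.
#' @param threshold minimum band-passed intensity (counts above local
#'   background) for a candidate maximum. The default suits the default
#'   rendering conditions: ~8 standard deviations of the band-passed read
#'   noise, about 2.5x below the band-passed peak of a default spot.
#' @param min_separation minimum distance between accepted maxima, pixels;
#'   equal-intensity ties keep the candidate with smaller (y, x).
#' @param refine_window side of the square centroid-refinement window,
#'   pixels (odd, >= 3).
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(bandpass_low = 1, bandpass_high = 3,
                             threshold = 1200, min_separation = 5,
                             refine_window = 7) {
  check_number(bandpass_low, "bandpass_low", 0, strict_lower = TRUE)
  check_number(bandpass_high, "bandpass_high", bandpass_low, strict_lower = TRUE)
  check_number(threshold, "threshold", 0)
  check_number(min_separation, "min_separation", 1)
  check_number(refine_window, "refine_window", 3, integer = TRUE)
  if (refine_window %% 2 == 0) stop("'refine_window' must be odd")
  structure(list(bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 threshold = threshold, min_separation = min_separation,
                 refine_window = as.integer(refine_window)),
            class = "detection_params")
}

#' Detect bacterial spots in one frame
#'
#' Pipeline: (1) estimate background by Gaussian smoothing at scale
#' `4 * bandpass_high` and subtract; (2) band-pass filter (difference of
#' Gaussians at `bandpass_low` and `bandpass_high`); (3) keep local maxima
#' above `threshold` separated by at least `min_separation` px; (4) refine
#' each to the intensity-weighted centroid of the background-subtracted image
#' inside `refine_window`. Coordinates are 0-based with pixel centres at
#' integer positions, x = column, y = row, origin top-left.
#'
#' @param frame 2-D numeric matrix (rows = y, columns = x).
#' @param params a [detection_params()] object.
#' @param frame_index 0-based frame index recorded in the output.
#' @return data.frame `frame, x_px, y_px, intensity, diameter_px`, sorted by
#'   (y, x). `intensity` is the summed background-subtracted signal in the
#'   refinement window; `diameter_px` is twice the rms radius of that signal.
#' @export
detect_spots <- function(frame, params = detection_params(), frame_index = 0L) {
  stopifnot(inherits(params, "detection_params"))
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("'frame' must be a 2-D numeric matrix")
  w <- params$refine_window
  if (w > nrow(frame) || w > ncol(frame))
    stop("refine_window larger than the image")
  bg <- cpp_gauss_blur(frame, 4 * params$bandpass_high)
  sub <- frame - bg
  bp <- cpp_gauss_blur(sub, params$bandpass_low) -
    cpp_gauss_blur(sub, params$bandpass_high)
  mx <- cpp_local_maxima(bp, params$threshold, params$min_separation)
  empty <- data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0), diameter_px = numeric(0))
  if (nrow(mx) == 0) return(empty)
  half <- (w - 1L) %/% 2L
  n <- nrow(mx)
  xs <- ys <- inten <- diam <- numeric(n)
  for (q in seq_len(n)) {
    i <- mx[q, 1] + 1L; j <- mx[q, 2] + 1L   # 1-based matrix indices
    i0 <- max(1L, i - half); i1 <- min(nrow(frame), i + half)
    j0 <- max(1L, j - half); j1 <- min(ncol(frame), j + half)
    win <- sub[i0:i1, j0:j1]
    win[win < 0] <- 0
    s <- sum(win)
    if (s <= 0) { xs[q] <- NA; next }
    rows <- (i0:i1) - 1L; cols <- (j0:j1) - 1L   # 0-based coordinates
    cy <- sum(rowSums(win) * rows) / s
    cx <- sum(colSums(win) * cols) / s
    r2 <- sum(win * (outer(rows - cy, cols - cx, function(a, b) a^2 + b^2))) / s
    xs[q] <- cx; ys[q] <- cy; inten[q] <- s; diam[q] <- 2 * sqrt(r2)
  }
  keep <- !is.na(xs)
  out <- data.frame(frame = as.integer(frame_index), x_px = xs[keep],
                    y_px = ys[keep], intensity = inten[keep],
                    diameter_px = diam[keep])
  out[order(out$y_px, out$x_px), , drop = FALSE]
}

#' Detect spots in every frame of a stack
#'
#' @param stack a `h x w x n` array, a list of matrices, or the path of a
#'   TIFF stack written by [write_frame_stack()].
#' @param params a [detection_params()] object.
#' @param verbose log progress every 100 frames.
#' @return concatenated [detect_spots()] tables with 0-based `frame` index;
#'   an empty stack gives the empty table (header only).
#' @export
detect_stack <- function(stack, params = detection_params(), verbose = FALSE) {
  if (is.character(stack)) stack <- read_frame_stack(stack)
  if (is.array(stack) && length(dim(stack)) == 3L) {
    n <- dim(stack)[3]
    get_frame <- function(f) stack[, , f]
  } else if (is.list(stack)) {
    n <- length(stack)
    get_frame <- function(f) stack[[f]]
  } else stop("'stack' must be a 3-D array, list of matrices, or TIFF path")
  res <- vector("list", n)
  for (f in seq_len(n)) {
    fr <- get_frame(f)
    if (!is.matrix(fr)) stop("unreadable frame at index ", f - 1L)
    res[[f]] <- detect_spots(fr, params, frame_index = f - 1L)
    if (verbose && f %% 100 == 0)
      message("detect_stack: frame ", f, "/", n)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0), diameter_px = numeric(0))
  rownames(out) <- NULL
  out
}
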