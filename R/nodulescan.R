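#' Colour-segmentation parameters for stained nodules
#'
#' Nodules are segmented by thresholding in hue/saturation/value space,
#' morphological closing, 8-connected component labelling, optional
#' distance-transform watershed splitting of touching blobs, and an area
#' filter.
#'
#' @param hue_range hue bounds in [0, 1]; when `hue_range[1] > hue_range[2]`
#'   the range wraps around 1 (needed for magenta stains).
#' @param saturation_min minimum saturation in [0, 1].
#' @param value_range brightness bounds in [0, 1].
#' @param min_area,max_area retained region area bounds, px^2
#'   (`0 < min_area < max_area`).
#' @param closing_radius morphological closing disc radius, px (0 disables).
#' @param split_touching split touching blobs by distance-transform
#'   watershed.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(hue_range = c(0.38, 0.62),
                                saturation_min = 0.25,
                                value_range = c(0.1, 0.95),
                                min_area = 50, max_area = 5000,
                                closing_radius = 2, split_touching = TRUE) {
  stopifnot(length(hue_range) == 2, all(hue_range >= 0 & hue_range <= 1),
            length(value_range) == 2,
            all(value_range >= 0 & value_range <= 1),
            value_range[1] <= value_range[2])
  check_number(saturation_min, "saturation_min", 0, 1)
  check_number(min_area, "min_area", 0, strict_lower = TRUE)
  check_number(max_area, "max_area", min_area, strict_lower = TRUE)
  check_number(closing_radius, "closing_radius", 0, integer = TRUE)
  structure(list(hue_range = hue_range, saturation_min = saturation_min,
                 value_range = value_range, min_area = min_area,
                 max_area = max_area, closing_radius = as.integer(closing_radius),
                 split_touching = isTRUE(split_touching)),
            class = "segmentation_params")
}

#' Stain presets for the two nodule marker stains
#'
#' `"xgal"` targets blue-green X-gal-type staining, `"magenta"` the
#' Magenta-GlcA-type stain (hue range wrapping through red).
#'
#' @param stain `"xgal"` or `"magenta"`.
#' @param ... overrides passed to [segmentation_params()].
#' @return a [segmentation_params()] object.
#' @export
stain_preset <- function(stain = c("xgal", "magenta"), ...) {
  stain <- match.arg(stain)
  defaults <- if (stain == "xgal")
    list(hue_range = c(0.38, 0.62), saturation_min = 0.25)
  else
    list(hue_range = c(0.78, 0.02), saturation_min = 0.25)
  args <- utils::modifyList(defaults, list(...))
  do.call(segmentation_params, args)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass over the label pairs.
label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  mx <- max(lab)
  if (mx < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right diagonal
  a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]     # down-left diagonal
  pick <- function(a, b) {
    sel <- a > 0 & b > 0 & a != b
    cbind(a[sel], b[sel])
  }
  pairs <- unique(rbind(pick(a1, b1), pick(a2, b2)))
  parent <- seq_len(mx)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(mx), find, 0L)
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment and count stained nodules in a root photograph
#'
#' Converts the image to hue/saturation/value, masks pixels inside the stain
#' bounds, applies morphological closing, labels connected components
#' (8-connectivity), optionally splits touching blobs by watershed on the
#' distance transform, and retains regions whose area lies in
#' `[min_area, max_area]`.
#'
#' @param image `height x width x 3` array in [0, 1], or a PNG/JPEG path.
#' @param params a [segmentation_params()] object.
#' @param image_id label echoed in the result.
#' @return an object of class `nodule_count_result`: `image_id`, `n_nodules`,
#'   `regions` (data.frame `region, area_px2, x_px, y_px, mean_r, mean_g,
#'   mean_b`; 0-based centroids), `params`, and the label matrix `labels`.
#' @export
segment_nodules <- function(image, params = segmentation_params(),
                            image_id = "image") {
  stopifnot(inherits(params, "segmentation_params"))
  if (is.character(image)) {
    image <- png::readPNG(image)
    if (length(dim(image)) == 3 && dim(image)[3] == 4)
      image <- image[, , 1:3]   # drop alpha
  }
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("colour image required: got greyscale or malformed input")
  h <- dim(image)[1]; w <- dim(image)[2]
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hr <- params$hue_range
  in_hue <- if (hr[1] <= hr[2]) hsv[1, ] >= hr[1] & hsv[1, ] <= hr[2]
  else hsv[1, ] >= hr[1] | hsv[1, ] <= hr[2]
  mask <- in_hue & hsv[2, ] >= params$saturation_min &
    hsv[3, ] >= params$value_range[1] & hsv[3, ] <= params$value_range[2]
  mask <- matrix(as.numeric(mask), h, w)
  if (params$closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * params$closing_radius + 1, shape = "disc")
    mask <- EBImage::imageData(EBImage::closing(EBImage::Image(mask), brush))
  }
  if (params$split_touching && any(mask > 0)) {
    dm <- EBImage::distmap(EBImage::Image(mask))
    lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1, ext = 1))
  } else {
    lab <- label8(mask)
  }
  empty <- data.frame(region = integer(0), area_px2 = numeric(0),
                      x_px = numeric(0), y_px = numeric(0),
                      mean_r = numeric(0), mean_g = numeric(0),
                      mean_b = numeric(0))
  mx <- max(lab)
  if (mx == 0)
    return(structure(list(image_id = image_id, n_nodules = 0L, regions = empty,
                          params = params, labels = lab),
                     class = "nodule_count_result"))
  areas <- tabulate(lab[lab > 0], nbins = mx)
  keep <- which(areas >= params$min_area & areas <= params$max_area)
  if (!length(keep))
    return(structure(list(image_id = image_id, n_nodules = 0L, regions = empty,
                          params = params, labels = lab),
                     class = "nodule_count_result"))
  rows <- row(lab); cols <- col(lab)
  regions <- do.call(rbind, lapply(seq_along(keep), function(q) {
    sel <- lab == keep[q]
    data.frame(region = q, area_px2 = areas[keep[q]],
               x_px = mean(cols[sel]) - 1, y_px = mean(rows[sel]) - 1,
               mean_r = mean(image[, , 1][sel]),
               mean_g = mean(image[, , 2][sel]),
               mean_b = mean(image[, , 3][sel]))
  }))
  structure(list(image_id = image_id, n_nodules = length(keep),
                 regions = regions, params = params, labels = lab),
            class = "nodule_count_result")
}

#' @export
print.nodule_count_result <- function(x, ...) {
  cat(sprintf("nodule_count_result '%s': %d nodules\n", x$image_id, x$n_nodules))
  invisible(x)
}
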