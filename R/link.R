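#' Track-linking parameters
#'
#' @param max_disp maximum displacement a cell may move between consecutive
#'   frames, pixels. `NULL` asks [link_detections()] callers to derive it
#'   from the experiment configuration (see [default_max_disp()]).
#' @param memory number of frames a track may persist unmatched before it is
#'   terminated (gap closing).
#' @param min_track_len minimum track length, frames (>= 2); shorter tracks
#'   are discarded by [filter_tracks()].
#' @param min_net_disp minimum net start-to-end displacement, pixels;
#'   immobile debris below this is discarded by [filter_tracks()].
#' @return an object of class `link_params`.
#' @export
link_params <- function(max_disp, memory = 1, min_track_len = 10,
                        min_net_disp = 5) {
  check_number(max_disp, "max_disp", 0, strict_lower = TRUE)
  check_number(memory, "memory", 0, integer = TRUE)
  check_number(min_track_len, "min_track_len", 2, integer = TRUE)
  check_number(min_net_disp, "min_net_disp", 0)
  structure(list(max_disp = max_disp, memory = as.integer(memory),
                 min_track_len = as.integer(min_track_len),
                 min_net_disp = min_net_disp),
            class = "link_params")
}

#' Default linking gate derived from the experiment configuration
#'
#' A generous per-frame displacement gate: `ceil(1.5 * mean_speed / fps /
#' pixel_size)` pixels, i.e. 1.5x the expected per-frame step.
#'
#' @param mean_speed expected swimming speed, um/s.
#' @param fps frame rate, frames/s.
#' @param pixel_size calibration, um/pixel.
#' @return gate radius in pixels.
#' @export
default_max_disp <- function(mean_speed, fps, pixel_size) {
  ceiling(1.5 * mean_speed / fps / pixel_size)
}

#' Optimal gated matching between two point sets
#'
#' Solves the frame-pair correspondence problem: minimise the total cost
#' `sum(d^2)` over matched pairs plus `(max_disp * gap_i)^2` for every
#' unmatched source point and `max_disp^2` for every unmatched target point,
#' where pairs farther apart than `max_disp * gap_i` are forbidden. Because
#' any allowed match is cheaper than leaving both ends unmatched, the optimum
#' is a maximum-cardinality matching of minimum squared displacement.
#'
#' @param prev numeric matrix `n x 2` of source (x, y) positions.
#' @param curr numeric matrix `m x 2` of target (x, y) positions.
#' @param max_disp gate radius per frame interval, pixels.
#' @param gaps integer vector (length `n`) of frame gaps since each source
#'   point was last seen (1 = consecutive frames).
#' @return list with `matches` (data.frame `i, j, cost, contested`; 1-based
#'   row indices into `prev` and `curr`; `contested` marks matches with
#'   alternative in-gate candidates on either side), `unmatched_prev`,
#'   `unmatched_curr`, and the `total_cost` of the optimal assignment.
#' @export
match_points <- function(prev, curr, max_disp, gaps = rep(1L, nrow(prev))) {
  prev <- as.matrix(prev); curr <- as.matrix(curr)
  n <- nrow(prev); m <- nrow(curr)
  check_number(max_disp, "max_disp", 0, strict_lower = TRUE)
  stopifnot(length(gaps) == n)
  gate <- max_disp * gaps
  if (n == 0 || m == 0) {
    return(list(matches = data.frame(i = integer(0), j = integer(0),
                                     cost = numeric(0), contested = logical(0)),
                unmatched_prev = seq_len(n), unmatched_curr = seq_len(m),
                total_cost = sum(gate^2) + m * max_disp^2))
  }
  BIG <- 1e12
  d2 <- outer(prev[, 1], curr[, 1], "-")^2 + outer(prev[, 2], curr[, 2], "-")^2
  cost <- d2
  cost[d2 > (gate^2)[row(d2)]] <- BIG
  sz <- n + m
  A <- matrix(0, sz, sz)
  A[seq_len(n), seq_len(m)] <- cost
  A[seq_len(n), m + seq_len(n)] <- BIG
  A[seq_len(n), m + seq_len(n)][cbind(seq_len(n), seq_len(n))] <- gate^2
  A[n + seq_len(m), seq_len(m)] <- BIG
  A[n + seq_len(m), seq_len(m)][cbind(seq_len(m), seq_len(m))] <- max_disp^2
  asg <- cpp_solve_lsap(A) + 1L   # column assigned to each row, 1-based
  mi <- which(asg[seq_len(n)] <= m & cost[cbind(seq_len(n), pmin(asg[seq_len(n)], m))] < BIG)
  mj <- asg[mi]
  # a match is contested when the source had other in-gate candidate targets
  # or the target other in-gate candidate sources: identity swaps live here
  gated <- cost < BIG
  contested <- if (length(mi))
    rowSums(gated)[mi] > 1L | colSums(gated)[mj] > 1L else logical(0)
  matches <- data.frame(i = mi, j = mj,
                        cost = if (length(mi)) d2[cbind(mi, mj)] else numeric(0),
                        contested = contested)
  up <- setdiff(seq_len(n), mi)
  uc <- setdiff(seq_len(m), mj)
  list(matches = matches, unmatched_prev = up, unmatched_curr = uc,
       total_cost = sum(matches$cost) + sum(gate[up]^2) + length(uc) * max_disp^2)
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame correspondence is solved by optimal assignment
#' ([match_points()]) within a displacement gate. Unmatched tracks persist up
#' to `memory` frames and then terminate; unmatched detections start new
#' tracks; track ids are assigned in order of first appearance. Frames missed
#' inside a surviving track are filled by linear interpolation and flagged
#' `is_gap = TRUE`. Points whose assignment had alternative in-gate
#' candidates (close encounters, where identity swaps can occur) are flagged
#' `is_contested = TRUE`; tumble detection excludes them.
#'
#' @param det detection table (`frame, x_px, y_px`, sorted by frame).
#' @param params a [link_params()] object.
#' @return data.frame `track_id, frame, x_px, y_px, is_gap, is_contested`
#'   ordered by (track_id, frame).
#' @export
link_detections <- function(det, params) {
  stopifnot(inherits(params, "link_params"))
  check_columns(det, c("frame", "x_px", "y_px"), "det")
  if (nrow(det) == 0)
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x_px = numeric(0), y_px = numeric(0), is_gap = logical(0),
                      is_contested = logical(0)))
  if (is.unsorted(det$frame)) stop("'det' must be sorted by frame")
  if (any(!is.finite(det$x_px)) || any(!is.finite(det$y_px)))
    stop("'det' contains non-finite coordinates")

  f0 <- min(det$frame); f1 <- max(det$frame)
  by_frame <- split(det[, c("x_px", "y_px")],
                    factor(det$frame, levels = f0:f1))
  tracks <- list()        # finished + live track records
  next_id <- 1L
  live <- integer(0)      # indices into `tracks` of live tracks

  new_track <- function(frame, x, y) {
    tracks[[next_id]] <<- list(id = next_id,
                               frame = frame, x = x, y = y, gap = FALSE,
                               contested = FALSE,
                               last_frame = frame, last_x = x, last_y = y)
    live <<- c(live, next_id)
    next_id <<- next_id + 1L
  }
  dets <- by_frame[[1]]
  if (nrow(dets)) for (q in seq_len(nrow(dets)))
    new_track(f0, dets$x_px[q], dets$y_px[q])

  for (t in seq(f0 + 1, length.out = f1 - f0)) {
    dets <- by_frame[[t - f0 + 1L]]
    nc <- nrow(dets)
    np <- length(live)
    matched_live <- logical(np)
    if (np && nc) {
      prev <- cbind(vapply(tracks[live], `[[`, 0, "last_x"),
                    vapply(tracks[live], `[[`, 0, "last_y"))
      gaps <- t - vapply(tracks[live], `[[`, 0, "last_frame")
      res <- match_points(prev, as.matrix(dets), params$max_disp, gaps)
      if (nrow(res$matches)) for (r in seq_len(nrow(res$matches))) {
        k <- live[res$matches$i[r]]
        j <- res$matches$j[r]
        tr <- tracks[[k]]
        gap <- t - tr$last_frame
        if (gap > 1L) {  # interpolate the missed frames, flagged
          tt <- seq_len(gap - 1L)
          w <- tt / gap
          tr$frame <- c(tr$frame, tr$last_frame + tt)
          tr$x <- c(tr$x, tr$last_x + w * (dets$x_px[j] - tr$last_x))
          tr$y <- c(tr$y, tr$last_y + w * (dets$y_px[j] - tr$last_y))
          tr$gap <- c(tr$gap, rep(TRUE, gap - 1L))
          tr$contested <- c(tr$contested, rep(FALSE, gap - 1L))
        }
        tr$frame <- c(tr$frame, t)
        tr$x <- c(tr$x, dets$x_px[j]); tr$y <- c(tr$y, dets$y_px[j])
        tr$gap <- c(tr$gap, FALSE)
        tr$contested <- c(tr$contested, res$matches$contested[r])
        tr$last_frame <- t; tr$last_x <- dets$x_px[j]; tr$last_y <- dets$y_px[j]
        tracks[[k]] <- tr
        matched_live[res$matches$i[r]] <- TRUE
      }
      unmatched_dets <- res$unmatched_curr
    } else {
      unmatched_dets <- seq_len(nc)
    }
    # retire tracks unmatched for longer than `memory` frames
    ages <- t - vapply(tracks[live], `[[`, 0, "last_frame")
    live <- live[ages <= params$memory]
    if (nc) for (j in unmatched_dets)
      new_track(t, dets$x_px[j], dets$y_px[j])
  }

  out <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(track_id = tr$id, frame = tr$frame, x_px = tr$x, y_px = tr$y,
               is_gap = tr$gap, is_contested = tr$contested)
  }))
  rownames(out) <- NULL
  out
}

#' Quality-filter linked tracks
#'
#' Drops tracks shorter than `min_track_len` frames and tracks whose net
#' start-to-end displacement is below `min_net_disp` pixels (immobile
#' debris). The counts removed by each rule are attached as attribute
#' `"dropped"` and logged.
#'
#' @param tracks a [link_detections()] table.
#' @param params a [link_params()] object.
#' @param verbose log the drop counts.
#' @return the filtered track table.
#' @export
filter_tracks <- function(tracks, params, verbose = FALSE) {
  stopifnot(inherits(params, "link_params"))
  check_columns(tracks, c("track_id", "frame", "x_px", "y_px"), "tracks")
  if (nrow(tracks) == 0) {
    attr(tracks, "dropped") <- c(short = 0L, immobile = 0L)
    return(tracks)
  }
  idx <- split(seq_len(nrow(tracks)), tracks$track_id)
  lens <- lengths(idx)
  net <- vapply(idx, function(ii) {
    sqrt((tracks$x_px[ii[length(ii)]] - tracks$x_px[ii[1]])^2 +
           (tracks$y_px[ii[length(ii)]] - tracks$y_px[ii[1]])^2)
  }, 0)
  short <- lens < params$min_track_len
  immobile <- !short & net < params$min_net_disp
  keep_ids <- names(idx)[!short & !immobile]
  dropped <- c(short = sum(short), immobile = sum(immobile))
  if (verbose)
    message("filter_tracks: dropped ", dropped["short"], " short and ",
            dropped["immobile"], " immobile of ", length(idx), " tracks")
  out <- tracks[tracks$track_id %in% as.integer(keep_ids), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
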