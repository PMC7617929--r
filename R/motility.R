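#' Tumble-detection parameters
#'
#' Tumbles are flagged at trajectory vertices whose turning angle exceeds
#' `turn_threshold` (and, when `speed_drop_fraction > 0`, whose instantaneous
#' speed drops below `(1 - speed_drop_fraction)` times the track median).
#' The default threshold sits at ~3 standard deviations of the per-interval
#' heading jitter expected from rotational diffusion at 10 frames/s
#' (`sqrt(0.062 rad^2/s / 10 fps)` is about 4.5 degrees), so run-phase wander
#' is rarely mistaken for a tumble while shallow genuine tumbles below the
#' threshold are, unavoidably, missed.
#'
#' @param turn_threshold minimum absolute turning angle per frame interval,
#'   degrees (0-180).
#' @param speed_drop_fraction fraction of the track median speed below which
#'   the instantaneous speed must fall (0 disables the speed criterion;
#'   appropriate when tumbles are near-instantaneous at the frame rate).
#' @param smooth_window centred moving-average window applied to positions
#'   before headings are computed, frames (odd). The default 1 (no
#'   smoothing) preserves the full turning angle of a single-frame
#'   reorientation; larger windows suit noisier real data but attenuate
#'   sharp turns.
#' @param min_run_frames flagged vertices closer than this merge into one
#'   event at the frame of maximal turning.
#' @return an object of class `tumble_params`.
#' @export
tumble_params <- function(turn_threshold = 15, speed_drop_fraction = 0,
                          smooth_window = 1, min_run_frames = 3) {
  check_number(turn_threshold, "turn_threshold", 0, 180, strict_lower = TRUE)
  if (turn_threshold >= 180) stop("'turn_threshold' must be < 180")
  check_number(speed_drop_fraction, "speed_drop_fraction", 0)
  if (speed_drop_fraction >= 1) stop("'speed_drop_fraction' must be < 1")
  check_number(smooth_window, "smooth_window", 1, integer = TRUE)
  if (smooth_window %% 2 == 0) stop("'smooth_window' must be odd")
  check_number(min_run_frames, "min_run_frames", 1, integer = TRUE)
  structure(list(turn_threshold = turn_threshold,
                 speed_drop_fraction = speed_drop_fraction,
                 smooth_window = as.integer(smooth_window),
                 min_run_frames = as.integer(min_run_frames)),
            class = "tumble_params")
}

#' Per-track swimming speed
#'
#' Per-step speed is the displacement between consecutive recorded frames
#' times `fps` divided by the frame gap; with gap-closed tracks the rows are
#' contiguous, so each row-to-row step spans one frame interval. Steps that
#' touch an interpolated (gap) row measure real displacement over the gap and
#' are included in the mean, flagged in the returned series.
#'
#' @param track one track's rows (`frame, x_px, y_px`, optional `is_gap`),
#'   ordered by frame.
#' @param pixel_size um/pixel. @param fps frames/s.
#' @return list with `mean_speed` (um/s, time-weighted mean of per-step
#'   speeds) and `steps` (data.frame `frame, speed_um_s, from_gap`).
#' @export
compute_speed <- function(track, pixel_size, fps) {
  check_columns(track, c("frame", "x_px", "y_px"), "track")
  if (nrow(track) < 2)
    stop("track must have at least 2 points to compute a speed")
  if (is.unsorted(track$frame, strictly = TRUE))
    stop("track frames must be strictly increasing")
  n <- nrow(track)
  gapf <- if ("is_gap" %in% names(track)) track$is_gap else rep(FALSE, n)
  cntf <- if ("is_contested" %in% names(track)) track$is_contested else rep(FALSE, n)
  dg <- diff(track$frame)
  disp <- sqrt(diff(track$x_px)^2 + diff(track$y_px)^2) * pixel_size
  speed <- disp * fps / dg
  from_gap <- gapf[-n] | gapf[-1]
  from_contested <- cntf[-n] | cntf[-1]
  # time-weighted mean: each step spans dg frame intervals
  list(mean_speed = sum(speed * dg) / sum(dg),
       steps = data.frame(frame = track$frame[-n], speed_um_s = speed,
                          from_gap = from_gap,
                          from_contested = from_contested))
}

#' Detect tumble events along one track
#'
#' Positions are optionally smoothed by a centred moving average, headings
#' taken between consecutive positions, and the turning angle evaluated at
#' every interior vertex. Vertices exceeding `turn_threshold` (and passing
#' the speed-drop criterion when enabled) are flagged; flagged vertices
#' closer than `min_run_frames` merge into a single event at the frame of
#' maximal turning. Vertices whose adjacent steps involve interpolated gap
#' rows (interpolation manufactures straight segments) or contested linking
#' assignments (close encounters, where identity swaps forge sharp kinks)
#' never seed events; they are censored from the analysable exposure
#' instead.
#'
#' @param track one track's rows ordered by frame.
#' @param params a [tumble_params()] object.
#' @param pixel_size um/pixel. @param fps frames/s.
#' @return integer vector of 0-based event frames. Attribute
#'   `"usable_vertices"` counts the analysable (uncensored) vertices, each
#'   covering one frame interval of tumble exposure; attribute `"too_short"`
#'   is set when the track was too short to analyse.
#' @export
detect_tumbles <- function(track, params = tumble_params(), pixel_size = 1,
                           fps = 1) {
  stopifnot(inherits(params, "tumble_params"))
  check_columns(track, c("frame", "x_px", "y_px"), "track")
  n <- nrow(track)
  need <- max(params$smooth_window + 2L, 3L)
  if (n < need) {
    out <- integer(0)
    attr(out, "too_short") <- TRUE
    attr(out, "usable_vertices") <- 0L
    return(out)
  }
  x <- track$x_px; y <- track$y_px
  w <- params$smooth_window
  if (w > 1) {
    x <- smooth_ma(x, w)
    y <- smooth_ma(y, w)
  }
  dx <- diff(x); dy <- diff(y)
  head_ang <- atan2(dy, dx)
  turn <- diff(head_ang)
  turn <- (turn + pi) %% (2 * pi) - pi          # wrap to (-pi, pi]
  turn_deg <- abs(turn) * 180 / pi
  # vertex v sits at track row v + 1 (between steps v and v + 1)
  flagged <- turn_deg > params$turn_threshold
  bad_pt <- if ("is_gap" %in% names(track)) track$is_gap else rep(FALSE, n)
  if ("is_contested" %in% names(track)) bad_pt <- bad_pt | track$is_contested
  step_bad <- bad_pt[-n] | bad_pt[-1]
  vertex_bad <- step_bad[-length(step_bad)] | step_bad[-1]
  flagged <- flagged & !vertex_bad
  usable <- sum(!vertex_bad)
  if (params$speed_drop_fraction > 0) {
    sp <- compute_speed(track, pixel_size, fps)$steps$speed_um_s
    vsp <- (sp[-length(sp)] + sp[-1]) / 2       # speed at each vertex
    flagged <- flagged & vsp < (1 - params$speed_drop_fraction) * median(sp)
  }
  out <- if (!any(flagged)) integer(0) else {
    vf <- which(flagged)                        # vertex indices (1-based)
    grp <- cumsum(c(1L, diff(vf) >= params$min_run_frames))
    ev <- vapply(split(vf, grp), function(vv) vv[which.max(turn_deg[vv])], 0L)
    sort(as.integer(track$frame[ev + 1L]))
  }
  attr(out, "usable_vertices") <- as.integer(usable)
  if (usable == 0L) attr(out, "too_short") <- TRUE
  out
}

smooth_ma <- function(v, w) {
  half <- (w - 1L) %/% 2L
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Per-track motility metrics
#'
#' @param tracks a (filtered) [link_detections()] table.
#' @param pixel_size um/pixel. @param fps frames/s.
#' @param params a [tumble_params()] object.
#' @param frame_dims optional `c(width, height)` in pixels; when given,
#'   tracks starting or ending within `edge_margin` of the border are flagged
#'   `boundary_truncated`.
#' @param edge_margin pixels (default 3).
#' @return data.frame `track_id, n_points, duration_s, exposure_s,
#'   mean_speed_um_s, n_tumbles, tumble_rate_per_s, too_short,
#'   boundary_truncated`. `duration_s` is the raw frame span
#'   `(last - first) / fps`; `exposure_s` is the analysable tumble exposure
#'   (usable vertices / fps) after censoring gap-interpolated and contested
#'   intervals and the unobservable track edges, and is the denominator of
#'   `tumble_rate_per_s` so that censoring does not bias the rate.
#' @export
track_metrics <- function(tracks, pixel_size, fps, params = tumble_params(),
                          frame_dims = NULL, edge_margin = 3) {
  check_columns(tracks, c("track_id", "frame", "x_px", "y_px"), "tracks")
  idx <- split(seq_len(nrow(tracks)), tracks$track_id)
  res <- lapply(idx, function(ii) {
    tr <- tracks[ii, , drop = FALSE]
    dur <- (tr$frame[nrow(tr)] - tr$frame[1]) / fps
    spd <- NA_real_
    if (nrow(tr) >= 2) {
      cs <- compute_speed(tr, pixel_size, fps)
      ok <- !cs$steps$from_contested   # swap-prone steps distort displacement
      spd <- if (any(ok)) mean(cs$steps$speed_um_s[ok]) else cs$mean_speed
    }
    ev <- detect_tumbles(tr, params, pixel_size, fps)
    too_short <- isTRUE(attr(ev, "too_short"))
    usable <- attr(ev, "usable_vertices")
    exposure <- usable / fps
    bt <- NA
    if (!is.null(frame_dims)) {
      ends <- tr[c(1, nrow(tr)), ]
      bt <- any(ends$x_px < edge_margin | ends$x_px > frame_dims[1] - 1 - edge_margin |
                  ends$y_px < edge_margin | ends$y_px > frame_dims[2] - 1 - edge_margin)
    }
    data.frame(track_id = tr$track_id[1], n_points = nrow(tr),
               duration_s = dur, exposure_s = exposure,
               mean_speed_um_s = spd, n_tumbles = length(ev),
               tumble_rate_per_s = if (exposure > 0) length(ev) / exposure else NA_real_,
               too_short = too_short, boundary_truncated = bt)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Population summary of motility metrics
#'
#' Per-group summaries over per-track metrics, excluding tracks flagged too
#' short. Speeds are the unweighted mean and SD across tracks. The
#' population tumble rate is the exposure-weighted mean of per-track rates
#' (equal to pooled events over pooled exposure): with an absorbing field of
#' view, cells that tumble change direction and stay in view longer, so
#' track exposure and tumbling are positively coupled and an unweighted mean
#' of per-track rates is biased low by selection of ballistic short
#' crossings. `tumble_sd` remains the SD of the per-track rates, describing
#' their dispersion (strongly zero-inflated when rate x exposure < 1).
#'
#' @param metrics a [track_metrics()] table.
#' @param groups group label per row of `metrics` (strain x condition).
#' @return data.frame `group, n_tracks, speed_mean, speed_sd, tumble_mean,
#'   tumble_sd`. Empty groups give `n_tracks = 0` with missing summaries and
#'   a warning.
#' @export
summarize_population <- function(metrics, groups) {
  check_columns(metrics, c("mean_speed_um_s", "tumble_rate_per_s",
                           "n_tumbles", "exposure_s", "too_short"), "metrics")
  stopifnot(length(groups) == nrow(metrics))
  groups <- factor(groups)
  rows <- lapply(levels(groups), function(g) {
    m <- metrics[groups == g & !metrics$too_short, , drop = FALSE]
    if (nrow(m) == 0) {
      warning("group '", g, "' has no usable tracks")
      return(data.frame(group = g, n_tracks = 0L, speed_mean = NA_real_,
                        speed_sd = NA_real_, tumble_mean = NA_real_,
                        tumble_sd = NA_real_))
    }
    data.frame(group = g, n_tracks = nrow(m),
               speed_mean = mean(m$mean_speed_um_s),
               speed_sd = sd(m$mean_speed_um_s),
               tumble_mean = sum(m$n_tumbles) / sum(m$exposure_s),
               tumble_sd = sd(m$tumble_rate_per_s))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Motility parameters of wildtype R. leguminosarum by growth condition
#'
#' Published single-cell tracking statistics for wildtype Rlv3841 swimming in
#' minimal media under carbon starvation: mean speed (um/s), between-track
#' speed SD, and mean tumble rate (events/s) on 1 mM glucose, 3 mM pyruvate
#' and 2 mM succinate. Used as generative ground truth for recovery studies.
#'
#' @return data.frame `condition, mean_speed, speed_sd, tumble_rate`.
#' @export
rlv_motility_params <- function() {
  data.frame(condition = c("glucose", "pyruvate", "succinate"),
             mean_speed = c(44, 38, 41),
             speed_sd = c(7, 6, 7),
             tumble_rate = c(0.11, 0.14, 0.08))
}
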