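# Shared fixtures: everything is generated in code at test time.

# a straight-line track table moving at `speed` um/s along `angle`
straight_track <- function(n = 30, speed = 44, angle = 0.3, pixel_size = 0.2,
                           fps = 10, x0 = 50, y0 = 50) {
  step <- speed / fps / pixel_size
  data.frame(track_id = 1L, frame = 0:(n - 1),
             x_px = x0 + step * cos(angle) * (0:(n - 1)),
             y_px = y0 + step * sin(angle) * (0:(n - 1)),
             is_gap = FALSE, is_contested = FALSE)
}

# noiseless frame with Gaussian spots at the given 0-based (x, y) positions
spot_frame <- function(xy, width = 128, height = 128, amplitude = 6000,
                       sigma = 1.5, background = 1200) {
  img <- matrix(background, height, width)
  xs <- matrix(0:(width - 1), height, width, byrow = TRUE)
  ys <- matrix(0:(height - 1), height, width)
  for (q in seq_len(nrow(xy)))
    img <- img + amplitude *
      exp(-((xs - xy[q, 1])^2 + (ys - xy[q, 2])^2) / (2 * sigma^2))
  img
}

# brute-force gated assignment oracle: enumerate all matchings recursively,
# minimising sum(d^2) over matches + (max_disp * gap_i)^2 per unmatched
# source + max_disp^2 per unmatched target. Independent of the package's
# shortest-augmenting-path solver.
brute_force_assignment_cost <- function(prev, curr, max_disp,
                                        gaps = rep(1, nrow(prev))) {
  n <- nrow(prev); m <- nrow(curr)
  gate <- max_disp * gaps
  d2 <- outer(prev[, 1], curr[, 1], "-")^2 + outer(prev[, 2], curr[, 2], "-")^2
  rec <- function(i, used) {
    if (i > n) return(sum(!used) * max_disp^2)
    best <- gate[i]^2 + rec(i + 1, used)       # leave source i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && d2[i, j] <= gate[i]^2) {
        used[j] <- TRUE
        best <- min(best, d2[i, j] + rec(i + 1, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1, rep(FALSE, m))
}
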