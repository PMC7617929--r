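test_that("a straight noiseless mover recovers its speed to 1e-6 relative", {
  tr <- straight_track(n = 30, speed = 44)
  sp <- compute_speed(tr, pixel_size = 0.2, fps = 10)
  expect_equal(sp$mean_speed, 44, tolerance = 1e-6)
  static <- straight_track(n = 10, speed = 0)
  expect_equal(compute_speed(static, 0.2, 10)$mean_speed, 0)
  expect_error(compute_speed(straight_track(n = 1), 0.2, 10), "at least 2")
})

test_that("speed uses real displacement over gap-closed frames", {
  tr <- straight_track(n = 21, speed = 40)
  tr$is_gap[11] <- TRUE   # pretend frame 10 was interpolated
  sp <- compute_speed(tr, 0.2, 10)
  expect_equal(sp$mean_speed, 40, tolerance = 1e-9)
  expect_equal(sum(sp$steps$from_gap), 2)
})

test_that("a single sharp turn yields exactly one tumble event at the turn frame", {
  step <- 22
  x <- c(0:19 * step, 19 * step + 0 * (1:20))
  y <- c(rep(0, 20), 1:20 * step)
  tr <- data.frame(track_id = 1L, frame = 0:39, x_px = x, y_px = y,
                   is_gap = FALSE, is_contested = FALSE)
  ev <- detect_tumbles(tr, tumble_params(turn_threshold = 50,
                                         speed_drop_fraction = 0,
                                         smooth_window = 1), 0.2, 10)
  expect_equal(as.integer(ev), 19L)
  straight <- straight_track(n = 40)
  expect_length(detect_tumbles(straight, tumble_params(), 0.2, 10), 0)
})

test_that("gap-flagged and contested intervals never seed tumble events", {
  step <- 22
  x <- c(0:19 * step, 19 * step + 0 * (1:20))
  y <- c(rep(0, 20), 1:20 * step)
  tr <- data.frame(track_id = 1L, frame = 0:39, x_px = x, y_px = y,
                   is_gap = FALSE, is_contested = FALSE)
  tr$is_contested[20] <- TRUE    # the corner detection was ambiguous
  ev <- detect_tumbles(tr, tumble_params(turn_threshold = 50), 0.2, 10)
  expect_length(ev, 0)
  expect_lt(attr(ev, "usable_vertices"), 38)
  tr$is_contested[20] <- FALSE
  tr$is_gap[20] <- TRUE
  expect_length(detect_tumbles(tr, tumble_params(turn_threshold = 50), 0.2, 10), 0)
})

test_that("too-short tracks report no events plus a flag", {
  tr <- straight_track(n = 2)
  ev <- detect_tumbles(tr, tumble_params(), 0.2, 10)
  expect_length(ev, 0)
  expect_true(attr(ev, "too_short"))
})

test_that("metrics are invariant under rotation and translation of coordinates", {
  set.seed(31)
  sw <- swimmer_params(n_cells = 6, mean_speed = 44, speed_sd = 7,
                       tumble_rate = 0.3, duration = 3,
                       fov_width = 5000, fov_height = 5000, seed = 17)
  tr <- simulate_tracks(sw, imaging_params())
  tab <- data.frame(track_id = tr$tracks$cell_id, frame = tr$tracks$frame,
                    x_px = tr$tracks$x_um / 0.2, y_px = tr$tracks$y_um / 0.2,
                    is_gap = FALSE, is_contested = FALSE)
  m0 <- track_metrics(tab, 0.2, 10)
  th <- 0.71
  rot <- tab
  rot$x_px <- cos(th) * tab$x_px - sin(th) * tab$y_px + 1234.5
  rot$y_px <- sin(th) * tab$x_px + cos(th) * tab$y_px - 987.1
  m1 <- track_metrics(rot, 0.2, 10)
  expect_equal(m1$mean_speed_um_s, m0$mean_speed_um_s, tolerance = 1e-9)
  expect_equal(m1$n_tumbles, m0$n_tumbles)
})

test_that("downsampling a 20 fps simulation to 10 fps changes mean speed by < 5%", {
  sw <- swimmer_params(n_cells = 150, mean_speed = 44, speed_sd = 7,
                       tumble_rate = 0.11, duration = 5,
                       fov_width = 2000, fov_height = 2000, seed = 23)
  im20 <- imaging_params(fps = 20)
  tr <- simulate_tracks(sw, im20)
  tab <- data.frame(track_id = tr$tracks$cell_id, frame = tr$tracks$frame,
                    x_px = tr$tracks$x_um / 0.2, y_px = tr$tracks$y_um / 0.2,
                    is_gap = FALSE, is_contested = FALSE)
  m20 <- track_metrics(tab, 0.2, 20)
  down <- tab[tab$frame %% 2 == 0, ]
  down$frame <- down$frame %/% 2
  m10 <- track_metrics(down, 0.2, 10)
  s20 <- mean(m20$mean_speed_um_s)
  s10 <- mean(m10$mean_speed_um_s)
  expect_lt(abs(s10 - s20) / s20, 0.05)
})

test_that("population summaries compute per-group means and SDs and flag empty groups", {
  mets <- data.frame(track_id = 1:3, n_points = 20, duration_s = 2,
                     exposure_s = 1.8,
                     mean_speed_um_s = c(40, 44, 48), n_tumbles = 0,
                     tumble_rate_per_s = 0, too_short = FALSE,
                     boundary_truncated = FALSE)
  s <- summarize_population(mets, rep("g", 3))
  expect_equal(s$speed_mean, 44)
  expect_equal(s$speed_sd, 4)
  two <- summarize_population(rbind(mets, mets), rep(c("a", "b"), each = 3))
  expect_equal(two$speed_mean[1], two$speed_mean[2])
  expect_equal(two$tumble_sd[1], two$tumble_sd[2])
  mets2 <- mets; mets2$too_short <- TRUE
  expect_warning(s2 <- summarize_population(mets2, rep("g", 3)), "no usable")
  expect_equal(s2$n_tracks, 0L)
})

test_that("recovered strain ordering matches the generative ordering (che1-like swims faster, tumbles less)", {
  im <- imaging_params(frame_width = 512, frame_height = 512)
  run <- function(speed, rate, seed) {
    sw <- swimmer_params(n_cells = 12, mean_speed = speed, speed_sd = 7,
                         tumble_rate = rate, duration = 3, seed = seed)
    track_motility_experiment(sw, im, n_batches = 8)$summary
  }
  wt <- run(44, 0.11, 301)
  che1 <- run(54, 0.05, 601)   # faster, rarely tumbling
  expect_gt(che1$speed_mean, wt$speed_mean)
  expect_lt(che1$tumble_mean, wt$tumble_mean)
})

test_that("per-track tumble rates are overdispersed when events per track are rare", {
  sw <- swimmer_params(n_cells = 300, mean_speed = 44, speed_sd = 7,
                       tumble_rate = 0.11, duration = 3,
                       fov_width = 2000, fov_height = 2000, seed = 41)
  tr <- simulate_tracks(sw, imaging_params())
  tab <- data.frame(track_id = tr$tracks$cell_id, frame = tr$tracks$frame,
                    x_px = tr$tracks$x_um / 0.2, y_px = tr$tracks$y_um / 0.2,
                    is_gap = FALSE, is_contested = FALSE)
  m <- track_metrics(tab, 0.2, 10)
  s <- summarize_population(m, rep("all", nrow(m)))
  # generative rate x duration < 1: many zero-event tracks, SD exceeds mean
  expect_gt(s$tumble_sd, s$tumble_mean)
})
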