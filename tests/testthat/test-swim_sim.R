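im_small <- imaging_params(frame_width = 256, frame_height = 256, seed = 5)

test_that("ballistic limit: zero tumbling and zero rotational diffusion give straight lines", {
  sw <- swimmer_params(n_cells = 5, mean_speed = 44, speed_sd = 0,
                       tumble_rate = 0, rot_diffusion = 0, duration = 2,
                       fov_width = 1e4, fov_height = 1e4, seed = 3)
  tr <- simulate_tracks(sw, im_small)
  for (id in 1:5) {
    d <- tr$tracks[tr$tracks$cell_id == id, ]
    steps <- sqrt(diff(d$x_um)^2 + diff(d$y_um)^2)
    expect_equal(steps, rep(4.4, nrow(d) - 1), tolerance = 1e-12)
    net <- sqrt((d$x_um[nrow(d)] - d$x_um[1])^2 + (d$y_um[nrow(d)] - d$y_um[1])^2)
    expect_equal(net, 44 * (nrow(d) - 1) / 10, tolerance = 1e-9)
  }
  expect_equal(sum(lengths(tr$tumble_frames)), 0)
})

test_that("short simulations record exactly the requested frames unless the cell exits", {
  sw <- swimmer_params(n_cells = 1, mean_speed = 10, speed_sd = 0,
                       tumble_rate = 0, duration = 0.3,
                       fov_width = 1e3, fov_height = 1e3, seed = 9)
  tr <- simulate_tracks(sw, im_small)
  expect_equal(nrow(tr$tracks), 3)
  expect_equal(tr$tracks$frame, 0:2)
})

test_that("speed and tumble statistics match the generative parameters within sampling error", {
  sw <- swimmer_params(n_cells = 600, mean_speed = 44, speed_sd = 7,
                       tumble_rate = 0.11, duration = 30,
                       fov_width = 2000, fov_height = 2000, seed = 12)
  tr <- simulate_tracks(sw, imaging_params())
  se_speed <- 7 / sqrt(600)
  expect_lt(abs(mean(tr$true_speeds) - 44), 2 * se_speed + 0.2)
  obs_s <- sum(tapply(tr$tracks$frame, tr$tracks$cell_id, length) - 1) / 10
  n_tum <- sum(lengths(tr$tumble_frames))
  rate <- n_tum / obs_s
  se_rate <- sqrt(n_tum) / obs_s
  expect_lt(abs(rate - 0.11), 3 * se_rate)
})

test_that("simulation and rendering are deterministic under a fixed seed", {
  sw <- swimmer_params(n_cells = 8, duration = 1, seed = 21)
  t1 <- simulate_tracks(sw, im_small)
  t2 <- simulate_tracks(sw, im_small)
  expect_identical(t1, t2)
  expect_identical(render_video(t1, im_small), render_video(t2, im_small))
})

test_that("invalid swimmer parameters are rejected with the field named", {
  expect_error(swimmer_params(mean_speed = -1), "mean_speed")
  expect_error(swimmer_params(tumble_rate = NaN), "tumble_rate")
  expect_error(swimmer_params(speed_sd = -0.1), "speed_sd")
  expect_error(swimmer_params(duration = 0), "duration")
})

test_that("a noiseless rendered cell sits at its true position and resolves from a neighbour", {
  im0 <- imaging_params(frame_width = 128, frame_height = 128, noise_sd = 0)
  sw <- swimmer_params(n_cells = 1, mean_speed = 1, speed_sd = 0,
                       tumble_rate = 0, rot_diffusion = 0, duration = 0.1,
                       seed = 2)
  tr <- simulate_tracks(sw, im0)
  fr <- render_video(tr, im0)
  img <- fr[, , 1] - im0$background_level
  xs <- matrix(0:127, 128, 128, byrow = TRUE)
  ys <- matrix(0:127, 128, 128)
  cx <- sum(img * xs) / sum(img)
  cy <- sum(img * ys) / sum(img)
  expect_lt(abs(cx - tr$tracks$x_um[1] / im0$pixel_size), 0.05)
  expect_lt(abs(cy - tr$tracks$y_um[1] / im0$pixel_size), 0.05)

  # two cells 30 px apart give exactly two local maxima above background
  frame2 <- spot_frame(rbind(c(40, 60), c(70, 60)))
  mx <- rhizotrack:::cpp_local_maxima(frame2 - 1200, 100, 5)
  expect_equal(nrow(mx), 2)
})

test_that("frame stacks round-trip through 16-bit TIFF bit-exactly", {
  sw <- swimmer_params(n_cells = 20, duration = 1, seed = 31)
  tr <- simulate_tracks(sw, im_small)
  fr <- render_video(tr, im_small)
  path <- tempfile(fileext = ".tif")
  write_frame_stack(fr, path, im_small)
  back <- read_frame_stack(path)
  expect_identical(as.integer(back), as.integer(fr))
  expect_equal(attr(back, "meta")$fps, 10)
  expect_equal(attr(back, "meta")$pixel_size_um, 0.2)
  unlink(c(path, paste0(path, ".json")))
})

test_that("halo tables follow the generative curves exactly at zero noise", {
  curves <- data.frame(strain = "wt", carbon_source = "succinate",
                       b = 2, c = 13, d = 42, e = 6)
  tab <- generate_halo_table(curves, noise_sd = 0, replicates = 3, seed = 1)
  expect_equal(nrow(tab), 18)   # 3 replicates x 6 default concentrations
  expect_equal(tab$diameter_mm,
               fourpl(tab$conc_mM, 2, 13, 42, 6), tolerance = 1e-12)
  # degenerate flat curve: constant response everywhere
  flat <- generate_halo_table(data.frame(strain = "f", carbon_source = "g",
                                         b = 2, c = 6, d = 6, e = 8),
                              noise_sd = 0, seed = 1)
  expect_true(all(flat$diameter_mm == 6))
  expect_error(generate_halo_table(curves, noise_sd = -1), "noise_sd")
})

test_that("cytometry generator honours counts, labels and the scatter ordering", {
  g <- generate_cytometry_events(30, 0, seed = 4)
  expect_equal(nrow(g$events), 30)
  expect_true(all(g$truth$label == "bacteria"))
  g2 <- generate_cytometry_events(3000, 2000, seed = 4)
  expect_equal(nrow(g2$events), 5000)
  expect_equal(sum(g2$truth$label == "bacteroid"), 2000)
  expect_error(
    generate_cytometry_events(10, 10, bacteria_mean = c(900, 150, 5000)),
    "forward and side scatter")
})

test_that("well-separated cytometry populations are perfectly recoverable by a midline gate", {
  bm <- c(200, 150, 5000); dm <- c(800, 600, 9000)   # >= 6 SD apart in scatter
  g <- generate_cytometry_events(400, 400, bacteria_mean = bm, bacteroid_mean = dm,
                                 bacteria_cov = default_scatter_cov(50, 40, 1000),
                                 bacteroid_cov = default_scatter_cov(50, 40, 1000),
                                 seed = 8)
  lab <- apply_gates(g$events, midline_gate(bm, dm))
  expect_equal(lab$label, g$truth$label)
})

test_that("nodule images carry exactly the requested number of stained blobs, deterministically", {
  blank <- generate_nodule_image(0, width = 300, height = 200, seed = 2)
  expect_equal(blank$n_nodules, 0)
  expect_equal(nrow(blank$centers), 0)
  img <- generate_nodule_image(25, radius_range = c(8, 14),
                               width = 1200, height = 900, seed = 2)
  expect_equal(img$n_nodules, 25)
  expect_equal(nrow(img$centers), 25)
  d <- as.matrix(dist(img$centers[, c("x_px", "y_px")]))
  expect_gte(min(d[upper.tri(d)]), 1.5 * 14)
  img2 <- generate_nodule_image(25, radius_range = c(8, 14),
                                width = 1200, height = 900, seed = 2)
  expect_identical(img, img2)
  expect_error(generate_nodule_image(50, radius_range = c(20, 30),
                                     width = 100, height = 100, seed = 1),
               "canvas")
})
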