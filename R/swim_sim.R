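#' Generative parameters for run-and-tumble swimmers
#'
#' Parameters of the minimal planar run-and-tumble model used to produce
#' ground-truthed trajectories. Each cell swims at a constant intrinsic speed
#' drawn from a normal distribution (truncated below at 10% of the mean);
#' between tumbles the heading wanders by rotational diffusion; tumbles arrive
#' as a Poisson process and instantaneously redraw the heading.
#'
#' @param n_cells number of cells to simulate.
#' @param mean_speed population mean swimming speed, um/s.
#' @param speed_sd between-cell speed standard deviation, um/s.
#' @param tumble_rate Poisson rate of reorientation events, events/s.
#' @param tumble_angle_spread concentration of the von Mises-style
#'   reorientation-angle distribution around the current heading; 0 means the
#'   new heading is drawn uniformly on the circle.
#' @param rot_diffusion rotational diffusion coefficient during runs, rad^2/s.
#'   The default 0.062 is the classic value measured for swimming bacteria.
#' @param duration observation time, s.
#' @param fov_width,fov_height field of view, um. `NULL` (default) derives
#'   them from the imaging frame dimensions and pixel size at simulation time.
#' @param seed RNG seed; identical seed and parameters give bit-identical
#'   trajectories.
#' @return an object of class `swimmer_params`.
#' @export
swimmer_params <- function(n_cells = 100, mean_speed = 44, speed_sd = 7,
                           tumble_rate = 0.11, tumble_angle_spread = 0,
                           rot_diffusion = 0.062, duration = 30,
                           fov_width = NULL, fov_height = NULL, seed = NULL) {
  check_number(n_cells, "n_cells", lower = 1, integer = TRUE)
  check_number(mean_speed, "mean_speed", lower = 0, strict_lower = TRUE)
  check_number(speed_sd, "speed_sd", lower = 0)
  check_number(tumble_rate, "tumble_rate", lower = 0)
  check_number(tumble_angle_spread, "tumble_angle_spread", lower = 0)
  check_number(rot_diffusion, "rot_diffusion", lower = 0)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  if (!is.null(fov_width)) check_number(fov_width, "fov_width", 0, strict_lower = TRUE)
  if (!is.null(fov_height)) check_number(fov_height, "fov_height", 0, strict_lower = TRUE)
  structure(list(n_cells = as.integer(n_cells), mean_speed = mean_speed,
                 speed_sd = speed_sd, tumble_rate = tumble_rate,
                 tumble_angle_spread = tumble_angle_spread,
                 rot_diffusion = rot_diffusion, duration = duration,
                 fov_width = fov_width, fov_height = fov_height, seed = seed),
            class = "swimmer_params")
}

#' Imaging parameters for rendering frame stacks
#'
#' Describes the virtual camera: frame rate, calibration, sensor size, point
#' spread function and noise. Defaults follow a 1440 x 1080 sensor recording
#' at 10 frames/s; the 0.2 um/pixel calibration is a plausible value for a
#' 40x objective on such a sensor and is always an explicit parameter, never
#' assumed downstream.
#'
#' @param fps frame rate, frames/s.
#' @param pixel_size camera calibration, um/pixel.
#' @param frame_width,frame_height sensor size, pixels (>= 16).
#' @param psf_sigma standard deviation of the isotropic Gaussian point spread
#'   function, pixels.
#' @param spot_amplitude peak intensity of one cell above background,
#'   16-bit camera counts.
#' @param background_level constant background intensity, counts.
#' @param noise_sd additive Gaussian read-noise standard deviation, counts.
#' @param seed RNG seed for the rendering noise.
#' @return an object of class `imaging_params`.
#' @export
imaging_params <- function(fps = 10, pixel_size = 0.2, frame_width = 1440,
                           frame_height = 1080, psf_sigma = 1.5,
                           spot_amplitude = 6000, background_level = 1200,
                           noise_sd = 600, seed = NULL) {
  check_number(fps, "fps", 0, strict_lower = TRUE)
  check_number(pixel_size, "pixel_size", 0, strict_lower = TRUE)
  check_number(frame_width, "frame_width", lower = 16, integer = TRUE)
  check_number(frame_height, "frame_height", lower = 16, integer = TRUE)
  check_number(psf_sigma, "psf_sigma", 0, strict_lower = TRUE)
  check_number(spot_amplitude, "spot_amplitude", 0, strict_lower = TRUE)
  check_number(background_level, "background_level", 0)
  check_number(noise_sd, "noise_sd", 0)
  structure(list(fps = fps, pixel_size = pixel_size,
                 frame_width = as.integer(frame_width),
                 frame_height = as.integer(frame_height),
                 psf_sigma = psf_sigma, spot_amplitude = spot_amplitude,
                 background_level = background_level, noise_sd = noise_sd,
                 seed = seed),
            class = "imaging_params")
}

#' Simulate ground-truthed run-and-tumble trajectories
#'
#' Cells start uniformly inside the field of view with uniform headings.
#' Per frame interval `dt = 1/fps` the heading gains a rotational-diffusion
#' increment `N(0, rot_diffusion * dt)`; with probability `1 - exp(-tumble_rate
#' * dt)` a tumble fires first, redrawing the heading (uniformly when
#' `tumble_angle_spread = 0`, otherwise von Mises around the current heading)
#' and recording that frame as a true tumble. A cell whose next position falls
#' outside the field of view has its record truncated at the last in-view
#' frame (absorbing boundary, as for a real camera).
#'
#' @param params a [swimmer_params()] object.
#' @param imaging an [imaging_params()] object; supplies the time step and,
#'   when `params` has no explicit field of view, the spatial extent.
#' @return an object of class `ground_truth_tracks`: a list with
#'   `tracks` (data.frame `cell_id, frame, x_um, y_um`), `true_speeds`
#'   (per-cell intrinsic speed, um/s), `tumble_frames` (per-cell integer
#'   vector of true tumble frames that fall inside the recorded span),
#'   `n_frames`, and the two parameter objects.
#' @export
simulate_tracks <- function(params, imaging = imaging_params()) {
  stopifnot(inherits(params, "swimmer_params"), inherits(imaging, "imaging_params"))
  fov_w <- if (is.null(params$fov_width))
    imaging$frame_width * imaging$pixel_size else params$fov_width
  fov_h <- if (is.null(params$fov_height))
    imaging$frame_height * imaging$pixel_size else params$fov_height
  dt <- 1 / imaging$fps
  n_steps <- max(1L, as.integer(round(params$duration * imaging$fps)))
  n_frames <- n_steps  # frames 0 .. n_frames - 1
  n <- params$n_cells

  with_seed(params$seed, {
    # intrinsic speeds: normal truncated below at 0.1 * mean_speed
    lo <- 0.1 * params$mean_speed
    speeds <- rnorm(n, params$mean_speed, params$speed_sd)
    while (any(bad <- speeds < lo))
      speeds[bad] <- rnorm(sum(bad), params$mean_speed, params$speed_sd)

    x <- matrix(NA_real_, n, n_frames)
    y <- matrix(NA_real_, n, n_frames)
    tumble <- matrix(FALSE, n, n_frames)
    px <- runif(n, 0, fov_w)
    py <- runif(n, 0, fov_h)
    heading <- runif(n, -pi, pi)
    alive <- rep(TRUE, n)
    x[, 1] <- px
    y[, 1] <- py
    p_tumble <- 1 - exp(-params$tumble_rate * dt)
    step_sd <- sqrt(params$rot_diffusion * dt)

    if (n_frames > 1) for (t in seq_len(n_frames - 1)) {
      idx <- which(alive)
      if (!length(idx)) break
      tum <- rbinom(length(idx), 1L, p_tumble) == 1L
      if (any(tum)) {
        ti <- idx[tum]
        if (params$tumble_angle_spread == 0) {
          heading[ti] <- runif(length(ti), -pi, pi)
        } else {
          heading[ti] <- heading[ti] +
            rvonmises(length(ti), params$tumble_angle_spread)
        }
        tumble[cbind(ti, t)] <- TRUE  # tumble recorded at frame t - 1 (0-based)
      }
      heading[idx] <- heading[idx] + rnorm(length(idx), 0, step_sd)
      nx <- px[idx] + speeds[idx] * dt * cos(heading[idx])
      ny <- py[idx] + speeds[idx] * dt * sin(heading[idx])
      inside <- nx >= 0 & nx <= fov_w & ny >= 0 & ny <= fov_h
      gone <- idx[!inside]
      alive[gone] <- FALSE
      keep <- idx[inside]
      if (length(keep)) {
        px[keep] <- nx[inside]
        py[keep] <- ny[inside]
        x[cbind(keep, t + 1L)] <- px[keep]
        y[cbind(keep, t + 1L)] <- py[keep]
      }
    }

    cell_len <- rowSums(!is.na(x))
    tracks <- data.frame(
      cell_id = rep(seq_len(n), cell_len),
      frame = unlist(lapply(cell_len, function(m) seq_len(m) - 1L), use.names = FALSE),
      x_um = as.vector(t(x))[!is.na(as.vector(t(x)))],
      y_um = as.vector(t(y))[!is.na(as.vector(t(y)))]
    )
    # a true tumble counts only if its reorientation step lies inside the record
    tumble_frames <- lapply(seq_len(n), function(i) {
      f <- which(tumble[i, ]) - 1L            # 0-based tumble frames
      f[f < cell_len[i] - 1L]
    })
    structure(list(tracks = tracks, true_speeds = speeds,
                   tumble_frames = tumble_frames, n_frames = n_frames,
                   params = params, imaging = imaging,
                   fov = c(width = fov_w, height = fov_h)),
              class = "ground_truth_tracks")
  })
}

# von Mises sampler (Best & Fisher rejection method); kappa > 0
rvonmises <- function(n, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
        break
      }
    }
  }
  out
}

#' @export
print.ground_truth_tracks <- function(x, ...) {
  cat(sprintf("ground_truth_tracks: %d cells, %d frames, %d recorded points\n",
              x$params$n_cells, x$n_frames, nrow(x$tracks)))
  cat(sprintf("  true tumbles inside records: %d\n",
              sum(lengths(x$tumble_frames))))
  invisible(x)
}

#' Render simulated trajectories as a microscopy frame stack
#'
#' Each frame is `background_level` plus one isotropic Gaussian spot
#' (sd `psf_sigma` px, peak `spot_amplitude`) per in-view cell plus additive
#' Gaussian read noise, quantized to 16-bit camera counts. Positions convert
#' from um to pixels through `pixel_size`; the pixel-centre origin is the
#' top-left pixel, x = column, y = row, 0-based.
#'
#' @param truth a [simulate_tracks()] result.
#' @param imaging an [imaging_params()] object.
#' @param path optional file stem; when given, the stack is written with
#'   [write_frame_stack()] and the path returned invisibly.
#' @return a `frame_height x frame_width x n_frames` integer array of counts
#'   (or the path when `path` is given).
#' @export
render_video <- function(truth, imaging = truth$imaging, path = NULL) {
  stopifnot(inherits(truth, "ground_truth_tracks"),
            inherits(imaging, "imaging_params"))
  tr <- truth$tracks
  if (nrow(tr) && max(tr$frame) >= truth$n_frames)
    stop("tracks reference frames beyond the simulated duration")
  h <- imaging$frame_height; w <- imaging$frame_width
  n_frames <- truth$n_frames
  sig <- imaging$psf_sigma
  rad <- ceiling(4 * sig)
  xs_px <- tr$x_um / imaging$pixel_size
  ys_px <- tr$y_um / imaging$pixel_size
  by_frame <- split(seq_len(nrow(tr)), factor(tr$frame, levels = 0:(n_frames - 1)))

  frames <- with_seed(imaging$seed, {
    arr <- array(0L, dim = c(h, w, n_frames))
    off <- (-rad):rad
    for (f in seq_len(n_frames)) {
      img <- matrix(imaging$background_level, h, w)
      for (q in by_frame[[f]]) {
        cx <- xs_px[q]; cy <- ys_px[q]
        jc <- round(cx); ic <- round(cy)
        js <- (jc + off); is <- (ic + off)
        jin <- js >= 0 & js <= w - 1; iin <- is >= 0 & is <= h - 1
        if (!any(jin) || !any(iin)) next
        gx <- exp(-0.5 * ((js[jin] - cx) / sig)^2)
        gy <- exp(-0.5 * ((is[iin] - cy) / sig)^2)
        patch <- imaging$spot_amplitude * (gy %o% gx)
        ii <- is[iin] + 1L; jj <- js[jin] + 1L
        img[ii, jj] <- img[ii, jj] + patch
      }
      if (imaging$noise_sd > 0)
        img <- img + rnorm(h * w, 0, imaging$noise_sd)
      arr[, , f] <- pmin.int(65535L, pmax.int(0L, as.integer(round(img))))
    }
    arr
  })
  if (!is.null(path)) {
    write_frame_stack(frames, path, imaging)
    return(invisible(path))
  }
  frames
}

#' Write a frame stack as multi-page 16-bit TIFF with JSON sidecar
#'
#' @param frames integer array `h x w x n` of 16-bit counts.
#' @param path output TIFF path; the sidecar metadata
#'   (`fps, pixel_size_um, width, height, seed`) goes to `<path>.json`.
#' @param imaging the [imaging_params()] used to produce the stack.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(frames, path, imaging) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  pages <- lapply(seq_len(dim(frames)[3]), function(f) frames[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(fps = imaging$fps, pixel_size_um = imaging$pixel_size,
               width = dim(frames)[2], height = dim(frames)[1],
               n_frames = dim(frames)[3],
               seed = if (is.null(imaging$seed)) NA else imaging$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path TIFF path.
#' @return integer array `h x w x n` of counts, with the sidecar metadata (if
#'   present) attached as attribute `"meta"`.
#' @export
read_frame_stack <- function(path) {
  if (!file.exists(path)) stop("no such frame stack: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0L, dim = c(h, w, length(pages)))
  for (f in seq_along(pages))
    arr[, , f] <- as.integer(round(pages[[f]] * 65535))
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(arr, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  arr
}

#' Four-parameter log-logistic response curve
#'
#' `fourpl(x) = c + (d - c) / (1 + exp(b * (log(x) - log(e))))`. With the
#' sign convention used throughout, `b > 0` means the response decreases with
#' dose, matching halo diameters shrinking at higher carbon concentrations.
#'
#' @param x dose (concentration, mM); must be > 0.
#' @param b slope. @param c lower asymptote. @param d upper asymptote.
#' @param e inflection dose (mM), > 0.
#' @return response values.
#' @export
fourpl <- function(x, b, c, d, e) {
  stopifnot(all(x > 0), e > 0)
  c + (d - c) / (1 + exp(b * (log(x) - log(e))))
}

#' Built-in generative halo dose-response curves
#'
#' One four-parameter log-logistic curve per strain x carbon source,
#' emulating the qualitative pattern of the swimming-halo assays: wildtype
#' halos shrink ~20% across the glucose range, ~30% on pyruvate and ~70% on
#' succinate; the che1-like mutant forms much smaller halos; the fliG-like
#' mutant is non-motile (flat response at colony size).
#'
#' @return data.frame with columns `strain, carbon_source, b, c, d, e`.
#' @export
default_halo_curves <- function() {
  rbind(
    data.frame(strain = "wildtype", carbon_source = c("glucose", "pyruvate", "succinate"),
               b = 2, c = c(32, 27, 13), d = c(40, 38, 42), e = c(8, 8, 6)),
    data.frame(strain = "che1", carbon_source = c("glucose", "pyruvate", "succinate"),
               b = 2, c = c(15, 14, 6), d = c(15, 15, 16), e = c(8, 8, 6)),
    data.frame(strain = "che2", carbon_source = c("glucose", "pyruvate", "succinate"),
               b = 2, c = c(30, 26, 11), d = c(36, 35, 38), e = c(8, 8, 6)),
    data.frame(strain = "fliG", carbon_source = c("glucose", "pyruvate", "succinate"),
               b = 2, c = 6, d = 6, e = 8)
  )
}

#' Generate a synthetic swimming-halo measurement table
#'
#' Halo diameters are drawn as `fourpl(conc) + N(0, noise_sd)` for each
#' strain x carbon source curve, replicate by replicate.
#'
#' @param curves data.frame with columns `strain, carbon_source, b, c, d, e`
#'   (default [default_halo_curves()]).
#' @param concentrations doses in mM (> 0); default 1-30 mM.
#' @param noise_sd replicate noise, mm (>= 0).
#' @param replicates replicates per concentration.
#' @param seed RNG seed.
#' @param path optional CSV path; the table is also returned.
#' @return data.frame `strain, carbon_source, conc_mM, diameter_mm, replicate`.
#' @export
generate_halo_table <- function(curves = default_halo_curves(),
                                concentrations = c(1, 2, 5, 10, 20, 30),
                                noise_sd = 1.5, replicates = 3, seed = NULL,
                                path = NULL) {
  check_columns(curves, c("strain", "carbon_source", "b", "c", "d", "e"), "curves")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(replicates, "replicates", lower = 1, integer = TRUE)
  out <- with_seed(seed, {
    rows <- lapply(seq_len(nrow(curves)), function(i) {
      cv <- curves[i, ]
      grid <- expand.grid(conc_mM = concentrations,
                          replicate = seq_len(replicates))
      mu <- fourpl(grid$conc_mM, cv$b, cv$c, cv$d, cv$e)
      data.frame(strain = cv$strain, carbon_source = cv$carbon_source,
                 conc_mM = grid$conc_mM,
                 diameter_mm = mu + rnorm(nrow(grid), 0, noise_sd),
                 replicate = grid$replicate)
    })
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' Generate a synthetic flow-cytometry event table
#'
#' Draws two trivariate normal populations in (forward scatter, side scatter,
#' fluorescence): undifferentiated bacteria and bacteroids. Bacteroids must
#' be larger in forward scatter and more granular in side scatter than the
#' bacteria, so their population means must exceed the bacteria means in both
#' scatter channels. Values are clipped at zero (instrument floor).
#'
#' @param n_bacteria,n_bacteroids events per class.
#' @param bacteria_mean,bacteroid_mean length-3 means `(fsc, ssc, fl)`.
#' @param bacteria_cov,bacteroid_cov 3x3 positive-definite covariances.
#' @param seed RNG seed.
#' @param path optional CSV stem: events go to `<path>`, hidden true labels
#'   to the companion `<sub(".csv", "", path)>.truth.csv`.
#' @return list with `events` (data.frame `fsc, ssc, fl`, shuffled) and
#'   `truth` (data.frame `label`, aligned with `events` rows).
#' @export
generate_cytometry_events <- function(n_bacteria, n_bacteroids,
                                      bacteria_mean = c(200, 150, 5000),
                                      bacteroid_mean = c(800, 600, 9000),
                                      bacteria_cov = default_scatter_cov(60, 50, 1500),
                                      bacteroid_cov = default_scatter_cov(150, 120, 2500),
                                      seed = NULL, path = NULL) {
  check_number(n_bacteria, "n_bacteria", lower = 0, integer = TRUE)
  check_number(n_bacteroids, "n_bacteroids", lower = 0, integer = TRUE)
  stopifnot(length(bacteria_mean) == 3, length(bacteroid_mean) == 3)
  if (!(bacteroid_mean[1] > bacteria_mean[1] && bacteroid_mean[2] > bacteria_mean[2]))
    stop("bacteroid population mean must exceed the bacteria mean in both ",
         "forward and side scatter (bacteroids are larger and more granular)")
  for (cv in list(bacteria_cov, bacteroid_cov))
    if (any(eigen(cv, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("covariance matrices must be positive-definite")
  out <- with_seed(seed, {
    draw <- function(n, mu, sigma) {
      if (n == 0) return(matrix(numeric(0), 0, 3))
      z <- matrix(rnorm(n * 3), n, 3) %*% chol(sigma)
      pmax(sweep(z, 2, mu, "+"), 0)
    }
    a <- draw(n_bacteria, bacteria_mean, bacteria_cov)
    b <- draw(n_bacteroids, bacteroid_mean, bacteroid_cov)
    ev <- rbind(a, b)
    lab <- c(rep("bacteria", n_bacteria), rep("bacteroid", n_bacteroids))
    ord <- sample.int(nrow(ev))
    list(events = data.frame(fsc = ev[ord, 1], ssc = ev[ord, 2], fl = ev[ord, 3]),
         truth = data.frame(label = lab[ord]))
  })
  if (!is.null(path)) {
    write.csv(out$events, path, row.names = FALSE)
    write.csv(out$truth, paste0(sub("\\.csv$", "", path), ".truth.csv"),
              row.names = FALSE)
  }
  out
}

#' Default scatter/fluorescence covariance with mild FSC-SSC correlation
#' @param fsc_sd,ssc_sd,fl_sd per-channel standard deviations.
#' @param rho FSC-SSC correlation (default 0.5).
#' @return 3x3 covariance matrix.
#' @export
default_scatter_cov <- function(fsc_sd, ssc_sd, fl_sd, rho = 0.5) {
  m <- diag(c(fsc_sd, ssc_sd, fl_sd)^2)
  m[1, 2] <- m[2, 1] <- rho * fsc_sd * ssc_sd
  m
}

#' Generate a synthetic stained-root nodule image
#'
#' Produces a root-coloured textured background bearing `n_nodules` compact
#' stained ellipses (blue-green X-gal-like or magenta GlcA-like). Blob
#' centres are at least `1.5 * max(radius_range)` apart and blobs lie fully
#' inside the canvas, so the true count equals `n_nodules`.
#'
#' @param n_nodules number of stained nodules (>= 0).
#' @param radius_range blob semi-major axis range, pixels.
#' @param stain `"xgal"` (blue-green) or `"magenta"`.
#' @param width,height canvas size, pixels.
#' @param seed RNG seed.
#' @param max_tries placement attempts per nodule before giving up.
#' @param path optional PNG path; a `<path>.truth.csv` companion records the
#'   true count.
#' @return list with `image` (`height x width x 3` array in [0, 1]),
#'   `n_nodules`, and `centers` (data.frame `x_px, y_px, radius_px`).
#' @export
generate_nodule_image <- function(n_nodules, radius_range = c(8, 14),
                                  stain = c("xgal", "magenta"),
                                  width = 1200, height = 900, seed = NULL,
                                  max_tries = 200, path = NULL) {
  stain <- match.arg(stain)
  check_number(n_nodules, "n_nodules", lower = 0, integer = TRUE)
  stopifnot(length(radius_range) == 2, all(radius_range > 0),
            radius_range[1] <= radius_range[2])
  rmax <- radius_range[2]
  min_sep <- 1.5 * rmax
  out <- with_seed(seed, {
    # textured root-coloured background
    base <- c(0.82, 0.73, 0.60)
    yy <- matrix(seq_len(height), height, width)
    xx <- matrix(seq_len(width), height, width, byrow = TRUE)
    mottle <- 0.03 * sin(xx / 37) * cos(yy / 53) + 0.02 * sin((xx + yy) / 71)
    img <- array(0, dim = c(height, width, 3))
    for (ch in 1:3)
      img[, , ch] <- pmin(1, pmax(0, base[ch] + mottle +
                                    rnorm(height * width, 0, 0.015)))
    # place blob centres with rejection sampling
    cx <- cy <- rr <- numeric(0)
    for (k in seq_len(n_nodules)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        r <- runif(1, radius_range[1], radius_range[2])
        px <- runif(1, rmax + 1, width - rmax - 1)
        py <- runif(1, rmax + 1, height - rmax - 1)
        if (!length(cx) || all((cx - px)^2 + (cy - py)^2 >= min_sep^2)) {
          cx <- c(cx, px); cy <- c(cy, py); rr <- c(rr, r)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ", n_nodules, " nodules with centre separation >= ",
             min_sep, " px on a ", width, "x", height,
             " canvas; enlarge the canvas or reduce n_nodules")
    }
    col0 <- if (stain == "xgal") c(0.08, 0.42, 0.48) else c(0.72, 0.12, 0.42)
    for (k in seq_along(cx)) {
      a <- rr[k]
      b <- rr[k] * runif(1, 0.7, 1)
      th <- runif(1, 0, pi)
      jit <- runif(3, -0.04, 0.04)
      i0 <- max(1, floor(cy[k] - a)); i1 <- min(height, ceiling(cy[k] + a))
      j0 <- max(1, floor(cx[k] - a)); j1 <- min(width, ceiling(cx[k] + a))
      ii <- matrix(i0:i1, i1 - i0 + 1, j1 - j0 + 1)
      jj <- matrix(j0:j1, i1 - i0 + 1, j1 - j0 + 1, byrow = TRUE)
      dx <- jj - cx[k]; dy <- ii - cy[k]
      u <- (dx * cos(th) + dy * sin(th)) / a
      v <- (-dx * sin(th) + dy * cos(th)) / b
      inside <- u^2 + v^2 <= 1
      for (ch in 1:3) {
        sub <- img[i0:i1, j0:j1, ch]
        sub[inside] <- pmin(1, pmax(0, col0[ch] + jit[ch]))
        img[i0:i1, j0:j1, ch] <- sub
      }
    }
    list(image = img, n_nodules = n_nodules,
         centers = data.frame(x_px = cx, y_px = cy, radius_px = rr))
  })
  if (!is.null(path)) {
    png::writePNG(out$image, path)
    write.csv(data.frame(image = basename(path), n_nodules = out$n_nodules),
              paste0(sub("\\.png$", "", path), ".truth.csv"), row.names = FALSE)
  }
  out
}
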