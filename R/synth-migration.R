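#' Configuration for synthetic migration movies
#'
#' Describes a time-lapse nuclei movie of migrating cells with a
#' stimulation-induced speed change: cells move as persistent random walks
#' at `speed_pre_um_min` up to frame `pre_stim_frames` and at
#' `speed_post_um_min` afterwards, emulating growth-factor stimulation part
#' way through acquisition (frames every 10-14 minutes).
#'
#' @param n_cells Number of cells.
#' @param n_frames Total frames (> `pre_stim_frames`).
#' @param frame_interval_min Minutes between frames (default 10).
#' @param pre_stim_frames Number of frames before stimulation.
#' @param speed_pre_um_min,speed_post_um_min Cell speeds (um/min, >= 0).
#' @param position_noise_um Gaussian jitter added to rendered positions.
#' @param image_size_px Image height/width in pixels.
#' @param pixel_size_um Pixel size (default 0.64, a binned 20x camera).
#' @param seed Integer seed.
#' @return A list of class `migration_sim_config`.
#' @export
migration_sim_config <- function(n_cells = 30L,
                                 n_frames = 30L,
                                 frame_interval_min = 10,
                                 pre_stim_frames = 10L,
                                 speed_pre_um_min = 0.1,
                                 speed_post_um_min = 0.5,
                                 position_noise_um = 0.1,
                                 image_size_px = c(360L, 360L),
                                 pixel_size_um = 0.64,
                                 seed = 1L) {
  if (n_frames <= pre_stim_frames) {
    abort("`n_frames` must exceed `pre_stim_frames`.",
          class = "fadyn_config_error")
  }
  if (speed_pre_um_min < 0 || speed_post_um_min < 0) {
    abort("speeds must be >= 0.", class = "fadyn_config_error")
  }
  assert_positive(frame_interval_min, "frame_interval_min")
  structure(list(n_cells = as.integer(n_cells),
                 n_frames = as.integer(n_frames),
                 frame_interval_min = frame_interval_min,
                 pre_stim_frames = as.integer(pre_stim_frames),
                 speed_pre_um_min = speed_pre_um_min,
                 speed_post_um_min = speed_post_um_min,
                 position_noise_um = position_noise_um,
                 image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um,
                 seed = as.integer(seed)),
            class = "migration_sim_config")
}

#' Generate a synthetic nuclei time-lapse movie with ground-truth tracks
#'
#' Cells perform persistent random walks (small turning-angle diffusion) at
#' the configured pre- and post-stimulation speeds; nuclei are rendered as
#' Gaussian blobs. Paths are reflected at a margin inside the field so cells
#' never leave the image. True per-cell positions and phase speeds are
#' returned alongside the movie.
#'
#' @param config A [migration_sim_config()].
#' @param snr Rendering signal-to-noise ratio.
#' @param render If `FALSE`, only ground truth is generated.
#' @return List with `frames` (list of matrices, or `NULL`), `truth`
#'   (tibble: `cell`, `frame`, `x_um`, `y_um`, `phase`), and `speeds`
#'   (tibble: `cell`, `phase`, `true_speed_um_min`).
#' @export
generate_migration_movie <- function(config, snr = 15, render = TRUE) {
  stopifnot(inherits(config, "migration_sim_config"))
  withr::local_seed(config$seed)
  nr <- config$image_size_px[1]
  nc <- config$image_size_px[2]
  ps <- config$pixel_size_um
  n <- config$n_cells
  nucleus_sigma_um <- 4.5
  margin_um <- 4 * nucleus_sigma_um
  w_um <- nc * ps
  h_um <- nr * ps
  # packing check: each cell needs ~a nucleus-sized patch of free area
  if (n * (2 * nucleus_sigma_um)^2 * 4 >
        (w_um - 2 * margin_um) * (h_um - 2 * margin_um)) {
    abort("too many cells for the field: initial positions exceed packing.",
          class = "fadyn_config_error")
  }

  x <- numeric(n)
  y <- numeric(n)
  for (k in seq_len(n)) {
    for (try in 1:200) {
      xx <- runif(1, margin_um, w_um - margin_um)
      yy <- runif(1, margin_um, h_um - margin_um)
      prev <- seq_len(k - 1)
      if (k == 1L || all(sqrt((x[prev] - xx)^2 + (y[prev] - yy)^2) >
                           4 * nucleus_sigma_um)) break
    }
    x[k] <- xx
    y[k] <- yy
  }
  heading <- runif(n, 0, 2 * pi)
  dt <- config$frame_interval_min

  truth <- vector("list", config$n_frames)
  frames <- if (render) vector("list", config$n_frames) else NULL
  for (f in seq_len(config$n_frames)) {
    phase <- if (f <= config$pre_stim_frames) "pre" else "post"
    if (f > 1) {
      sp <- if (phase == "pre") config$speed_pre_um_min
            else config$speed_post_um_min
      heading <- heading + rnorm(n, 0, 0.45)
      x <- x + sp * dt * cos(heading)
      y <- y + sp * dt * sin(heading)
      # reflect at margins (cells stay in the field)
      over_x <- x < margin_um | x > w_um - margin_um
      over_y <- y < margin_um | y > h_um - margin_um
      x <- pmin(pmax(x, margin_um), w_um - margin_um)
      y <- pmin(pmax(y, margin_um), h_um - margin_um)
      heading[over_x] <- pi - heading[over_x]
      heading[over_y] <- -heading[over_y]
      # nuclei exclude each other: push apart pairs closer than contact
      contact <- 3.4 * nucleus_sigma_um
      if (n > 1) {
        for (it in 1:3) {
          dxm <- outer(x, x, "-")
          dym <- outer(y, y, "-")
          dm <- sqrt(dxm^2 + dym^2)
          close_ij <- which(upper.tri(dm) & dm < contact, arr.ind = TRUE)
          if (!nrow(close_ij)) break
          for (r in seq_len(nrow(close_ij))) {
            i <- close_ij[r, 1]; j <- close_ij[r, 2]
            dd <- max(dm[i, j], 1e-6)
            push <- (contact - dd) / 2
            ux <- (x[i] - x[j]) / dd
            uy <- (y[i] - y[j]) / dd
            x[i] <- x[i] + push * ux; y[i] <- y[i] + push * uy
            x[j] <- x[j] - push * ux; y[j] <- y[j] - push * uy
            # colliding cells turn away so pairs do not keep shoving
            heading[i] <- atan2(uy, ux) + rnorm(1, 0, 0.2)
            heading[j] <- atan2(-uy, -ux) + rnorm(1, 0, 0.2)
          }
        }
        x <- pmin(pmax(x, margin_um), w_um - margin_um)
        y <- pmin(pmax(y, margin_um), h_um - margin_um)
      }
    }
    truth[[f]] <- tibble(cell = seq_len(n), frame = f,
                         x_um = x, y_um = y, phase = phase)
    if (render) {
      xr <- x + rnorm(n, 0, config$position_noise_um)
      yr <- y + rnorm(n, 0, config$position_noise_um)
      clean <- render_spots_gauss(nr, nc, um_to_px(yr, ps), um_to_px(xr, ps),
                                  rep(1, n),
                                  rep(nucleus_sigma_um / ps, n),
                                  rep(nucleus_sigma_um / ps, n),
                                  rep(0, n))
      frames[[f]] <- add_camera_noise(clean, snr)
    }
  }
  truth <- bind_rows(truth)
  speeds <- truth |>
    group_by(.data$cell, .data$phase) |>
    arrange(.data$frame, .by_group = TRUE) |>
    summarise(true_speed_um_min = if (n() < 2) NA_real_ else
      mean(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)) / dt,
      .groups = "drop")
  list(frames = frames, truth = truth, speeds = speeds)
}
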