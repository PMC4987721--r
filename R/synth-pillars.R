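#' Configuration for synthetic micropillar-array movies
#'
#' Describes a movie of fluorescent pillar tops arranged in a hexagonal
#' lattice (default 4 um centre-to-centre pitch) plus an actin channel
#' carrying the cell footprint. Pillars under the cell deflect following a
#' 2-D Ornstein-Uhlenbeck (OU) process — stationary, exponentially
#' autocorrelated, the structure the force half-time analysis assumes —
#' while free pillars stay at their lattice positions.
#'
#' @param grid_pitch_um Lattice pitch (um, > 0; default 4).
#' @param grid_rotation_deg Lattice rotation in degrees.
#' @param n_pillars Approximate number of pillars (lattice is trimmed to
#'   this count).
#' @param n_frames Number of frames (default 80, i.e. 400 min at 5-min
#'   intervals).
#' @param frame_interval_min Minutes between frames (default 5).
#' @param ou_sd_um Stationary standard deviation of each OU deflection
#'   component (um).
#' @param ou_tau_min OU correlation time (min, > 0).
#' @param detection_noise_um Gaussian localization noise added to emitted
#'   detections (um).
#' @param miss_rate Probability that a pillar-frame detection is dropped.
#' @param cell_footprint List with `center_um` (length-2, or `NULL` for the
#'   lattice centroid) and `radius_um`; pillars inside it are cell-coupled.
#' @param pillar_diameter_um Pillar-top diameter for rendering (default 2).
#' @param pixel_size_um Rendering pixel size (default 0.2).
#' @param seed Integer seed.
#' @return A list of class `pillar_sim_config`.
#' @export
pillar_sim_config <- function(grid_pitch_um = 4,
                              grid_rotation_deg = 0,
                              n_pillars = 400L,
                              n_frames = 80L,
                              frame_interval_min = 5,
                              ou_sd_um = 0.3,
                              ou_tau_min = 30,
                              detection_noise_um = 0.05,
                              miss_rate = 0.02,
                              cell_footprint = list(center_um = NULL,
                                                    radius_um = 20),
                              pillar_diameter_um = 2,
                              pixel_size_um = 0.2,
                              seed = 1L) {
  assert_positive(grid_pitch_um, "grid_pitch_um")
  assert_positive(ou_tau_min, "ou_tau_min")
  if (miss_rate < 0 || miss_rate >= 1) {
    abort("`miss_rate` must be in [0, 1).", class = "fadyn_config_error")
  }
  if (ou_sd_um < 0 || detection_noise_um < 0) {
    abort("noise amplitudes must be >= 0.", class = "fadyn_config_error")
  }
  structure(list(grid_pitch_um = grid_pitch_um,
                 grid_rotation_deg = grid_rotation_deg,
                 n_pillars = as.integer(n_pillars),
                 n_frames = as.integer(n_frames),
                 frame_interval_min = frame_interval_min,
                 ou_sd_um = ou_sd_um,
                 ou_tau_min = ou_tau_min,
                 detection_noise_um = detection_noise_um,
                 miss_rate = miss_rate,
                 cell_footprint = cell_footprint,
                 pillar_diameter_um = pillar_diameter_um,
                 pixel_size_um = pixel_size_um,
                 seed = as.integer(seed)),
            class = "pillar_sim_config")
}

# Hexagonal lattice positions (row-major, trimmed to n), un-rotated, with
# integer lattice indices under basis a1 = (pitch, 0),
# a2 = pitch * (cos 60, sin 60).
hex_lattice <- function(n, pitch) {
  ncols <- ceiling(sqrt(n / (sqrt(3) / 2)))
  nrows <- ceiling(n / ncols)
  ij <- tidyr::expand_grid(j = seq_len(nrows) - 1L, i = seq_len(ncols) - 1L)
  ij <- ij[seq_len(min(n, nrow(ij))), ]
  tibble(i = ij$i, j = ij$j,
         x = pitch * (ij$i + ij$j / 2),
         y = pitch * ij$j * sqrt(3) / 2)
}

# Exact OU update over one time step.
ou_step <- function(x, dt, tau, sd) {
  a <- exp(-dt / tau)
  x * a + sd * sqrt(1 - a^2) * rnorm(length(x))
}

#' Render one pillar-top image
#'
#' Pillar tops are drawn as soft-edged discs (a hard disc convolved with a
#' Gaussian point-spread function), then Poisson shot noise and Gaussian
#' read noise are applied. Positions are physical micrometres; the pixel
#' grid uses the pixel-centre convention.
#'
#' @param x_um,y_um Pillar-top positions (um).
#' @param image_size_px Image height/width (pixels).
#' @param pixel_size_um Pixel size (um, default 0.2).
#' @param diameter_um Disc diameter (um, default 2).
#' @param psf_sigma_um Gaussian PSF width (um, default 0.3).
#' @param snr Signal-to-noise ratio (set `Inf` for a noise-free frame).
#' @return Numeric matrix.
#' @export
render_pillar_frame <- function(x_um, y_um, image_size_px,
                                pixel_size_um = 0.2, diameter_um = 2,
                                psf_sigma_um = 0.3, snr = 20) {
  clean <- render_spots_disc(image_size_px[1], image_size_px[2],
                             um_to_px(y_um, pixel_size_um),
                             um_to_px(x_um, pixel_size_um),
                             rep(1, length(x_um)),
                             radius_px = diameter_um / 2 / pixel_size_um,
                             blur_px = psf_sigma_um / pixel_size_um)
  if (is.finite(snr)) add_camera_noise(clean, snr) else clean
}

#' Generate a synthetic micropillar movie with ground truth
#'
#' Builds the hexagonal lattice, simulates OU deflections for cell-coupled
#' pillars, and emits (a) a detection table with localization noise and
#' dropped detections at `miss_rate`, (b) full ground truth (per-pillar base
#' positions, per-frame true deflections, miss schedule), and optionally
#' (c) rendered pillar-top and actin movies.
#'
#' @param config A [pillar_sim_config()].
#' @param snr Rendering signal-to-noise ratio.
#' @param render If `TRUE`, rendered movies are included.
#' @return List with `pillars` (tibble: `pillar`, `i`, `j`, `base_x_um`,
#'   `base_y_um`, `inside_cell`), `truth` (tibble: `pillar`, `frame`,
#'   `dx_um`, `dy_um`, `missed`), `detections` (tibble: `frame`, `x_um`,
#'   `y_um`), `footprint` (list `center_um`, `radius_um`),
#'   `image_size_px`, and `frames`/`actin` (lists of matrices or `NULL`).
#' @export
generate_pillar_movie <- function(config, snr = 20, render = FALSE) {
  stopifnot(inherits(config, "pillar_sim_config"))
  withr::local_seed(config$seed)
  ps <- config$pixel_size_um
  lat <- hex_lattice(config$n_pillars, config$grid_pitch_um)
  th <- config$grid_rotation_deg * pi / 180
  cx <- mean(lat$x); cy <- mean(lat$y)
  x0 <- cx + cos(th) * (lat$x - cx) - sin(th) * (lat$y - cy)
  y0 <- cy + sin(th) * (lat$x - cx) + cos(th) * (lat$y - cy)
  margin <- 4
  x0 <- x0 - min(x0) + margin
  y0 <- y0 - min(y0) + margin
  field_w <- max(x0) + margin
  field_h <- max(y0) + margin
  image_size_px <- c(ceiling(field_h / ps), ceiling(field_w / ps))

  fp <- config$cell_footprint
  if (is.null(fp$center_um)) fp$center_um <- c(mean(x0), mean(y0))
  if (fp$center_um[1] - fp$radius_um < 0 ||
      fp$center_um[2] - fp$radius_um < 0 ||
      fp$center_um[1] + fp$radius_um > field_w ||
      fp$center_um[2] + fp$radius_um > field_h) {
    abort("cell footprint extends outside the field.",
          class = "fadyn_config_error")
  }
  n <- nrow(lat)
  inside <- sqrt((x0 - fp$center_um[1])^2 + (y0 - fp$center_um[2])^2) <=
    fp$radius_um
  pillars <- tibble(pillar = seq_len(n), i = lat$i, j = lat$j,
                    base_x_um = x0, base_y_um = y0, inside_cell = inside)

  nf <- config$n_frames
  dx <- matrix(0, nf, n)
  dy <- matrix(0, nf, n)
  if (config$ou_sd_um > 0 && any(inside)) {
    idx <- which(inside)
    dx[1, idx] <- rnorm(length(idx), 0, config$ou_sd_um)
    dy[1, idx] <- rnorm(length(idx), 0, config$ou_sd_um)
    for (f in seq_len(nf)[-1]) {
      dx[f, idx] <- ou_step(dx[f - 1, idx], config$frame_interval_min,
                            config$ou_tau_min, config$ou_sd_um)
      dy[f, idx] <- ou_step(dy[f - 1, idx], config$frame_interval_min,
                            config$ou_tau_min, config$ou_sd_um)
    }
  }
  missed <- matrix(runif(nf * n) < config$miss_rate, nf, n)
  noise_x <- matrix(rnorm(nf * n, 0, config$detection_noise_um), nf, n)
  noise_y <- matrix(rnorm(nf * n, 0, config$detection_noise_um), nf, n)

  truth <- tibble(pillar = rep(seq_len(n), each = nf),
                  frame = rep(seq_len(nf), n),
                  dx_um = as.vector(dx), dy_um = as.vector(dy),
                  missed = as.vector(missed))
  det <- truth |>
    filter(!.data$missed) |>
    mutate(x_um = pillars$base_x_um[.data$pillar] + .data$dx_um +
             noise_x[cbind(.data$frame, .data$pillar)],
           y_um = pillars$base_y_um[.data$pillar] + .data$dy_um +
             noise_y[cbind(.data$frame, .data$pillar)]) |>
    select("frame", "pillar", "x_um", "y_um") |>
    arrange(.data$frame, .data$pillar)

  frames <- actin <- NULL
  if (render) {
    frames <- vector("list", nf)
    actin <- vector("list", nf)
    for (f in seq_len(nf)) {
      frames[[f]] <- render_pillar_frame(
        x0 + dx[f, ], y0 + dy[f, ], image_size_px,
        pixel_size_um = ps, diameter_um = config$pillar_diameter_um,
        snr = snr)
      cell_clean <- render_spots_disc(
        image_size_px[1], image_size_px[2],
        um_to_px(fp$center_um[2], ps), um_to_px(fp$center_um[1], ps),
        1, radius_px = fp$radius_um / ps, blur_px = 1 / ps)
      actin[[f]] <- add_camera_noise(cell_clean, snr)
    }
  }
  list(pillars = pillars, truth = truth, detections = det,
       footprint = fp, image_size_px = image_size_px,
       frame_interval_min = config$frame_interval_min,
       frames = frames, actin = actin)
}
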