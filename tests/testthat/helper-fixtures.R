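# Shared fixtures built in code at test time.

# Simulated per-pillar force-magnitude tracks from a 2-D OU deflection
# process: the independent route to force series that bypasses imaging.
sim_force_tracks <- function(n_pillars, n_frames, tau_min, sd_um = 0.3,
                             k = 65.8, dt_min = 5) {
  a <- exp(-dt_min / tau_min)
  out <- vector("list", n_pillars)
  for (p in seq_len(n_pillars)) {
    x <- numeric(n_frames)
    y <- numeric(n_frames)
    x[1] <- rnorm(1, 0, sd_um)
    y[1] <- rnorm(1, 0, sd_um)
    for (i in 2:n_frames) {
      x[i] <- x[i - 1] * a + sd_um * sqrt(1 - a^2) * rnorm(1)
      y[i] <- y[i - 1] * a + sd_um * sqrt(1 - a^2) * rnorm(1)
    }
    out[[p]] <- tibble::tibble(track = p, frame = seq_len(n_frames),
                               force_nN = k * sqrt(x^2 + y^2))
  }
  dplyr::bind_rows(out)
}

# Brute-force two-sample KS: evaluate both ECDFs at every pooled sample
# point and take the maximal absolute difference (plus its sign).
brute_force_ks <- function(test, ref) {
  pts <- sort(unique(c(test, ref)))
  ft <- vapply(pts, function(t) mean(test <= t), numeric(1))
  fr <- vapply(pts, function(t) mean(ref <= t), numeric(1))
  k <- which.max(abs(fr - ft))
  list(d = abs(fr - ft)[k], signed_d = (fr - ft)[k])
}

# Run the pillar analysis chain on a generated movie (detection-table
# route): track, fit grid on free pillars, convert to forces, select.
run_pillar_chain <- function(mv, k = 65.8, fraction = 1) {
  fp <- mv$footprint
  f1 <- dplyr::filter(mv$detections, frame == min(frame))
  excl <- sqrt((f1$x_um - fp$center_um[1])^2 +
                 (f1$y_um - fp$center_um[2])^2) <= fp$radius_um
  grid <- fit_reference_grid(f1, pitch_um = 4, exclude = excl)
  tracks <- compute_deflections(track_pillars(mv$detections), grid, k)
  in_cell <- sqrt((tracks$x_um - fp$center_um[1])^2 +
                    (tracks$y_um - fp$center_um[2])^2) <= fp$radius_um
  sel <- select_top_deflected(tracks, in_cell, fraction = fraction)
  list(grid = grid, tracks = tracks, selection = sel,
       selected_tracks = dplyr::filter(
         tracks, track %in% sel$track[sel$selected]))
}

# Ellipse pixel mask (axes in pixels) for moment-based feature tests.
ellipse_mask <- function(nr, nc, cy, cx, a, b, theta = 0) {
  yy <- matrix(seq_len(nr), nr, nc)
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  u <- cos(theta) * (xx - cx) + sin(theta) * (yy - cy)
  v <- -sin(theta) * (xx - cx) + cos(theta) * (yy - cy)
  (u / a)^2 + (v / b)^2 <= 1
}
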