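#' Micropillar array specification
#'
#' Geometry and mechanics of the elastomeric micropillar array. The printed
#' bending stiffness (65.8 nN/um for 4.1 um tall, 2 um wide pillars) is
#' taken as the force-conversion constant; the effective Young's modulus of
#' the array follows from the stiffness and pillar radius through the
#' sphere-indentation equivalence `E_eff = 9 k / (4 pi r)`.
#'
#' @param height_um Pillar height (default 4.1).
#' @param diameter_um Pillar diameter (default 2.0).
#' @param pitch_um Centre-to-centre lattice pitch (default 4.0).
#' @param bending_stiffness_nN_um Tip bending stiffness (default 65.8).
#' @param material_young_MPa Optional bulk elastomer modulus; when given,
#'   the stiffness is recomputed from it via [pillar_stiffness()].
#' @return A list of class `pillar_spec` with the derived
#'   `effective_young_kPa` attached.
#' @export
pillar_spec <- function(height_um = 4.1, diameter_um = 2.0, pitch_um = 4.0,
                        bending_stiffness_nN_um = 65.8,
                        material_young_MPa = NULL) {
  assert_positive(height_um, "height_um")
  assert_positive(diameter_um, "diameter_um")
  assert_positive(pitch_um, "pitch_um")
  if (!is.null(material_young_MPa)) {
    bending_stiffness_nN_um <- pillar_stiffness(height_um, diameter_um,
                                                material_young_MPa)
  }
  assert_positive(bending_stiffness_nN_um, "bending_stiffness_nN_um")
  structure(list(height_um = height_um, diameter_um = diameter_um,
                 pitch_um = pitch_um,
                 bending_stiffness_nN_um = bending_stiffness_nN_um,
                 effective_young_kPa = effective_young_modulus(
                   bending_stiffness_nN_um, diameter_um / 2),
                 material_young_MPa = material_young_MPa),
            class = "pillar_spec")
}

#' Euler-Bernoulli bending stiffness of a cylindrical pillar
#'
#' `k = 3 pi E r^4 / (4 h^3)` for a cylindrical cantilever loaded at the
#' tip (no shear or substrate-warping correction).
#'
#' @param height_um Pillar height (um).
#' @param diameter_um Pillar diameter (um).
#' @param material_young_MPa Elastomer Young's modulus (MPa).
#' @return Bending stiffness in nN/um.
#' @export
pillar_stiffness <- function(height_um, diameter_um, material_young_MPa) {
  assert_positive(height_um, "height_um")
  assert_positive(diameter_um, "diameter_um")
  assert_positive(material_young_MPa, "material_young_MPa")
  r <- diameter_um / 2
  # E in MPa = uN/um^2; k in uN/um = 1000 nN/um
  3 * pi * material_young_MPa * r^4 / (4 * height_um^3) * 1000
}

#' Effective Young's modulus of a micropillar array
#'
#' Continuum-equivalent substrate rigidity via the sphere-indentation
#' equivalence for micropost arrays: `E_eff = 9 k / (4 pi r)`.
#'
#' @param k Bending stiffness in nN/um (or 0).
#' @param radius_um Pillar radius (um).
#' @return Effective modulus in kPa.
#' @export
effective_young_modulus <- function(k, radius_um) {
  assert_positive(radius_um, "radius_um")
  if (length(k) != 1L || !is.finite(k) || k < 0) {
    abort("`k` must be a single non-negative number.",
          class = "fadyn_config_error")
  }
  # k/r in nN/um^2 = kPa * 1e... 1 nN/um^2 = 1 kPa
  9 * k / (4 * pi * radius_um)
}

#' Detect pillar tops with sub-pixel precision
#'
#' Band-pass filtering (difference of Gaussians), local-maxima detection
#' above a noise-adaptive threshold, then intensity-weighted centroid
#' refinement in a window around each maximum after local background
#' subtraction. Deterministic given the frame.
#'
#' @param frame 2-D numeric matrix (pillar-top channel).
#' @param pixel_size_um Pixel size (default 0.2).
#' @param spot_radius_um Approximate pillar-top radius (default 1).
#' @param threshold Minimum band-passed peak height as a fraction of the
#'   band-passed dynamic range (default 0.3).
#' @return Tibble with `x_um`, `y_um`, `intensity` (one row per pillar;
#'   empty, with a warning, for blank frames).
#' @export
detect_pillars <- function(frame, pixel_size_um = 0.2, spot_radius_um = 1,
                           threshold = 0.3) {
  assert_image2d(frame, "pillar frame")
  r_px <- spot_radius_um / pixel_size_um
  if (diff(range(frame)) <= 0) {
    warn("blank or saturated frame: no pillars detected.")
    return(tibble(x_um = numeric(0), y_um = numeric(0),
                  intensity = numeric(0)))
  }
  bp <- as_matrix_img(EBImage::gblur(frame, sigma = 0.15 * r_px)) -
    as_matrix_img(EBImage::gblur(frame, sigma = 1.5 * r_px))
  dyn <- max(bp)
  if (dyn <= 0) {
    warn("no band-passed signal: no pillars detected.")
    return(tibble(x_um = numeric(0), y_um = numeric(0),
                  intensity = numeric(0)))
  }
  brush <- EBImage::makeBrush(2L * ceiling(0.8 * r_px) + 1L, shape = "disc")
  mx <- as_matrix_img(EBImage::dilate(bp, brush))
  peaks <- which(bp == mx & bp > threshold * dyn)
  if (!length(peaks)) {
    warn("no peaks above threshold: no pillars detected.")
    return(tibble(x_um = numeric(0), y_um = numeric(0),
                  intensity = numeric(0)))
  }
  pr <- (peaks - 1L) %% nrow(frame) + 1L
  pc <- (peaks - 1L) %/% nrow(frame) + 1L
  half <- ceiling(1.4 * r_px)
  out <- matrix(NA_real_, length(peaks), 3)
  for (k in seq_along(peaks)) {
    rr <- max(1L, pr[k] - half):min(nrow(frame), pr[k] + half)
    cc <- max(1L, pc[k] - half):min(ncol(frame), pc[k] + half)
    w <- frame[rr, cc]
    # local background: median of the window border
    border <- c(w[1, ], w[nrow(w), ], w[, 1], w[, ncol(w)])
    w <- pmax(w - median(border), 0)
    tot <- sum(w)
    if (tot <= 0) next
    out[k, 1] <- sum(colSums(w) * cc) / tot
    out[k, 2] <- sum(rowSums(w) * rr) / tot
    out[k, 3] <- tot
  }
  ok <- complete.cases(out)
  tibble(x_um = px_to_um(out[ok, 1], pixel_size_um),
         y_um = px_to_um(out[ok, 2], pixel_size_um),
         intensity = out[ok, 3])
}

#' Fit the reference undeflected hexagonal grid
#'
#' Estimates lattice orientation from nearest-neighbour direction angles
#' folded into the 60-degree sector, assigns every centroid an integer
#' lattice index, and refines origin and basis vectors by trimmed least
#' squares on pillars outside the exclusion region (cell footprint), where
#' pillars are undeflected. Falls back to all pillars, with a warning, when
#' fewer than 10 free centroids are available.
#'
#' @param centroids Tibble with `x_um`, `y_um`.
#' @param pitch_um Nominal lattice pitch.
#' @param exclude Logical vector marking centroids to exclude from the fit
#'   (e.g. inside the cell mask), or `NULL`.
#' @param n_iter Assignment/refit iterations.
#' @return A list of class `pillar_grid`: `origin`, `a1`, `a2` (um),
#'   `residual_rms_um`, `rotation_deg`, `pitch_um`.
#' @export
fit_reference_grid <- function(centroids, pitch_um = 4, exclude = NULL,
                               n_iter = 3L) {
  centroids <- as_tibble(centroids)
  n <- nrow(centroids)
  if (is.null(exclude)) exclude <- rep(FALSE, n)
  free <- which(!exclude)
  if (length(free) < 10L) {
    warn("fewer than 10 free pillars: fitting the grid on all centroids.")
    free <- seq_len(n)
  }
  p <- cbind(centroids$x_um, centroids$y_um)
  pf <- p[free, , drop = FALSE]
  # orientation from nearest-neighbour angles folded into [0, 60) degrees
  d <- as.matrix(stats::dist(pf))
  diag(d) <- Inf
  ang <- c()
  for (i in seq_len(nrow(pf))) {
    nb <- which(d[i, ] > 0.7 * pitch_um & d[i, ] < 1.3 * pitch_um)
    if (!length(nb)) next
    a <- atan2(pf[nb, 2] - pf[i, 2], pf[nb, 1] - pf[i, 1])
    ang <- c(ang, a %% (pi / 3))
  }
  if (!length(ang)) {
    abort("no neighbour pairs near the nominal pitch; cannot fit grid.",
          class = "fadyn_input_error")
  }
  # circular mean on the 60-degree torus
  theta <- atan2(mean(sin(6 * ang)), mean(cos(6 * ang))) / 6
  basis <- function(theta, pitch) {
    a1 <- pitch * c(cos(theta), sin(theta))
    a2 <- pitch * c(cos(theta + pi / 3), sin(theta + pi / 3))
    cbind(a1, a2)
  }
  B <- basis(theta, pitch_um)
  origin <- pf[1, ]
  idx <- NULL
  for (it in seq_len(n_iter)) {
    ij <- t(round(solve(B, t(p) - origin)))
    X <- cbind(1, ij)
    keep_rows <- free
    fit_x <- stats::lm.fit(X[keep_rows, , drop = FALSE], p[keep_rows, 1])
    fit_y <- stats::lm.fit(X[keep_rows, , drop = FALSE], p[keep_rows, 2])
    res <- sqrt((X[keep_rows, ] %*% fit_x$coefficients - p[keep_rows, 1])^2 +
                  (X[keep_rows, ] %*% fit_y$coefficients - p[keep_rows, 2])^2)
    # trim gross outliers (mis-assigned or perturbed pillars)
    good <- res < pmax(0.25 * pitch_um, 3 * median(res))
    if (sum(good) >= 10L) keep_rows <- keep_rows[good]
    fit_x <- stats::lm.fit(X[keep_rows, , drop = FALSE], p[keep_rows, 1])
    fit_y <- stats::lm.fit(X[keep_rows, , drop = FALSE], p[keep_rows, 2])
    origin <- c(fit_x$coefficients[1], fit_y$coefficients[1])
    B <- rbind(fit_x$coefficients[2:3], fit_y$coefficients[2:3])
    idx <- ij
  }
  pred <- t(origin + B %*% t(idx))
  res_free <- sqrt(rowSums((p[free, , drop = FALSE] -
                              pred[free, , drop = FALSE])^2))
  a1 <- B[, 1]
  a2 <- B[, 2]
  structure(list(origin = origin, a1 = a1, a2 = a2,
                 residual_rms_um = sqrt(mean(res_free^2)),
                 rotation_deg = (atan2(a1[2], a1[1]) * 180 / pi) %% 60,
                 pitch_um = mean(c(sqrt(sum(a1^2)), sqrt(sum(a2^2)))),
                 index = idx),
            class = "pillar_grid")
}

#' Predicted lattice positions for integer indices
#'
#' @param grid A [fit_reference_grid()] result.
#' @param ij Two-column matrix of lattice indices.
#' @return Two-column matrix of positions (um).
#' @export
grid_positions <- function(grid, ij) {
  t(grid$origin + cbind(grid$a1, grid$a2) %*% t(ij))
}

#' Deflections and forces from assigned centroids
#'
#' The deflection is the observed centroid minus the lattice-predicted
#' position; the force is `F = k * delta` componentwise. Deflections larger
#' than half the pitch indicate a lattice mis-assignment and are excluded.
#'
#' @param centroids Tibble with `x_um`, `y_um` (and any id columns, kept).
#' @param grid A [fit_reference_grid()] result.
#' @param k Bending stiffness (nN/um).
#' @param ij Optional two-column lattice-index matrix; when `NULL`, indices
#'   are assigned by rounding in the grid basis.
#' @return Input tibble with `dx_um`, `dy_um`, `defl_um`, `fx_nN`, `fy_nN`,
#'   `force_nN` plus lattice indices `i`, `j`; mis-assigned rows dropped.
#' @export
compute_deflections <- function(centroids, grid, k, ij = NULL) {
  assert_positive(k, "k")
  centroids <- as_tibble(centroids)
  p <- cbind(centroids$x_um, centroids$y_um)
  B <- cbind(grid$a1, grid$a2)
  if (is.null(ij)) ij <- t(round(solve(B, t(p) - grid$origin)))
  pred <- grid_positions(grid, ij)
  d <- p - pred
  defl <- sqrt(rowSums(d^2))
  out <- centroids |>
    mutate(i = ij[, 1], j = ij[, 2],
           dx_um = d[, 1], dy_um = d[, 2], defl_um = defl,
           fx_nN = k * d[, 1], fy_nN = k * d[, 2],
           force_nN = k * defl)
  bad <- out$defl_um > grid$pitch_um / 2
  if (any(bad)) {
    warn(sprintf("%d detections beyond pitch/2 flagged as mis-assigned.",
                 sum(bad)))
  }
  out[!bad, ]
}

#' Track pillars across frames with gap closing
#'
#' Nearest-neighbour linking gated at `gate_um` (2 um): detections in each
#' frame are matched to active tracks by ascending displacement (greedy);
#' tracks missing a match stay alive one extra frame, so a pillar lost for
#' a single frame is re-linked two frames apart. Unmatched detections start
#' new tracks.
#'
#' @param detections Tibble with `frame`, `x_um`, `y_um` (>= 2 frames).
#' @param gate_um Maximum linking displacement (default 2).
#' @param max_gap Maximum frame gap bridged (default 2).
#' @return Tibble: input rows plus a `track` id, ordered by track, frame.
#' @export
track_pillars <- function(detections, gate_um = 2, max_gap = 2L) {
  detections <- as_tibble(detections)
  frames <- sort(unique(detections$frame))
  if (length(frames) < 2L) {
    abort("need detections from at least 2 frames.",
          class = "fadyn_input_error")
  }
  det <- detections |> arrange(.data$frame)
  det$track <- NA_integer_
  # active tracks: id, last x, y, last frame
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_f <- integer(0)
  next_id <- 0L
  for (f in frames) {
    rows <- which(det$frame == f)
    alive <- which(f - act_f <= max_gap)
    assigned <- rep(NA_integer_, length(rows))
    if (length(alive) && length(rows)) {
      cost <- outer(seq_along(alive), seq_along(rows),
                    Vectorize(function(i, j) {
                      sqrt((act_x[alive[i]] - det$x_um[rows[j]])^2 +
                             (act_y[alive[i]] - det$y_um[rows[j]])^2)
                    }))
      m <- greedy_match(cost, gate = gate_um)
      for (i in seq_along(alive)) {
        if (!is.na(m[i])) assigned[m[i]] <- alive[i]
      }
    }
    for (j in seq_along(rows)) {
      if (is.na(assigned[j])) {
        next_id <- next_id + 1L
        act_id <- c(act_id, next_id)
        act_x <- c(act_x, det$x_um[rows[j]])
        act_y <- c(act_y, det$y_um[rows[j]])
        act_f <- c(act_f, f)
        det$track[rows[j]] <- next_id
      } else {
        a <- assigned[j]
        det$track[rows[j]] <- act_id[a]
        act_x[a] <- det$x_um[rows[j]]
        act_y[a] <- det$y_um[rows[j]]
        act_f[a] <- f
      }
    }
  }
  arrange(det, .data$track, .data$frame)
}

#' Segment the cell footprint from an actin frame
#'
#' Gaussian low-pass filter, background subtraction, then two edge
#' detectors each followed by dilation and hole filling: a Sobel gradient
#' and a Laplacian-of-Gaussian zero-crossing band. The union is cleaned by
#' erosion and only components above `min_area_px` are kept.
#'
#' @param frame 2-D numeric matrix (actin channel).
#' @param sigma_px Low-pass width (default 4).
#' @param min_area_px Minimum component area kept (default 500).
#' @return Logical mask matrix.
#' @export
segment_cell_mask <- function(frame, sigma_px = 4, min_area_px = 500L) {
  assert_image2d(frame, "actin frame")
  if (diff(range(frame)) <= 0) {
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  sm <- as_matrix_img(EBImage::gblur(frame, sigma = sigma_px))
  sub <- pmax(sm - median(sm), 0)
  dyn <- max(sub)
  if (dyn <= 0) return(matrix(FALSE, nrow(frame), ncol(frame)))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- as_matrix_img(EBImage::filter2(sub, kx))
  gy <- as_matrix_img(EBImage::filter2(sub, t(kx)))
  grad <- sqrt(gx^2 + gy^2)
  edge1 <- grad > 0.5 * max(grad)
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lg <- as_matrix_img(EBImage::filter2(sub, lap))
  # for a bright object the LoG response is negative just inside the edge,
  # so the negative band traces the cell boundary from within
  edge2 <- lg < -0.3 * max(-lg)
  brush <- EBImage::makeBrush(7, shape = "disc")
  m1 <- EBImage::fillHull(EBImage::dilate(edge1, brush))
  m2 <- EBImage::fillHull(EBImage::dilate(edge2, brush))
  mask <- as_matrix_img(m1) > 0 | as_matrix_img(m2) > 0
  mask <- as_matrix_img(EBImage::erode(mask, brush)) > 0
  labels <- as_matrix_img(EBImage::bwlabel(mask))
  keep <- drop_small_labels(labels, min_area_px)
  keep > 0
}

#' Select the top-deflected cell-coupled pillars
#'
#' A pillar counts as cell-coupled when it lies inside the cell mask in at
#' least half of its frames; coupled pillars are ranked by time-averaged
#' deflection magnitude and the top `fraction` (default 5%, at least one
#' pillar) is kept.
#'
#' @param tracks Tibble with `track`, `frame`, `defl_um` and positions.
#' @param in_cell Logical vector over rows of `tracks` (inside cell mask),
#'   or `NULL` to treat all pillars as coupled.
#' @param fraction Fraction of coupled pillars kept (0 < fraction <= 1).
#' @param min_coupled_frac Minimum fraction of frames inside the mask.
#' @return Tibble with `track`, `mean_defl_um`, `selected`; attribute-free.
#' @export
select_top_deflected <- function(tracks, in_cell = NULL, fraction = 0.05,
                                 min_coupled_frac = 0.5) {
  if (fraction <= 0 || fraction > 1) {
    abort("`fraction` must be in (0, 1].", class = "fadyn_config_error")
  }
  tracks <- as_tibble(tracks)
  if (is.null(in_cell)) in_cell <- rep(TRUE, nrow(tracks))
  stats_tbl <- tracks |>
    mutate(.in = in_cell) |>
    group_by(.data$track) |>
    summarise(mean_defl_um = mean(.data$defl_um),
              coupled = mean(.data$.in) >= min_coupled_frac,
              .groups = "drop")
  coupled <- filter(stats_tbl, .data$coupled)
  if (!nrow(coupled)) {
    warn("no cell-coupled pillars; empty selection.")
    return(mutate(stats_tbl, selected = FALSE))
  }
  n_keep <- max(1L, ceiling(fraction * nrow(coupled)))
  sel_ids <- coupled |>
    arrange(dplyr::desc(.data$mean_defl_um)) |>
    head(n_keep) |>
    dplyr::pull(.data$track)
  mutate(stats_tbl, selected = .data$track %in% sel_ids)
}

#' Condition-level force summaries
#'
#' Per-time-point mean force magnitude across selected pillars, per-pillar
#' time-mean forces, and the empirical cumulative distribution of all
#' per-pillar-frame force magnitudes.
#'
#' @param tracks Tibble with `track`, `frame`, `force_nN` (selected tracks).
#' @return A list of class `force_summary`: `timeseries` (tibble `frame`,
#'   `mean_force_nN`, `n`), `per_pillar` (tibble `track`,
#'   `mean_force_nN`), `cdf` (function), `forces` (vector).
#' @export
force_timeseries_summary <- function(tracks) {
  tracks <- as_tibble(tracks)
  if (!nrow(tracks)) {
    abort("need at least one selected track.", class = "fadyn_input_error")
  }
  ts <- tracks |>
    group_by(.data$frame) |>
    summarise(mean_force_nN = mean(.data$force_nN), n = n(),
              .groups = "drop")
  pp <- tracks |>
    group_by(.data$track) |>
    summarise(mean_force_nN = mean(.data$force_nN), .groups = "drop")
  structure(list(timeseries = ts, per_pillar = pp,
                 cdf = ecdf(tracks$force_nN), forces = tracks$force_nN),
            class = "force_summary")
}

# Unbiased (divide-by-(n-k)) sample autocovariance of a mean-subtracted
# series. Returns NULL for zero-variance series.
autocov_unbiased <- function(x, n_lags) {
  x <- x - mean(x)
  if (sum(x^2) <= 0) return(NULL)
  n <- length(x)
  vapply(0:(n_lags - 1L), function(l) {
    sum(x[seq_len(n - l)] * x[(1 + l):n]) / (n - l)
  }, numeric(1))
}

#' Force autocorrelation and exponential half-time
#'
#' Computes the mean-subtracted, lag-unbiased autocovariance of each
#' selected pillar's force-magnitude series, averages the covariance
#' curves across pillars, normalizes the pooled curve to unity at lag 0,
#' and fits `a * exp(-lambda t) + c` over the fit window (default the
#' first 2 h: 25 points at 5-min spacing). Pooling before normalization
#' avoids the ratio bias of per-series normalization on short series, and
#' the constant offset absorbs the downward shift that estimating each
#' series' mean imprints on every lag; the half-time of the decaying
#' component is `ln 2 / lambda`. Zero-variance series are excluded with a
#' warning.
#'
#' @param tracks Tibble with `track`, `frame`, `force_nN`.
#' @param frame_interval_min Minutes between frames (default 5).
#' @param fit_window_min Fit window length in minutes (default 120).
#' @return A list of class `autocorr_fit`: `lags_min`, `mean_autocorr`,
#'   `n_pillars`, `amplitude`, `lambda_per_min`, `halftime_min`, `sse`.
#' @export
force_autocorrelation <- function(tracks, frame_interval_min = 5,
                                  fit_window_min = 120) {
  tracks <- as_tibble(tracks)
  n_lags <- floor(fit_window_min / frame_interval_min) + 1L
  series <- split(tracks$force_nN, tracks$track)
  series <- series[lengths(series) >= n_lags]
  if (!length(series)) {
    abort("no track reaches the fit-window length.",
          class = "fadyn_input_error")
  }
  curves <- lapply(series, autocov_unbiased, n_lags = n_lags)
  dropped <- sum(vapply(curves, is.null, logical(1)))
  if (dropped > 0) {
    warn(sprintf("%d zero-variance series excluded.", dropped))
    curves <- curves[!vapply(curves, is.null, logical(1))]
  }
  if (!length(curves)) {
    abort("all series have zero variance.", class = "fadyn_input_error")
  }
  covs <- do.call(rbind, curves)
  mean_cov <- colMeans(covs)
  mean_ac <- mean_cov / mean_cov[1]
  lags <- (0:(n_lags - 1L)) * frame_interval_min
  fit <- fit_exp_decay(lags, mean_ac)
  structure(list(lags_min = lags, mean_autocorr = mean_ac,
                 n_pillars = length(curves),
                 amplitude = fit$a, lambda_per_min = fit$lambda,
                 offset = fit$c,
                 halftime_min = log(2) / fit$lambda, sse = fit$sse,
                 pillar_covs = covs),
            class = "autocorr_fit")
}

# Least-squares fit of a * exp(-lambda * t) + c. For fixed lambda the
# model is linear in (a, c), so the profile SSE is minimised over lambda
# by 1-D golden-section search: deterministic and convergence-proof. The
# constant offset absorbs the finite-series bias of the mean-subtracted
# autocorrelation estimator (a shared downward shift of every lag), which
# would otherwise inflate the fitted decay rate; the half-time is
# ln(2)/lambda of the decaying component.
fit_exp_decay <- function(t, y) {
  linfit <- function(lambda) {
    X <- cbind(exp(-lambda * t), 1)
    fit <- stats::lm.fit(X, y)
    list(a = fit$coefficients[[1]], c = fit$coefficients[[2]],
         sse = sum(fit$residuals^2))
  }
  prof <- function(lambda) linfit(lambda)$sse
  # bracket the optimum over a wide log-spaced grid, then refine
  grid <- exp(seq(log(1e-4), log(5), length.out = 40))
  sses <- vapply(grid, prof, numeric(1))
  k <- which.min(sses)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(length(grid), k + 1L)]
  opt <- stats::optimize(prof, c(lo, hi), tol = 1e-9)
  best <- linfit(opt$minimum)
  list(a = best$a, lambda = opt$minimum, c = best$c, sse = best$sse)
}

#' @export
print.autocorr_fit <- function(x, ...) {
  cat(sprintf(
    "Force autocorrelation (%d pillars): a = %.3f, lambda = %.4f /min, halftime = %.1f min\n",
    x$n_pillars, x$amplitude, x$lambda_per_min, x$halftime_min))
  invisible(x)
}

#' Compare autocorrelation half-times with an extra-sum-of-squares F-test
#'
#' Fits the exponential decay to both conditions' mean autocorrelation
#' curves jointly (shared amplitude, rate and offset) and separately, and
#' forms the nested-model statistic
#' `F = ((SSE_shared - SSE_sep)/ddf) / (SSE_sep/df_sep)`. Because the lag
#' points of an autocorrelation curve are strongly correlated, the
#' classical F distribution is anticonservative for this statistic; the
#' reported `p` is therefore calibrated by permuting pillars between the
#' two conditions (exchangeable under the null) and recomputing the
#' statistic, while the parametric p-value is kept as `p_parametric`.
#'
#' @param fit1,fit2 [force_autocorrelation()] results.
#' @param n_perm Number of pillar permutations (default 199; set 0 to skip
#'   and report only the parametric p-value).
#' @return A list of class `halftime_ftest`: `f`, `df1`, `df2`, `p`
#'   (permutation), `p_parametric`, `halftime1_min`, `halftime2_min`.
#' @export
compare_halftimes <- function(fit1, fit2, n_perm = 199L) {
  stopifnot(inherits(fit1, "autocorr_fit"), inherits(fit2, "autocorr_fit"))
  t1 <- fit1$lags_min; t2 <- fit2$lags_min
  if (!identical(t1, t2)) {
    abort("fit windows must match.", class = "fadyn_input_error")
  }
  n <- length(t1) + length(t2)
  if (n < 8) abort("insufficient points.", class = "fadyn_input_error")
  fstat <- function(y1, y2) {
    sep1 <- fit_exp_decay(t1, y1)
    sep2 <- fit_exp_decay(t2, y2)
    shared <- fit_exp_decay(c(t1, t2), c(y1, y2))
    sse_sep <- sep1$sse + sep2$sse
    max((shared$sse - sse_sep) / 3 / (sse_sep / (n - 6)), 0)
  }
  f_obs <- fstat(fit1$mean_autocorr, fit2$mean_autocorr)
  p_par <- pf(f_obs, 3, n - 6, lower.tail = FALSE)
  p <- p_par
  if (n_perm > 0) {
    all_covs <- rbind(fit1$pillar_covs, fit2$pillar_covs)
    n1 <- nrow(fit1$pillar_covs)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      pick <- sample.int(nrow(all_covs), n1)
      m1 <- colMeans(all_covs[pick, , drop = FALSE])
      m2 <- colMeans(all_covs[-pick, , drop = FALSE])
      if (fstat(m1 / m1[1], m2 / m2[1]) >= f_obs) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  structure(list(f = f_obs, df1 = 3L, df2 = n - 6L,
                 p = p, p_parametric = p_par, n_perm = n_perm,
                 halftime1_min = fit1$halftime_min,
                 halftime2_min = fit2$halftime_min),
            class = "halftime_ftest")
}

#' @export
print.halftime_ftest <- function(x, ...) {
  cat(sprintf(
    "Extra-sum-of-squares F-test: F(%d, %d) = %.3f, p = %.3g (halftimes %.1f vs %.1f min)\n",
    x$df1, x$df2, x$f, x$p, x$halftime1_min, x$halftime2_min))
  invisible(x)
}

#' Compare per-pillar mean forces between two conditions
#'
#' Welch's unequal-variance t-test (Satterthwaite degrees of freedom).
#'
#' @param forces1,forces2 Numeric vectors of per-pillar mean forces
#'   (each n >= 3).
#' @return The [stats::t.test()] `htest` object.
#' @export
compare_forces <- function(forces1, forces2) {
  if (length(forces1) < 3 || length(forces2) < 3) {
    abort("each group needs >= 3 values.", class = "fadyn_input_error")
  }
  if (sd(forces1) == 0 && sd(forces2) == 0) {
    abort("both groups have zero variance.", class = "fadyn_input_error")
  }
  t.test(forces1, forces2, var.equal = FALSE)
}

#' Closed-form magnitude autocorrelation of a 2-D OU deflection process
#'
#' For a two-component OU process with component correlation
#' `c(t) = exp(-t/tau)`, the correlation of the deflection magnitude
#' (a Rayleigh variable) is
#' `rho(t) = (2F1(-1/2, -1/2; 1; c^2) - 1) / (4/pi - 1)`.
#' Used as the independent oracle for half-time recovery tests.
#'
#' @param t_min Lag times (min).
#' @param tau_min OU correlation time (min).
#' @return Autocorrelation values in `[0, 1]`.
#' @export
ou_magnitude_autocorr <- function(t_min, tau_min) {
  z <- exp(-2 * t_min / tau_min)
  # 2F1(-1/2,-1/2;1;z) by series (converges for z in [0,1])
  f <- vapply(z, function(zz) {
    term <- 1; s <- 1
    for (k in 0:200) {
      term <- term * ((k - 0.5)^2 / (k + 1)^2) * zz
      s <- s + term
      if (abs(term) < 1e-14) break
    }
    s
  }, numeric(1))
  (f - 1) / (4 / pi - 1)
}

#' Half-time of the OU magnitude autocorrelation
#'
#' Solves `ou_magnitude_autocorr(t, tau) = 1/2` for `t`.
#'
#' @param tau_min OU correlation time (min).
#' @return Half-time in minutes (~0.32 * tau).
#' @export
ou_magnitude_halftime <- function(tau_min) {
  stats::uniroot(function(t) ou_magnitude_autocorr(t, tau_min) - 0.5,
                 interval = c(1e-6 * tau_min, 10 * tau_min))$root
}
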