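test_that("cantilever stiffness and effective modulus match closed forms", {
  # linearity in the material modulus
  expect_equal(pillar_stiffness(4.1, 2, 4), 2 * pillar_stiffness(4.1, 2, 2))
  # direct evaluation: 3*pi*E*r^4/(4h^3)
  expect_equal(pillar_stiffness(4.1, 2, 2), 68.4, tolerance = 1e-3)
  # inverse solve: E = 1.925 MPa reproduces the 65.8 nN/um array
  expect_equal(pillar_stiffness(4.1, 2, 1.925), 65.8, tolerance = 1e-3)
  expect_error(pillar_stiffness(-1, 2, 2), class = "fadyn_config_error")

  expect_equal(effective_young_modulus(65.8, 1), 47.2, tolerance = 0.005)
  expect_equal(effective_young_modulus(0, 1), 0)
  # 0.1 N/m = 100 nN/um at r = 2 um
  expect_equal(effective_young_modulus(100, 2), 35.8, tolerance = 1e-3)
  expect_error(effective_young_modulus(65.8, 0),
               class = "fadyn_config_error")
  # pillar_spec keeps stiffness and modulus consistent
  spec <- pillar_spec()
  expect_equal(spec$effective_young_kPa,
               effective_young_modulus(spec$bending_stiffness_nN_um, 1))
})

test_that("pillar detection localizes discs to sub-pixel accuracy", {
  expect_warning(det0 <- detect_pillars(matrix(0, 50, 50)), "blank")
  expect_equal(nrow(det0), 0)

  set.seed(5)
  fr <- render_pillar_frame(10.07, 20.03, c(160, 120), snr = 20)
  det <- detect_pillars(fr)
  expect_equal(nrow(det), 1)
  expect_lt(sqrt((det$x_um - 10.07)^2 + (det$y_um - 20.03)^2), 0.05)
})

test_that("reference grid fitting recovers lattice geometry", {
  lat <- fadyn:::hex_lattice(200, 4)
  g <- fit_reference_grid(tibble::tibble(x_um = lat$x, y_um = lat$y), 4)
  expect_lt(g$residual_rms_um, 1e-9)
  expect_equal(sqrt(sum(g$a1^2)), 4, tolerance = 1e-9)
  expect_equal(sqrt(sum(g$a2^2)), 4, tolerance = 1e-9)
  # 60-degree basis angle
  cosang <- sum(g$a1 * g$a2) / 16
  expect_equal(cosang, cos(pi / 3), tolerance = 1e-9)

  # rotation recovered within 0.5 degrees with 30% perturbed but excluded
  set.seed(3)
  th <- 13 * pi / 180
  p <- cbind(lat$x, lat$y) %*% t(matrix(c(cos(th), sin(th),
                                          -sin(th), cos(th)), 2, 2))
  pert <- sample(nrow(p), 60)
  p[pert, ] <- p[pert, ] + matrix(rnorm(120, 0, 0.4), ncol = 2)
  g2 <- fit_reference_grid(tibble::tibble(x_um = p[, 1], y_um = p[, 2]), 4,
                           exclude = seq_len(nrow(p)) %in% pert)
  expect_lt(abs(g2$rotation_deg - 13), 0.5)

  # pitch recovered within 1% under 0.05 um noise on all pillars
  set.seed(4)
  p3 <- cbind(lat$x, lat$y) + matrix(rnorm(2 * nrow(lat), 0, 0.05), ncol = 2)
  g3 <- fit_reference_grid(tibble::tibble(x_um = p3[, 1], y_um = p3[, 2]), 4)
  expect_lt(abs(g3$pitch_um - 4) / 4, 0.01)
})

test_that("grid fit is rotation-equivariant", {
  lat <- fadyn:::hex_lattice(150, 4)
  g0 <- fit_reference_grid(tibble::tibble(x_um = lat$x, y_um = lat$y), 4)
  th <- 25 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p <- cbind(lat$x, lat$y) %*% t(R)
  g1 <- fit_reference_grid(tibble::tibble(x_um = p[, 1], y_um = p[, 2]), 4)
  expect_equal(abs(sum(g1$a1 * (R %*% g0$a1))) / 16, 1, tolerance = 1e-6)
  expect_equal(g1$pitch_um, g0$pitch_um, tolerance = 1e-9)
})

test_that("deflections convert linearly to forces and flag mis-assignments", {
  lat <- fadyn:::hex_lattice(100, 4)
  g <- fit_reference_grid(tibble::tibble(x_um = lat$x, y_um = lat$y), 4)
  on_lattice <- compute_deflections(
    tibble::tibble(x_um = lat$x[1], y_um = lat$y[1]), g, 65.8)
  expect_equal(on_lattice$force_nN, 0, tolerance = 1e-9)

  shifted <- compute_deflections(
    tibble::tibble(x_um = lat$x[12] + 0.5, y_um = lat$y[12]), g, 65.8)
  expect_equal(shifted$force_nN, 32.9, tolerance = 1e-9)
  expect_equal(shifted$fx_nN, 32.9, tolerance = 1e-9)

  # a deflection beyond pitch/2 cannot be assigned and is dropped
  expect_warning(
    far <- compute_deflections(
      tibble::tibble(x_um = lat$x[12] + 2.3, y_um = lat$y[12] + 1.4),
      g, 65.8, ij = cbind(lat$i[12], lat$j[12])),
    "mis-assigned")
  expect_equal(nrow(far), 0)
})

test_that("gap-closing tracker keeps pillars through misses", {
  # static detections, no misses: all tracks full length
  det <- tidyr::expand_grid(frame = 1:10, pillar = 1:9) |>
    dplyr::mutate(x_um = 4 * ((pillar - 1) %% 3),
                  y_um = 4 * ((pillar - 1) %/% 3))
  tk <- track_pillars(det)
  expect_equal(dplyr::n_distinct(tk$track), 9)
  expect_true(all(dplyr::count(tk, track)$n == 10))
  # conservation: one detection per track and frame
  expect_equal(anyDuplicated(tk[, c("track", "frame")]), 0L)

  # close pair: assignment by ascending displacement prevents swaps
  two <- tibble::tibble(frame = rep(1:2, each = 2),
                        x_um = c(0, 1.5, 0.1, 1.6), y_um = 0)
  tk2 <- track_pillars(two, gate_um = 2)
  expect_equal(dplyr::n_distinct(tk2$track), 2)
  expect_equal(sort(dplyr::count(tk2, track)$n), c(2, 2))

  expect_error(track_pillars(tibble::tibble(frame = 1, x_um = 0, y_um = 0)),
               class = "fadyn_input_error")
})

test_that("a 2% miss rate still leaves >90% of pillars fully tracked", {
  cfg <- pillar_sim_config(seed = 6, n_pillars = 150, n_frames = 40,
                           miss_rate = 0.02,
                           cell_footprint = list(center_um = NULL,
                                                 radius_um = 10))
  mv <- generate_pillar_movie(cfg)
  tk <- track_pillars(mv$detections)
  per_pillar <- tk |>
    dplyr::group_by(pillar) |>
    dplyr::summarise(one = dplyr::n_distinct(track) == 1,
                     tr = track[1], .groups = "drop")
  spans <- tk |>
    dplyr::group_by(track) |>
    dplyr::summarise(first = min(frame), last = max(frame))
  j <- dplyr::left_join(per_pillar, spans, by = c(tr = "track"))
  ok <- j$one & j$first <= 3 & j$last >= cfg$n_frames - 2
  expect_gt(mean(ok), 0.9)
})

test_that("cell mask segmentation recovers the actin footprint", {
  expect_equal(sum(segment_cell_mask(matrix(0, 60, 60))), 0)

  pm <- generate_pillar_movie(
    pillar_sim_config(seed = 3, n_pillars = 200, n_frames = 1,
                      cell_footprint = list(center_um = NULL,
                                            radius_um = 15)),
    render = TRUE)
  m <- segment_cell_mask(pm$actin[[1]])
  nr <- nrow(m); nc <- ncol(m)
  yy <- matrix(fadyn:::px_to_um(seq_len(nr), 0.2), nr, nc)
  xx <- matrix(fadyn:::px_to_um(seq_len(nc), 0.2), nr, nc, byrow = TRUE)
  truth <- sqrt((xx - pm$footprint$center_um[1])^2 +
                  (yy - pm$footprint$center_um[2])^2) <= 15
  expect_gte(sum(m & truth) / sum(m | truth), 0.8)

  # two disjoint cells give two components without a bridge
  two <- fadyn:::render_spots_disc(300, 300, c(80, 220), c(80, 220),
                                   c(1, 1), radius_px = 50, blur_px = 5)
  set.seed(1)
  m2 <- segment_cell_mask(fadyn:::add_camera_noise(two, 20))
  expect_equal(max(EBImage::bwlabel(m2)), 2)
})

test_that("top-deflected selection ranks coupled pillars", {
  tr <- tidyr::expand_grid(track = 1:40, frame = 1:10) |>
    dplyr::mutate(defl_um = 0.01 * track)
  sel <- select_top_deflected(tr, fraction = 1)
  expect_true(all(sel$selected))
  sel2 <- select_top_deflected(tr, fraction = 0.05)
  expect_equal(sum(sel2$selected), 2)  # ceil(0.05 * 40)
  expect_setequal(sel2$track[sel2$selected], c(39, 40))

  # planted high-deflection pillars land in the top selection
  set.seed(2)
  tr2 <- tidyr::expand_grid(track = 1:100, frame = 1:10) |>
    dplyr::mutate(defl_um = abs(rnorm(dplyr::n(), 0.1, 0.02)) +
                    ifelse(track %in% c(7, 55, 91), 1, 0))
  sel3 <- select_top_deflected(tr2, fraction = 0.05)
  expect_true(all(c(7, 55, 91) %in% sel3$track[sel3$selected]))

  # uncoupled pillars are never selected
  expect_warning(
    sel4 <- select_top_deflected(tr, in_cell = rep(FALSE, nrow(tr))),
    "no cell-coupled")
  expect_false(any(sel4$selected))
  expect_error(select_top_deflected(tr, fraction = 0),
               class = "fadyn_config_error")
})

test_that("force summaries aggregate constant and mixed inputs correctly", {
  tr <- tidyr::expand_grid(track = 1:2, frame = 1:6) |>
    dplyr::mutate(force_nN = ifelse(track == 1, 10, 30))
  fs <- force_timeseries_summary(tr)
  expect_true(all(fs$timeseries$mean_force_nN == 20))
  expect_equal(sort(fs$per_pillar$mean_force_nN), c(10, 30))
  expect_equal(fs$cdf(10), 0.5)
  expect_equal(fs$cdf(30), 1)
  expect_error(force_timeseries_summary(tr[0, ]),
               class = "fadyn_input_error")
})

test_that("autocorrelation is unit at lag 0 and fits exact decays", {
  # noise-free exponential: the fitted half-time is exact
  t <- (0:24) * 5
  fit <- fadyn:::fit_exp_decay(t, exp(-t * log(2) / 22))
  expect_equal(log(2) / fit$lambda, 22, tolerance = 1e-4)
  expect_equal(fit$a, 1, tolerance = 1e-4)
  expect_equal(fit$c, 0, tolerance = 1e-5)

  set.seed(8)
  tracks <- sim_force_tracks(12, 60, tau_min = 30)
  ac <- force_autocorrelation(tracks)
  expect_equal(ac$mean_autocorr[1], 1)
  expect_equal(length(ac$lags_min), 25)
  expect_gt(ac$halftime_min, 0)

  const <- tidyr::expand_grid(track = 1:3, frame = 1:30) |>
    dplyr::mutate(force_nN = 5)
  expect_error(suppressWarnings(force_autocorrelation(const)),
               class = "fadyn_input_error")
})

test_that("pipeline half-time recovery matches the OU magnitude oracle", {
  cfg <- pillar_sim_config(seed = 11, n_pillars = 144, ou_tau_min = 40,
                           cell_footprint = list(center_um = NULL,
                                                 radius_um = 18))
  mv <- generate_pillar_movie(cfg)
  chain <- run_pillar_chain(mv)
  ac <- force_autocorrelation(chain$selected_tracks)
  oracle <- ou_magnitude_halftime(40)
  expect_lt(abs(ac$halftime_min - oracle) / oracle, 0.25)
  # mean force recovery within 5% of ground truth
  truth <- mv$truth |>
    dplyr::filter(!missed,
                  pillar %in% mv$pillars$pillar[mv$pillars$inside_cell]) |>
    dplyr::mutate(f = 65.8 * sqrt(dx_um^2 + dy_um^2))
  expect_lt(abs(mean(chain$selected_tracks$force_nN) - mean(truth$f)) /
              mean(truth$f), 0.05)
})

test_that("force statistics scale linearly with deflection amplitude", {
  set.seed(10)
  tracks <- sim_force_tracks(10, 60, tau_min = 30)
  doubled <- dplyr::mutate(tracks, force_nN = 2 * force_nN)
  f1 <- force_timeseries_summary(tracks)
  f2 <- force_timeseries_summary(doubled)
  expect_equal(f2$per_pillar$mean_force_nN, 2 * f1$per_pillar$mean_force_nN)
  a1 <- force_autocorrelation(tracks)
  a2 <- force_autocorrelation(doubled)
  expect_equal(a2$halftime_min, a1$halftime_min, tolerance = 1e-9)
})

test_that("half-time comparison is null-calibrated and detects differences", {
  set.seed(12)
  a <- force_autocorrelation(sim_force_tracks(15, 80, tau_min = 40))
  same <- compare_halftimes(a, a, n_perm = 99)
  expect_lt(same$f, 1e-9)
  expect_gt(same$p, 0.9)

  b <- force_autocorrelation(sim_force_tracks(20, 80, tau_min = 68))
  c_ <- force_autocorrelation(sim_force_tracks(20, 80, tau_min = 140))
  diff <- compare_halftimes(b, c_, n_perm = 199)
  expect_lt(diff$p, 0.05)
  expect_gt(diff$halftime2_min, diff$halftime1_min)
})

test_that("Welch force comparison matches a permutation oracle", {
  x <- c(1, 2, 3)
  same <- compare_forces(x, x)
  expect_gt(same$p.value, 0.99)

  set.seed(13)
  f1 <- rnorm(15, 20, 3)
  f2 <- rnorm(15, 30, 5)
  w <- compare_forces(f1, f2)
  expect_lt(w$p.value, 0.05)
  obs <- abs(mean(f1) - mean(f2))
  perm <- replicate(2000, {
    z <- sample(c(f1, f2))
    abs(mean(z[1:15]) - mean(z[16:30]))
  })
  expect_lt((1 + sum(perm >= obs)) / 2001, 0.05)
  # antisymmetry of the statistic
  expect_equal(compare_forces(f2, f1)$statistic, -w$statistic,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(compare_forces(c(1, 1, 1), c(2, 2, 2)),
               class = "fadyn_input_error")
  expect_error(compare_forces(1:2, 1:5), class = "fadyn_input_error")
})
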