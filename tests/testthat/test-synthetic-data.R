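test_that("generators are deterministic under a fixed seed", {
  a <- generate_fa_image(fa_image_config(seed = 3))
  b <- generate_fa_image(fa_image_config(seed = 3))
  expect_identical(a, b)

  cfg <- pillar_sim_config(seed = 42, n_pillars = 80, n_frames = 6,
                           cell_footprint = list(center_um = NULL,
                                                 radius_um = 8))
  expect_identical(generate_pillar_movie(cfg), generate_pillar_movie(cfg))

  mcfg <- migration_sim_config(seed = 5, n_cells = 8, n_frames = 6,
                               pre_stim_frames = 3)
  expect_identical(generate_migration_movie(mcfg),
                   generate_migration_movie(mcfg))
})

test_that("empty and degenerate fields behave as documented", {
  im <- generate_fa_image(fa_image_config(n_cells = 0, seed = 1))
  expect_equal(nrow(im$truth), 0)
  expect_equal(max(segment_adhesions(im$vinculin)), 0)

  mv <- generate_migration_movie(
    migration_sim_config(seed = 2, n_cells = 5, n_frames = 8,
                         pre_stim_frames = 3, speed_pre_um_min = 0,
                         speed_post_um_min = 0), render = FALSE)
  expect_true(all(mv$speeds$true_speed_um_min == 0))
  pos1 <- dplyr::filter(mv$truth, frame == 1)
  pos8 <- dplyr::filter(mv$truth, frame == 8)
  expect_equal(pos1$x_um, pos8$x_um)

  pm <- generate_pillar_movie(
    pillar_sim_config(seed = 3, n_pillars = 60, n_frames = 5, ou_sd_um = 0,
                      cell_footprint = list(center_um = NULL,
                                            radius_um = 6)))
  expect_true(all(pm$truth$dx_um == 0 & pm$truth$dy_um == 0))
})

test_that("condition multiplier scales true areas without moving spots", {
  a <- generate_fa_image(fa_image_config(seed = 3,
                                         condition_size_multiplier = 1))
  b <- generate_fa_image(fa_image_config(seed = 3,
                                         condition_size_multiplier = 1.5))
  expect_equal(a$truth$x_um, b$truth$x_um)
  expect_equal(a$truth$y_um, b$truth$y_um)
  expect_equal(b$truth$area_um2 / a$truth$area_um2,
               rep(1.5, nrow(a$truth)))
})

test_that("a 1.5x size multiplier is detectable as a positive signed shift", {
  pool <- function(mult, seeds) {
    unlist(lapply(seeds, function(s)
      generate_fa_image(fa_image_config(
        seed = s, condition_size_multiplier = mult))$truth$area_um2))
  }
  noco <- pool(1.5, 1:17)   # ~2000 adhesions
  dmso <- pool(1.0, 21:37)
  ks <- signed_ks_test(noco, dmso)
  oracle <- brute_force_ks(noco, dmso)
  expect_gt(ks$signed_d, 0)
  expect_equal(abs(ks$signed_d), oracle$d)
  expect_equal(sign(ks$signed_d), sign(oracle$signed_d))
})

test_that("screen dataset emits duplicate wells and planted categories", {
  layout <- tibble::tibble(well = "B02", gene = "siGFP", is_control = TRUE)
  ds <- generate_screen_dataset(layout, seed = 1, n_images = 1,
                                base_config = fa_image_config(
                                  n_cells = 2, adhesions_per_cell = 5))
  combos <- dplyr::distinct(ds$truth, well, replicate, condition)
  expect_equal(nrow(combos), 6)  # 1 well x 2 replicates x 3 conditions

  expect_equal(planted_category(1, 1, 1), "assembly_blocked")
  expect_equal(planted_category(1, 1.6, 1.6), "disassembly_blocked")
  expect_equal(planted_category(1.5, 2.4, 1.5), "increase")
  expect_equal(planted_category(0.7, 1.1, 0.7), "decrease")
  expect_equal(planted_category(1, 1.6, 1.0), "none")

  expect_error(generate_screen_dataset(layout, seed = 1,
                                       conditions = c("DMSO", "mystery")),
               class = "fadyn_input_error")
  expect_error(generate_screen_dataset(
    tibble::tibble(well = c("A1", "A1"), gene = c("g1", "g2")), seed = 1),
    class = "fadyn_input_error")
})

test_that("migration ground truth matches the configured kinematics", {
  mv <- generate_migration_movie(
    migration_sim_config(seed = 4, n_cells = 4, n_frames = 8,
                         pre_stim_frames = 3, speed_pre_um_min = 0.2,
                         speed_post_um_min = 0.6, position_noise_um = 0),
    render = FALSE)
  post <- mv$truth |>
    dplyr::filter(phase == "post") |>
    dplyr::group_by(cell) |>
    dplyr::arrange(frame, .by_group = TRUE) |>
    dplyr::summarise(steps = list(sqrt(diff(x_um)^2 + diff(y_um)^2)))
  steps <- unlist(post$steps)
  # post-stimulation step length is v * dt except when walls/contacts act
  expect_true(mean(abs(steps - 6) < 1e-9) > 0.8)

  big <- generate_migration_movie(
    migration_sim_config(seed = 11, n_cells = 50, n_frames = 25,
                         pre_stim_frames = 5, speed_post_um_min = 0.5,
                         image_size_px = c(480L, 480L)), render = FALSE)
  m <- mean(dplyr::filter(big$speeds, phase == "post")$true_speed_um_min)
  expect_lt(abs(m - 0.5) / 0.5, 0.05)
})

test_that("migration generator rejects over-packed fields", {
  expect_error(generate_migration_movie(
    migration_sim_config(seed = 1, n_cells = 500, n_frames = 4,
                         pre_stim_frames = 2,
                         image_size_px = c(128L, 128L))),
    class = "fadyn_config_error")
})

test_that("pillar lattice has the configured pitch and hexagonal geometry", {
  pm <- generate_pillar_movie(
    pillar_sim_config(seed = 2, n_pillars = 120, n_frames = 2,
                      cell_footprint = list(center_um = NULL,
                                            radius_um = 8)))
  p <- cbind(pm$pillars$base_x_um, pm$pillars$base_y_um)
  d <- as.matrix(dist(p))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_equal(unname(nn), rep(4, nrow(p)), tolerance = 1e-9)
  # interior pillars have six neighbours at the pitch
  interior <- which(rowSums(d < 4.1) == 6)
  expect_gt(length(interior), 0)
})

test_that("OU deflections have the configured variance and decay", {
  cfg <- pillar_sim_config(seed = 8, n_pillars = 900, n_frames = 80,
                           ou_sd_um = 0.3, ou_tau_min = 10,
                           cell_footprint = list(center_um = NULL,
                                                 radius_um = 40))
  pm <- generate_pillar_movie(cfg)
  coupled <- pm$pillars$pillar[pm$pillars$inside_cell]
  tr <- dplyr::filter(pm$truth, pillar %in% coupled)
  expect_gt(nrow(tr), 500)
  expect_lt(abs(var(tr$dx_um) - 0.3^2) / 0.3^2, 0.05)
  expect_lt(abs(var(tr$dy_um) - 0.3^2) / 0.3^2, 0.05)
  # component autocorrelation at lag tau ~ exp(-1)
  wide <- matrix(tr$dx_um, nrow = cfg$n_frames)
  lag <- cfg$ou_tau_min / cfg$frame_interval_min
  ac <- cor(as.vector(wide[seq_len(80 - lag), ]),
            as.vector(wide[(1 + lag):80, ]))
  expect_lt(abs(ac - exp(-1)) / exp(-1), 0.1)
})

test_that("ground-truth object counts equal rendered object counts", {
  im <- generate_fa_image(fa_image_config(seed = 9, n_cells = 3,
                                          adhesions_per_cell = 7))
  expect_equal(nrow(im$truth), 21)
  nuc <- segment_nuclei(im$nuclei)
  expect_equal(nuc$count, 3)

  pm <- generate_pillar_movie(
    pillar_sim_config(seed = 4, n_pillars = 90, n_frames = 2, ou_sd_um = 0,
                      miss_rate = 0,
                      cell_footprint = list(center_um = NULL,
                                            radius_um = 6)),
    render = TRUE)
  det <- detect_pillars(pm$frames[[1]])
  expect_equal(nrow(det), nrow(pm$pillars))
})
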