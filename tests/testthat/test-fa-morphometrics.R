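test_that("image QC includes fields with at least 3 nuclei", {
  expect_false(qc_image(0)$included)
  expect_false(qc_image(2)$included)
  expect_true(qc_image(3)$included)
  expect_error(qc_image(-1))
})

test_that("nuclei segmentation counts blobs and splits touching pairs", {
  blank <- matrix(0, 120, 120)
  expect_equal(segment_nuclei(blank)$count, 0)

  # 7 well-separated Gaussian nuclei
  set.seed(1)
  pos <- expand.grid(r = c(25, 60, 95), c = c(25, 60, 95))[1:7, ]
  clean <- fadyn:::render_spots_gauss(120, 120, pos$r, pos$c, rep(1, 7),
                                      rep(6, 7), rep(6, 7), rep(0, 7))
  img <- fadyn:::add_camera_noise(clean, 15)
  expect_equal(segment_nuclei(img)$count, 7)

  # two touching nuclei with distinct intensity peaks
  pair <- fadyn:::render_spots_gauss(80, 80, c(40, 40), c(30, 48),
                                     c(1, 0.9), c(6, 6), c(6, 6), c(0, 0))
  img2 <- fadyn:::add_camera_noise(pair, 20)
  expect_equal(segment_nuclei(img2)$count, 2)

  expect_error(segment_nuclei(array(0, c(4, 4, 2))),
               class = "fadyn_input_error")
})

test_that("adhesion segmentation ignores objects smaller than 4 pixels", {
  set.seed(2)
  img <- matrix(0, 80, 80)
  img[40, 40:42] <- 1  # 3-pixel object
  lab <- segment_adhesions(fadyn:::add_camera_noise(img, 30))
  expect_equal(max(lab), 0)

  blank <- fadyn:::add_camera_noise(matrix(0, 80, 80), 15)
  expect_equal(max(segment_adhesions(blank)), 0)

  expect_error(segmentation_params(gaussian_sigma_px = 0),
               class = "fadyn_config_error")
  expect_error(segmentation_params(rolling_ball_radius_px = -1),
               class = "fadyn_config_error")
})

test_that("synthetic adhesions are recovered with sub-2-px centroids", {
  im <- generate_fa_image(fa_image_config(seed = 5, snr = 12))
  rec <- measure_adhesions(segment_adhesions(im$vinculin), im$vinculin)
  tr <- dplyr::filter(im$truth, area_px >= 6)
  d <- sqrt(outer(tr$x_um, rec$x_um, "-")^2 +
              outer(tr$y_um, rec$y_um, "-")^2) / 0.339
  expect_gte(mean(apply(d, 1, min) < 2), 0.95)
  # no emitted record below the 4-px filter
  expect_true(all(rec$area_px >= 4))
  # areas partition the image
  expect_lte(sum(rec$area_px), length(im$vinculin))
})

test_that("measured features match geometric ground truth", {
  # 4-px square at the default pixel size covers 0.46 um^2
  m <- matrix(0L, 10, 10)
  m[5:6, 5:6] <- 1L
  rec <- measure_adhesions(m, matrix(1, 10, 10), pixel_size_um = 0.339)
  expect_equal(round(rec$area_um2, 2), 0.46)
  expect_equal(rec$mean_intensity, 1)

  # disc: compact factor near 1, elongation near 0
  disc <- ellipse_mask(90, 90, 45, 45, 20, 20)
  rd <- measure_adhesions(matrix(as.integer(disc), 90, 90),
                          matrix(1, 90, 90))
  expect_lt(abs(rd$compact_factor - 1), 0.1)
  expect_lt(rd$elongation, 0.05)

  # 2:1 ellipse: moment axis ratio 2 within 5%, orientation recovered
  ell <- ellipse_mask(80, 80, 40, 40, 24, 12, theta = 0)
  re <- measure_adhesions(matrix(as.integer(ell), 80, 80),
                          matrix(1, 80, 80))
  ratio <- sqrt(1 / (1 - re$elongation))
  expect_lt(abs(ratio - 2) / 2, 0.05)
  expect_lt(abs(re$orientation_deg), 3)
  expect_true(re$orientation_deg >= -90 && re$orientation_deg < 90)

  # empty mask gives an empty table, not an error
  expect_equal(nrow(measure_adhesions(matrix(0L, 5, 5), matrix(0, 5, 5))), 0)
  expect_error(measure_adhesions(matrix(0L, 5, 5), matrix(0, 6, 6)),
               class = "fadyn_input_error")
})

test_that("features scale correctly with pixel size", {
  ell <- matrix(as.integer(ellipse_mask(60, 60, 30, 30, 15, 8)), 60, 60)
  img <- matrix(1, 60, 60)
  a <- measure_adhesions(ell, img, pixel_size_um = 0.339)
  b <- measure_adhesions(ell, img, pixel_size_um = 0.678)
  expect_equal(b$area_um2, 4 * a$area_um2)
  expect_equal(b$perimeter_um, 2 * a$perimeter_um)
  for (f in c("elongation", "extension", "dispersion", "compact_factor")) {
    expect_equal(b[[f]], a[[f]])
  }
})

test_that("segmentation is translation-equivariant", {
  im <- generate_fa_image(fa_image_config(seed = 7, n_cells = 2,
                                          adhesions_per_cell = 6,
                                          image_size_px = c(240L, 240L)))
  img <- im$vinculin
  shift <- 15L
  shifted <- matrix(0, nrow(img), ncol(img))
  shifted[(1 + shift):nrow(img), (1 + shift):ncol(img)] <-
    img[seq_len(nrow(img) - shift), seq_len(ncol(img) - shift)]
  r1 <- measure_adhesions(segment_adhesions(img), img)
  r2 <- measure_adhesions(segment_adhesions(shifted), shifted)
  r1 <- dplyr::arrange(r1, x_um, y_um)
  r2 <- dplyr::arrange(r2, x_um, y_um)
  expect_equal(nrow(r1), nrow(r2))
  expect_equal(r2$x_um - r1$x_um, rep(shift * 0.339, nrow(r1)),
               tolerance = 0.02)
  expect_equal(r2$y_um - r1$y_um, rep(shift * 0.339, nrow(r1)),
               tolerance = 0.02)
})

test_that("run_well pools included fields over both channels", {
  im_lo <- generate_fa_image(fa_image_config(seed = 2, n_cells = 2,
                                             adhesions_per_cell = 5))
  out <- run_well(list(im_lo), well = "A1", condition = "DMSO")
  expect_equal(nrow(out$records), 0)
  expect_false(any(out$qc$included))

  fields <- lapply(1:2, function(s)
    generate_fa_image(fa_image_config(seed = s + 30, n_cells = 4,
                                      adhesions_per_cell = 5, snr = 12)))
  out2 <- run_well(fields, well = "A2", condition = "nocodazole")
  expect_setequal(unique(out2$records$channel), c("paxillin", "vinculin"))
  expect_equal(unique(out2$records$condition), "nocodazole")
  # 40 planted adhesions: pooled vinculin count within 10%
  n_vin <- sum(out2$records$channel == "vinculin")
  expect_lt(abs(n_vin - 40) / 40, 0.1)

  # a field missing one channel is analysed for the other, with a warning
  fields[[1]]$paxillin <- NULL
  expect_warning(out3 <- run_well(fields, well = "A3", condition = "DMSO"),
                 "no paxillin channel")
  expect_true(any(out3$records$channel == "vinculin"))
})
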