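#' Configuration for synthetic focal-adhesion images
#'
#' Describes one synthetic multi-channel field of view: a nuclei channel plus
#' two focal-adhesion (FA) channels (paxillin- and vinculin-like) that share
#' adhesion positions and sizes but carry independent intensity jitter.
#' True adhesion areas are drawn from a log-normal distribution (in square
#' micrometres) and scaled by `condition_size_multiplier`, which emulates the
#' microtubule-drug assay: a multiplier above 1 mimics drug-induced FA
#' assembly (larger adhesions), below 1 mimics disassembly.
#'
#' @param image_size_px Integer pair, image height and width in pixels.
#' @param pixel_size_um Pixel size in micrometres (default 0.339, so that a
#'   4-pixel object covers 0.46 um^2).
#' @param n_cells Number of cells in the field.
#' @param adhesions_per_cell Number of adhesions rendered per cell.
#' @param size_lognormal_mu_sigma Meanlog and sdlog of the adhesion-area
#'   distribution, in log um^2.
#' @param condition_size_multiplier Multiplicative shift applied to all true
#'   areas (> 0).
#' @param snr Shot-noise signal-to-noise ratio at unit spot amplitude (> 0).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A list of class `fa_image_config`.
#' @export
fa_image_config <- function(image_size_px = c(360L, 360L),
                            pixel_size_um = 0.339,
                            n_cells = 8L,
                            adhesions_per_cell = 15L,
                            size_lognormal_mu_sigma = c(0, 0.6),
                            condition_size_multiplier = 1,
                            snr = 15,
                            seed = 1L) {
  assert_positive(pixel_size_um, "pixel_size_um")
  assert_positive(snr, "snr")
  assert_positive(condition_size_multiplier, "condition_size_multiplier")
  if (length(image_size_px) != 2L || any(image_size_px < 16)) {
    abort("`image_size_px` must be two integers >= 16.",
          class = "fadyn_config_error")
  }
  if (n_cells < 0 || adhesions_per_cell < 0) {
    abort("`n_cells` and `adhesions_per_cell` must be non-negative.",
          class = "fadyn_config_error")
  }
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um,
                 n_cells = as.integer(n_cells),
                 adhesions_per_cell = as.integer(adhesions_per_cell),
                 size_lognormal_mu_sigma = size_lognormal_mu_sigma,
                 condition_size_multiplier = condition_size_multiplier,
                 snr = snr,
                 seed = as.integer(seed)),
            class = "fa_image_config")
}

#' Generate a synthetic focal-adhesion field of view
#'
#' Renders nuclei as Gaussian blobs and focal adhesions as anisotropic 2-D
#' Gaussian spots (aspect ratio drawn uniformly in 1-4) placed in an annulus
#' near the synthetic cell edge, where peripheral elongated adhesions sit in
#' real images. Both FA channels share spot positions and sizes; per-spot
#' intensities get independent log-normal jitter per channel. Poisson shot
#' noise plus Gaussian read noise is applied to every channel.
#'
#' @param config An [fa_image_config()].
#' @return A list with numeric matrices `nuclei`, `paxillin`, `vinculin` and
#'   a `truth` tibble (one row per adhesion: `cell`, `adhesion`, `x_um`,
#'   `y_um`, `area_um2`, `area_px`, `aspect`, `theta`).
#' @export
generate_fa_image <- function(config) {
  stopifnot(inherits(config, "fa_image_config"))
  withr::local_seed(config$seed)
  nr <- config$image_size_px[1]
  nc <- config$image_size_px[2]
  ps <- config$pixel_size_um

  cell_radius_um <- 15
  nucleus_sigma_um <- 3.5
  r_cell_px <- cell_radius_um / ps

  n_cells <- config$n_cells
  margin <- r_cell_px + 2
  if (n_cells > 0 && (nr < 2 * margin || nc < 2 * margin)) {
    abort("image too small for the configured cell radius.",
          class = "fadyn_config_error")
  }
  # cells keep some distance so their adhesion annuli rarely overlap
  cell_row <- numeric(n_cells)
  cell_col <- numeric(n_cells)
  for (k in seq_len(n_cells)) {
    for (try in 1:100) {
      rr <- runif(1, margin, nr - margin)
      cc <- runif(1, margin, nc - margin)
      if (k == 1L || all(sqrt((cell_row[seq_len(k - 1)] - rr)^2 +
                                (cell_col[seq_len(k - 1)] - cc)^2) >
                           1.6 * r_cell_px)) break
    }
    cell_row[k] <- rr
    cell_col[k] <- cc
  }

  n_adh <- n_cells * config$adhesions_per_cell
  truth <- tibble(cell = integer(0), adhesion = integer(0),
                  x_um = numeric(0), y_um = numeric(0),
                  area_um2 = numeric(0), area_px = numeric(0),
                  aspect = numeric(0), theta = numeric(0))
  fa_clean <- matrix(0, nr, nc)
  if (n_adh > 0) {
    cell_of <- rep(seq_len(n_cells), each = config$adhesions_per_cell)
    mu <- config$size_lognormal_mu_sigma[1] +
      log(config$condition_size_multiplier)
    area_um2 <- rlnorm(n_adh, mu, config$size_lognormal_mu_sigma[2])
    area_px <- area_um2 / ps^2
    aspect <- runif(n_adh, 1, 4)
    # the half-maximum contour of the Gaussian spot encloses ~the true area
    sig_prod <- area_px / (2 * pi * log(2))
    sig_major <- sqrt(sig_prod * aspect)
    sig_minor <- sqrt(sig_prod / aspect)
    # adhesions are discrete structures that do not interpenetrate:
    # required separation grows with the extents of both spots
    ang <- numeric(n_adh)
    row <- numeric(n_adh)
    col <- numeric(n_adh)
    for (k in seq_len(n_adh)) {
      prev <- seq_len(k - 1)
      # separation uses the unit-multiplier spot extents so that identical
      # seeds give identical placements across condition multipliers
      sig0 <- sig_major / sqrt(config$condition_size_multiplier)
      need <- 2 / ps + 1.5 * (sig0[k] + sig0[prev])
      for (try in 1:80) {
        a <- runif(1, 0, 2 * pi)
        rad <- r_cell_px * sqrt(runif(1, 0.55^2, 1))
        rr <- cell_row[cell_of[k]] + rad * sin(a)
        cc <- cell_col[cell_of[k]] + rad * cos(a)
        if (k == 1L || all(sqrt((row[prev] - rr)^2 + (col[prev] - cc)^2) >
                             need)) break
      }
      ang[k] <- a
      row[k] <- min(max(rr, 3), nr - 3)
      col[k] <- min(max(cc, 3), nc - 3)
    }
    theta <- ang + pi / 2 + rnorm(n_adh, 0, 0.3)  # roughly tangential
    truth <- tibble(cell = cell_of, adhesion = seq_len(n_adh),
                    x_um = px_to_um(col, ps), y_um = px_to_um(row, ps),
                    area_um2 = area_um2, area_px = area_px,
                    aspect = aspect, theta = theta)
    amp <- rlnorm(n_adh, 0, 0.2)
  }

  nuc_clean <- render_spots_gauss(nr, nc, cell_row, cell_col,
                                  rep(1, n_cells),
                                  rep(nucleus_sigma_um / ps, n_cells),
                                  rep(nucleus_sigma_um / ps, n_cells),
                                  rep(0, n_cells))
  pax_clean <- fa_clean
  vin_clean <- fa_clean
  if (n_adh > 0) {
    # per-spot intensity jitter is channel specific, so each FA channel is
    # rendered with its own amplitudes at the shared positions
    jitter1 <- rlnorm(n_adh, 0, 0.15)
    jitter2 <- rlnorm(n_adh, 0, 0.15)
    pax_clean <- render_spots_gauss(nr, nc, row, col, amp * jitter1,
                                    sig_major, sig_minor, theta)
    vin_clean <- render_spots_gauss(nr, nc, row, col, amp * jitter2,
                                    sig_major, sig_minor, theta)
  }
  list(nuclei = add_camera_noise(nuc_clean, config$snr),
       paxillin = add_camera_noise(pax_clean, config$snr),
       vinculin = add_camera_noise(vin_clean, config$snr),
       truth = truth)
}

#' Planted hit category implied by a gene's condition multipliers
#'
#' Maps the three per-condition size multipliers (control-like baseline,
#' drug-induced assembly, washout-induced disassembly) to the hit category
#' the screen should recover: `increase`/`decrease` for baseline shifts,
#' `assembly_blocked` when the drug condition fails to enlarge adhesions,
#' `disassembly_blocked` when washout fails to shrink them again.
#'
#' @param m_dmso,m_noco,m_washout Size multipliers per condition.
#' @param eps Relative tolerance below which a multiplier ratio counts as
#'   "no change" (default 0.05).
#' @return One of `"increase"`, `"decrease"`, `"assembly_blocked"`,
#'   `"disassembly_blocked"`, `"none"`.
#' @export
planted_category <- function(m_dmso, m_noco, m_washout, eps = 0.05) {
  if (m_dmso > 1 + eps) return("increase")
  if (m_dmso < 1 - eps) return("decrease")
  if (m_noco / m_dmso < 1 + eps) return("assembly_blocked")
  if (m_washout / m_noco > 1 - eps) return("disassembly_blocked")
  "none"
}

#' Generate a synthetic siRNA screen dataset
#'
#' For every well in the plate layout and every assay condition, draws true
#' adhesion-area samples (and optionally renders images) with the gene's
#' per-condition size multiplier. Wells are generated in transfection
#' duplicate and both replicates carry the same gene and multipliers.
#'
#' @param layout Tibble with columns `well`, `gene`, `is_control` (logical).
#'   Wells must be unique.
#' @param effects Tibble with columns `gene`, `m_dmso`, `m_noco`,
#'   `m_washout`. Genes absent from `effects` get the neutral responder
#'   pattern (1, 1.6, 1.0): normal baseline, drug-induced assembly, full
#'   washout disassembly.
#' @param seed Integer seed.
#' @param conditions Condition labels; must be the three canonical labels.
#' @param n_images Fields of view per well.
#' @param base_config An [fa_image_config()] used as template.
#' @param render If `TRUE`, rendered image triplets are included (slow);
#'   otherwise only ground truth tables are returned.
#' @return A list with `truth` (per-adhesion tibble: `well`, `replicate`,
#'   `gene`, `condition`, `image`, `area_um2`, ...), `categories` (tibble
#'   `gene`, `category` of planted truth), and `images` (list or `NULL`).
#' @export
generate_screen_dataset <- function(layout, effects = NULL, seed = 1L,
                                    conditions = c("DMSO", "nocodazole",
                                                   "washout"),
                                    n_images = 3L,
                                    base_config = fa_image_config(),
                                    render = FALSE) {
  layout <- as_tibble(layout)
  stopifnot(all(c("well", "gene") %in% names(layout)))
  if (anyDuplicated(layout$well)) {
    abort("layout wells must be unique.", class = "fadyn_input_error")
  }
  if (!"is_control" %in% names(layout)) layout$is_control <- FALSE
  canonical <- c("DMSO", "nocodazole", "washout")
  if (!all(conditions %in% canonical)) {
    abort(sprintf("unknown condition label: %s",
                  paste(setdiff(conditions, canonical), collapse = ", ")),
          class = "fadyn_input_error")
  }
  neutral <- tibble(gene = unique(layout$gene),
                    m_dmso = 1, m_noco = 1.6, m_washout = 1.0)
  if (is.null(effects)) {
    effects <- neutral
  } else {
    effects <- bind_rows(as_tibble(effects),
                         filter(neutral, !.data$gene %in% effects$gene))
  }
  categories <- effects |>
    filter(.data$gene %in% layout$gene) |>
    mutate(category = purrr::pmap_chr(
      list(.data$m_dmso, .data$m_noco, .data$m_washout),
      planted_category)) |>
    select("gene", "category")

  grid <- tidyr::expand_grid(layout, replicate = c("A", "B"),
                             condition = conditions,
                             image = seq_len(n_images)) |>
    left_join(effects, by = "gene") |>
    mutate(multiplier = dplyr::case_when(
      condition == "DMSO" ~ .data$m_dmso,
      condition == "nocodazole" ~ .data$m_noco,
      TRUE ~ .data$m_washout))

  images <- if (render) vector("list", nrow(grid)) else NULL
  truth_list <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cfg <- base_config
    cfg$condition_size_multiplier <- grid$multiplier[k]
    cfg$seed <- as.integer((seed * 7919L + k * 104729L) %% .Machine$integer.max)
    im <- generate_fa_image(cfg)
    truth_list[[k]] <- im$truth |>
      mutate(well = grid$well[k], replicate = grid$replicate[k],
             gene = grid$gene[k], is_control = grid$is_control[k],
             condition = grid$condition[k], image = grid$image[k])
    if (render) {
      images[[k]] <- im[c("nuclei", "paxillin", "vinculin")]
    }
  }
  if (render) {
    names(images) <- paste(grid$well, grid$replicate, grid$condition,
                           grid$image, sep = "_")
  }
  list(truth = bind_rows(truth_list), categories = categories,
       images = images,
       layout = layout, effects = effects, seed = seed)
}
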