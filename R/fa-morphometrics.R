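#' Segmentation parameters for focal-adhesion images
#'
#' @param gaussian_sigma_px Gaussian pre-smoothing width in pixels (> 0).
#' @param rolling_ball_radius_px Radius of the background structuring
#'   element in pixels (> 0). Background is estimated by greyscale
#'   morphological opening with a disc of this radius and subtracted.
#' @param min_area_px Minimum object area kept, in pixels (default 4, i.e.
#'   0.46 um^2 at the default 0.339 um pixel size).
#' @param watershed_h Watershed merge tolerance as a fraction of the
#'   image dynamic range (default 0.1); maxima closer in height than this
#'   are merged into one object region.
#' @param local_threshold_method Per-region threshold, currently `"otsu"`.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(gaussian_sigma_px = 1,
                                rolling_ball_radius_px = 10,
                                min_area_px = 4L,
                                watershed_h = 0.1,
                                local_threshold_method = c("otsu")) {
  assert_positive(gaussian_sigma_px, "gaussian_sigma_px")
  assert_positive(rolling_ball_radius_px, "rolling_ball_radius_px")
  if (min_area_px < 1) {
    abort("`min_area_px` must be >= 1.", class = "fadyn_config_error")
  }
  structure(list(gaussian_sigma_px = gaussian_sigma_px,
                 rolling_ball_radius_px = rolling_ball_radius_px,
                 min_area_px = as.integer(min_area_px),
                 watershed_h = watershed_h,
                 local_threshold_method = match.arg(local_threshold_method)),
            class = "segmentation_params")
}

# Background subtraction: greyscale opening with a disc structuring element
# (the morphological analogue of rolling-ball background estimation).
subtract_background <- function(img, radius_px) {
  brush <- EBImage::makeBrush(2L * ceiling(radius_px) + 1L, shape = "disc")
  bg <- EBImage::opening(img, brush)
  pmax(img - bg, 0)
}

#' Segment nuclei and count them
#'
#' Gaussian blur, Otsu global threshold, hole filling, then a watershed on
#' the distance transform to split touching nuclei with distinct peaks.
#'
#' @param img 2-D numeric matrix (nuclei channel).
#' @param sigma_px Blur width in pixels.
#' @param min_area_px Minimum nucleus area kept.
#' @return List with `labels` (integer matrix) and `count`.
#' @export
segment_nuclei <- function(img, sigma_px = 3, min_area_px = 50L) {
  assert_image2d(img, "nuclei image")
  rng <- range(img)
  if (diff(rng) <= 0) {
    return(list(labels = matrix(0L, nrow(img), ncol(img)), count = 0L))
  }
  norm <- (img - rng[1]) / diff(rng)
  sm <- EBImage::gblur(norm, sigma = sigma_px)
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  mask <- sm > thr
  mask <- EBImage::fillHull(mask)
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  labels <- drop_small_labels(as_matrix_img(labels), min_area_px)
  list(labels = labels, count = max(labels))
}

as_matrix_img <- function(x) {
  if (inherits(x, "Image")) EBImage::imageData(x) else x
}

# Relabel consecutively after dropping labels below min area.
drop_small_labels <- function(labels, min_area_px) {
  labels <- as_matrix_img(labels)
  if (max(labels) == 0) return(matrix(0L, nrow(labels), ncol(labels)))
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area_px)
  map <- integer(length(areas))
  map[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  pos <- labels > 0
  out[pos] <- map[labels[pos]]
  out
}

#' Image-level quality control on the nuclei count
#'
#' Fields with fewer than 3 cells are excluded from analysis.
#'
#' @param count Non-negative nuclei count.
#' @param min_cells Inclusion threshold (default 3).
#' @return A tibble with `nuclei_count` and `included`.
#' @export
qc_image <- function(count, min_cells = 3L) {
  stopifnot(count >= 0)
  tibble(nuclei_count = as.integer(count),
         included = count >= min_cells)
}

#' Segment focal adhesions by watershed-masked clustering
#'
#' Pipeline: Gaussian smoothing, background subtraction (greyscale opening),
#' intensity watershed whose basins partition the signal around each local
#' maximum (merge tolerance `watershed_h` of the dynamic range), a per-basin
#' Otsu threshold that masks each region down to its bright core, connected
#' component labelling, and removal of objects below `min_area_px`.
#'
#' @param img 2-D numeric matrix (one FA channel).
#' @param params A [segmentation_params()].
#' @return Integer label matrix (0 = background).
#' @export
segment_adhesions <- function(img, params = segmentation_params()) {
  assert_image2d(img, "fa image")
  stopifnot(inherits(params, "segmentation_params"))
  sm <- EBImage::gblur(img, sigma = params$gaussian_sigma_px)
  sm <- as_matrix_img(sm)
  brush <- EBImage::makeBrush(
    2L * ceiling(params$rolling_ball_radius_px) + 1L, shape = "disc")
  bg <- EBImage::opening(sm, brush)
  sub <- pmax(sm - bg, 0)
  # raw signal over the same background: masking on it keeps object areas
  # at their unsmoothed extent (a 3-px object stays below the 4-px filter)
  sub_raw <- pmax(img - bg, 0)
  dyn <- max(sub)
  if (dyn <= 0) return(matrix(0L, nrow(img), ncol(img)))
  # noise scale after smoothing: raw pixel noise attenuated by the blur
  atten <- min(1, 1 / (2 * params$gaussian_sigma_px * sqrt(pi)))
  noise_sd <- max(stats::mad(img) * atten, 1e-9 * dyn)
  low <- max(4 * noise_sd, 0.05 * dyn)
  cand <- sub > low
  if (!any(cand)) return(matrix(0L, nrow(img), ncol(img)))
  ws <- EBImage::watershed(EBImage::Image(sub * cand),
                           tolerance = params$watershed_h * dyn, ext = 1)
  ws <- as_matrix_img(ws)
  mask <- matrix(FALSE, nrow(img), ncol(img))
  idx_all <- which(ws > 0)
  regions <- split(idx_all, ws[idx_all])
  for (px in regions) {
    if (max(sub[px]) < 8 * noise_sd) next  # indistinguishable from noise
    v <- sub_raw[px]
    thr <- otsu_threshold(v)
    mask[px[v > thr]] <- TRUE
  }
  labels <- as_matrix_img(EBImage::bwlabel(mask))
  drop_small_labels(labels, params$min_area_px)
}

#' Measure per-adhesion morphometric features
#'
#' Converts each labelled object to one feature record. Areas use the pixel
#' size; the perimeter is the Manhattan boundary-edge count corrected by
#' pi/4 and floored at the isoperimetric minimum `2*sqrt(pi*area)`, which
#' keeps `compact_factor = 4*pi*area/perimeter^2` in (0, 1]. Shape features
#' come from the eigenvalues `l1 >= l2` of the second-central-moment matrix
#' of pixel coordinates: `elongation = 1 - l2/l1`, `extension = l1/area_px`,
#' `dispersion = 4*pi*(l1+l2)/area_px^2`, and `orientation_deg` is the
#' principal-axis angle from the +x (column) axis in [-90, 90).
#'
#' @param labels Integer label matrix from [segment_adhesions()].
#' @param img Intensity image of the same shape.
#' @param pixel_size_um Pixel size in micrometres.
#' @return A tibble with one row per label: `label`, `area_px`, `area_um2`,
#'   `perimeter_um`, `extension`, `dispersion`, `elongation`,
#'   `orientation_deg`, `compact_factor`, `mean_intensity`, `x_um`, `y_um`.
#' @export
measure_adhesions <- function(labels, img, pixel_size_um = 0.339) {
  assert_image2d(img, "fa image")
  if (!identical(dim(labels), dim(img))) {
    abort("mask and image must have the same shape.",
          class = "fadyn_input_error")
  }
  idx <- which(labels > 0)
  if (!length(idx)) {
    return(tibble(label = integer(0), area_px = integer(0),
                  area_um2 = numeric(0), perimeter_um = numeric(0),
                  extension = numeric(0), dispersion = numeric(0),
                  elongation = numeric(0), orientation_deg = numeric(0),
                  compact_factor = numeric(0), mean_intensity = numeric(0),
                  x_um = numeric(0), y_um = numeric(0)))
  }
  lab <- labels[idx]
  rr <- (idx - 1L) %% nrow(labels) + 1L
  cc <- (idx - 1L) %/% nrow(labels) + 1L
  inten <- img[idx]
  edges <- label_edge_counts(labels)

  df <- tibble(lab = lab, r = rr, c = cc, i = inten) |>
    group_by(.data$lab) |>
    summarise(area_px = n(),
              mx = mean(.data$c), my = mean(.data$r),
              mu20 = mean((.data$c - mean(.data$c))^2),
              mu02 = mean((.data$r - mean(.data$r))^2),
              mu11 = mean((.data$c - mean(.data$c)) *
                            (.data$r - mean(.data$r))),
              mean_intensity = mean(.data$i),
              .groups = "drop")
  tr <- df$mu20 + df$mu02
  det_gap <- sqrt(pmax((df$mu20 - df$mu02)^2 + 4 * df$mu11^2, 0))
  l1 <- (tr + det_gap) / 2
  l2 <- (tr - det_gap) / 2
  theta <- 0.5 * atan2(2 * df$mu11, df$mu20 - df$mu02) * 180 / pi
  theta <- ((theta + 90) %% 180) - 90
  perim_px <- pmax(edges * pi / 4, 2 * sqrt(pi * df$area_px))
  area_um2 <- df$area_px * pixel_size_um^2
  tibble(label = df$lab,
         area_px = as.integer(df$area_px),
         area_um2 = area_um2,
         perimeter_um = perim_px * pixel_size_um,
         extension = l1 / df$area_px,
         dispersion = 4 * pi * (l1 + l2) / df$area_px^2,
         elongation = ifelse(l1 > 0, 1 - l2 / l1, 0),
         orientation_deg = theta,
         compact_factor = 4 * pi * df$area_px / perim_px^2,
         mean_intensity = df$mean_intensity,
         x_um = px_to_um(df$mx, pixel_size_um),
         y_um = px_to_um(df$my, pixel_size_um))
}

#' Analyse all images of one well and condition
#'
#' Runs nuclei QC on every field, segments both FA channels of included
#' fields independently, and pools all per-adhesion records (images from
#' duplicate wells are passed together and pooled).
#'
#' @param images List of fields; each field is a list with elements
#'   `nuclei` and at least one of `paxillin`, `vinculin`.
#' @param params A [segmentation_params()].
#' @param pixel_size_um Pixel size in micrometres.
#' @param well,condition Identifiers attached to every record.
#' @return List with `records` (AdhesionRecord tibble with `well`,
#'   `condition`, `channel`, `image` columns) and `qc` (per-image tibble).
#' @export
run_well <- function(images, params = segmentation_params(),
                     pixel_size_um = 0.339,
                     well = "well", condition = "DMSO") {
  channels <- c("paxillin", "vinculin")
  qc_list <- vector("list", length(images))
  rec_list <- list()
  for (k in seq_along(images)) {
    field <- images[[k]]
    nuc <- segment_nuclei(field$nuclei)
    qc <- qc_image(nuc$count)
    qc_list[[k]] <- mutate(qc, well = well, condition = condition, image = k)
    if (!qc$included) next
    for (ch in channels) {
      if (is.null(field[[ch]])) {
        warn(sprintf("image %d of well %s has no %s channel; skipped.",
                     k, well, ch))
        next
      }
      labels <- segment_adhesions(field[[ch]], params)
      rec <- measure_adhesions(labels, field[[ch]], pixel_size_um)
      if (nrow(rec)) {
        rec_list[[length(rec_list) + 1L]] <-
          mutate(rec, well = well, condition = condition,
                 channel = ch, image = k)
      }
    }
  }
  records <- if (length(rec_list)) bind_rows(rec_list) else
    mutate(measure_adhesions(matrix(0L, 1, 1), matrix(0, 1, 1)),
           well = character(0), condition = character(0),
           channel = character(0), image = integer(0))
  list(records = records, qc = bind_rows(qc_list))
}
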