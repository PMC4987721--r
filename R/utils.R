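# Internal helpers shared across modules.

# Physical <-> pixel coordinate conversion (pixel-centre convention):
# x_um corresponds to columns, y_um to rows of the image matrix.
px_to_um <- function(px, pixel_size_um) (px - 0.5) * pixel_size_um
um_to_px <- function(um, pixel_size_um) um / pixel_size_um + 0.5

assert_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", what),
          class = "fadyn_config_error")
  }
  invisible(x)
}

assert_image2d <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort(sprintf("`%s` must be a 2-D numeric matrix.", what),
          class = "fadyn_input_error")
  }
  invisible(img)
}

# Additively stamp soft-edged discs (a hard disc of radius `radius_px`
# convolved with a Gaussian PSF of width `blur_px`; the radial profile of
# that convolution is well approximated by pnorm((R - r) / blur), which is
# radially symmetric and therefore centroid-unbiased).
render_spots_disc <- function(nrow, ncol, row, col, amp, radius_px, blur_px) {
  img <- matrix(0, nrow, ncol)
  if (length(row) == 0L) return(img)
  half <- ceiling(radius_px + 4 * blur_px)
  for (k in seq_along(row)) {
    r0 <- row[k]; c0 <- col[k]
    rr <- max(1L, floor(r0 - half)):min(nrow, ceiling(r0 + half))
    cc <- max(1L, floor(c0 - half)):min(ncol, ceiling(c0 + half))
    if (!length(rr) || !length(cc)) next
    dr <- rr - r0
    dc <- cc - c0
    rad <- sqrt(outer(dr^2, dc^2, "+"))
    img[rr, cc] <- img[rr, cc] + amp[k] * pnorm((radius_px - rad) / blur_px)
  }
  img
}

# Additively stamp anisotropic 2-D Gaussian spots. sig_major/sig_minor in
# pixels, theta in radians measured from the +x (column) axis.
render_spots_gauss <- function(nrow, ncol, row, col, amp,
                               sig_major, sig_minor, theta) {
  img <- matrix(0, nrow, ncol)
  if (length(row) == 0L) return(img)
  for (k in seq_along(row)) {
    r0 <- row[k]; c0 <- col[k]
    half <- ceiling(4 * max(sig_major[k], sig_minor[k]))
    rr <- max(1L, floor(r0 - half)):min(nrow, ceiling(r0 + half))
    cc <- max(1L, floor(c0 - half)):min(ncol, ceiling(c0 + half))
    if (!length(rr) || !length(cc)) next
    # rotate (dx, dy) into the spot frame; dy runs along rows
    dy <- matrix(rr - r0, length(rr), length(cc))
    dx <- matrix(cc - c0, length(rr), length(cc), byrow = TRUE)
    u <- cos(theta[k]) * dx + sin(theta[k]) * dy
    v <- -sin(theta[k]) * dx + cos(theta[k]) * dy
    img[rr, cc] <- img[rr, cc] +
      amp[k] * exp(-0.5 * (u^2 / sig_major[k]^2 + v^2 / sig_minor[k]^2))
  }
  img
}

# Camera noise model: the clean image (arbitrary units, peak ~1 for a
# full-intensity spot) is scaled to photons so that the shot-noise SNR at
# unit intensity equals `snr`, Poisson shot noise is applied on top of a
# small constant background, and Gaussian read noise is added. Returned
# image is rescaled back to unit-amplitude scale.
add_camera_noise <- function(img, snr, background = 0.05, read_sd_photons = 2) {
  assert_positive(snr, "snr")
  peak_photons <- snr^2
  lambda <- (pmax(img, 0) + background) * peak_photons
  photons <- matrix(rpois(length(lambda), lambda), nrow(lambda), ncol(lambda))
  photons <- photons + rnorm(length(photons), 0, read_sd_photons)
  photons / peak_photons
}

# Otsu threshold of a numeric vector (maximises between-class variance over
# a 256-bin histogram). Used for per-watershed-region thresholding.
otsu_threshold <- function(v, n_bins = 256L) {
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])
  h <- tabulate(pmin(n_bins, 1L + floor((v - rng[1]) / diff(rng) * n_bins)),
                nbins = n_bins)
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(n_bins))
  mu_t <- mu[n_bins]
  n <- w[n_bins]
  between <- (mu_t * w - mu * n)^2 / (w * (n - w))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  rng[1] + k / n_bins * diff(rng)
}

# Manhattan boundary length per label: number of 4-neighbour pixel faces
# adjacent to a different label or to background.
label_edge_counts <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(integer(0))
  pad <- matrix(0L, nrow(labels) + 2L, ncol(labels) + 2L)
  pad[2:(nrow(labels) + 1L), 2:(ncol(labels) + 1L)] <- labels
  counts <- numeric(max(ids))
  core <- pad[2:(nrow(pad) - 1L), 2:(ncol(pad) - 1L)]
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- pad[2:(nrow(pad) - 1L) + sh[1], 2:(ncol(pad) - 1L) + sh[2]]
    diffm <- core > 0 & nb != core
    t <- tapply(rep(1, sum(diffm)), core[diffm], sum)
    counts[as.integer(names(t))] <- counts[as.integer(names(t))] + t
  }
  counts[ids]
}

# Centroids (row, col) of a labelled mask, as a tibble.
label_centroids <- function(labels) {
  idx <- which(labels > 0)
  if (!length(idx)) {
    return(tibble(label = integer(0), row = numeric(0), col = numeric(0),
                  area_px = integer(0)))
  }
  lab <- labels[idx]
  rr <- (idx - 1L) %% nrow(labels) + 1L
  cc <- (idx - 1L) %/% nrow(labels) + 1L
  tibble(label = lab, row = rr, col = cc) |>
    group_by(.data$label) |>
    summarise(row = mean(.data$row), col = mean(.data$col),
              area_px = n(), .groups = "drop")
}

# Greedy one-to-one matching by ascending cost. `cost` is a matrix
# (rows = sources, cols = targets); entries above `gate` are forbidden.
# Returns an integer vector over rows: matched column or NA.
greedy_match <- function(cost, gate = Inf) {
  match_of <- rep(NA_integer_, nrow(cost))
  if (nrow(cost) == 0L || ncol(cost) == 0L) return(match_of)
  ord <- order(cost)
  used_col <- rep(FALSE, ncol(cost))
  used_row <- rep(FALSE, nrow(cost))
  for (k in ord) {
    if (cost[k] > gate) break
    i <- (k - 1L) %% nrow(cost) + 1L
    j <- (k - 1L) %/% nrow(cost) + 1L
    if (!used_row[i] && !used_col[j]) {
      match_of[i] <- j
      used_row[i] <- TRUE
      used_col[j] <- TRUE
    }
  }
  match_of
}
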