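#' Track nuclei by frame-to-frame mask overlap
#'
#' Each label in frame t+1 is linked to the frame-t label sharing the most
#' pixels (one-to-one, greedy by overlap size; equal overlaps are broken by
#' smaller centroid distance). Labels without any overlapping predecessor
#' start new tracks; a track ends at its first miss (no gap closing), so
#' cells swapping positions without overlap terminate both tracks rather
#' than teleporting.
#'
#' @param masks List of integer label matrices (same shape, ordered frames).
#' @param pixel_size_um Pixel size used for the physical coordinates.
#' @param frame_interval_min Minutes between frames (stored per step).
#' @param stim_frame Last pre-stimulation frame index (phase labelling);
#'   `Inf` labels everything `pre`.
#' @return Tibble with `track`, `frame`, `x_um`, `y_um`, `phase`.
#' @export
track_nuclei <- function(masks, pixel_size_um = 0.64,
                         frame_interval_min = 10, stim_frame = Inf) {
  if (!length(masks)) {
    abort("empty frame list.", class = "fadyn_input_error")
  }
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L) {
    abort("masks must share a common shape.", class = "fadyn_input_error")
  }
  cents <- lapply(masks, label_centroids)
  rows <- list()
  next_track <- 0L
  prev_tracks <- integer(0)  # track id per label of previous frame
  for (f in seq_along(masks)) {
    cen <- cents[[f]]
    n_lab <- if (nrow(cen)) max(cen$label) else 0L
    track_of <- rep(NA_integer_, n_lab)
    if (f > 1L && n_lab > 0L && length(prev_tracks)) {
      a <- masks[[f - 1L]]
      b <- masks[[f]]
      both <- a > 0L & b > 0L
      if (any(both)) {
        ov <- table(prev = a[both], cur = b[both])
        prev_ids <- as.integer(rownames(ov))
        cur_ids <- as.integer(colnames(ov))
        # cost: -overlap, tie-broken by centroid distance
        pc <- cents[[f - 1L]]
        d2 <- outer(seq_along(prev_ids), seq_along(cur_ids),
                    Vectorize(function(i, j) {
                      pi_ <- pc[pc$label == prev_ids[i], ]
                      cj <- cen[cen$label == cur_ids[j], ]
                      (pi_$row - cj$row)^2 + (pi_$col - cj$col)^2
                    }))
        cost <- -as.matrix(ov) + d2 / (max(d2) + 1)  # distance only breaks ties
        cost[as.matrix(ov) == 0] <- Inf
        m <- greedy_match(cost)
        for (i in seq_along(prev_ids)) {
          if (!is.na(m[i]) && prev_ids[i] <= length(prev_tracks) &&
              !is.na(prev_tracks[prev_ids[i]])) {
            track_of[cur_ids[m[i]]] <- prev_tracks[prev_ids[i]]
          }
        }
      }
    }
    new_ids <- which(is.na(track_of))
    if (n_lab > 0L && length(new_ids)) {
      track_of[new_ids] <- next_track + seq_along(new_ids)
      next_track <- next_track + length(new_ids)
    }
    if (nrow(cen)) {
      rows[[f]] <- tibble(track = track_of[cen$label], frame = f,
                          x_um = px_to_um(cen$col, pixel_size_um),
                          y_um = px_to_um(cen$row, pixel_size_um))
    }
    prev_tracks <- track_of
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    return(tibble(track = integer(0), frame = integer(0),
                  x_um = numeric(0), y_um = numeric(0), phase = character(0)))
  }
  out |>
    mutate(phase = ifelse(.data$frame <= stim_frame, "pre", "post")) |>
    arrange(.data$track, .data$frame)
}

#' Per-cell average migration speed
#'
#' Speed is the mean over consecutive frames of the Euclidean position
#' shift divided by the frame interval, computed separately for the pre-
#' and post-stimulation phases. Tracks (or phases) with fewer than
#' `min_steps` steps are omitted.
#'
#' @param tracks Tibble as returned by [track_nuclei()] (columns `track`,
#'   `frame`, `x_um`, `y_um`, `phase`).
#' @param frame_interval_min Minutes per frame; either a single value or a
#'   vector over frames (intervals may vary 10-14 min between movies), in
#'   which case the per-step interval is used.
#' @param min_steps Minimum number of steps per record (default 5).
#' @return Tibble with `track`, `phase`, `mean_speed_um_min`, `n_steps`.
#' @export
compute_cell_speed <- function(tracks, frame_interval_min = 10,
                               min_steps = 5L) {
  tracks <- as_tibble(tracks)
  interval_of <- function(frames) {
    if (length(frames) < 2L) return(numeric(0))
    if (length(frame_interval_min) == 1L) {
      rep(frame_interval_min, length(frames) - 1L)
    } else {
      frame_interval_min[frames[-length(frames)]]
    }
  }
  tracks |>
    arrange(.data$track, .data$frame) |>
    group_by(.data$track, .data$phase) |>
    filter(n() >= min_steps + 1L,
           all(diff(.data$frame) == 1L)) |>
    summarise(mean_speed_um_min = mean(
      sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2) /
        interval_of(.data$frame)),
      n_steps = n() - 1L, .groups = "drop")
}

#' Compare speed populations with Kruskal-Wallis and Dunn's post test
#'
#' Kruskal-Wallis H (with tie correction, via [stats::kruskal.test()])
#' followed by Dunn's pairwise z statistics on the joint ranks, adjusted
#' for multiple comparisons (Bonferroni over all pairs by default,
#' matching common post-test behaviour).
#'
#' @param speeds Tibble with columns `group` and `speed` (or a named list
#'   of numeric vectors).
#' @param p_adjust Adjustment method passed to [stats::p.adjust()].
#' @return A list of class `group_comparison` with `h`, `df`, `p`, and
#'   `pairs` (tibble: `group1`, `group2`, `z`, `p_raw`, `p_adj`).
#' @export
compare_speed_populations <- function(speeds, p_adjust = "bonferroni") {
  if (is.list(speeds) && !is.data.frame(speeds)) {
    speeds <- tibble(group = rep(names(speeds), lengths(speeds)),
                     speed = unlist(speeds, use.names = FALSE))
  }
  speeds <- as_tibble(speeds)
  stopifnot(all(c("group", "speed") %in% names(speeds)))
  groups <- split(speeds$speed, speeds$group)
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    abort("need >= 2 groups with >= 2 values each.",
          class = "fadyn_input_error")
  }
  kw <- kruskal.test(speeds$speed, factor(speeds$group))
  x <- speeds$speed
  g <- speeds$group
  N <- length(x)
  rk <- rank(x)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(rk, g, mean)
  n_g <- tapply(rk, g, length)
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  z <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z[k] <- (mean_rank[[i]] - mean_rank[[j]]) / se
  }
  p_raw <- 2 * pnorm(-abs(z))
  p_adj <- pmin(stats::p.adjust(p_raw, method = p_adjust), 1)
  structure(list(h = unname(kw$statistic), df = unname(kw$parameter),
                 p = kw$p.value,
                 pairs = tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                                z = z, p_raw = p_raw, p_adj = p_adj)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.3f, df = %d, p = %.3g\n",
              x$h, x$df, x$p))
  print(x$pairs)
  invisible(x)
}

# D'Agostino-Pearson K^2 omnibus normality test (skewness and kurtosis
# z-transforms combined; K^2 ~ chi^2 with 2 df under normality).
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 9) abort("need n >= 9.", class = "fadyn_input_error")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  # skewness transform
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transform
  e_g2 <- -6 / (n + 1)
  var_g2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (g2 - e_g2) / sqrt(var_g2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2,
                                               lower.tail = FALSE))
}

#' Consensus normality assessment
#'
#' A sample is called normal only when all three tests fail to reject at
#' `alpha`: Lilliefors-corrected Kolmogorov-Smirnov, D'Agostino-Pearson
#' omnibus, and Shapiro-Wilk. Degenerate (constant) samples are non-normal.
#'
#' @param x Numeric sample, n >= 9.
#' @param alpha Significance level (default 0.05).
#' @return `TRUE` if every test's p-value exceeds `alpha`.
#' @export
assess_normality <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 9) {
    abort("sample too small for the three-test consensus (need n >= 9).",
          class = "fadyn_input_error")
  }
  if (sd(x) == 0) return(FALSE)
  if (length(x) > 5000) x <- x[seq_len(5000)]  # Shapiro-Wilk limit
  p1 <- nortest::lillie.test(x)$p.value
  p2 <- dagostino_pearson(x)$p.value
  p3 <- shapiro.test(x)$p.value
  all(c(p1, p2, p3) > alpha)
}
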