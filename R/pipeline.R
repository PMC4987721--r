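#' Build a run manifest
#'
#' Records tool version, configuration echo, seeds, input file hashes and
#' per-stage record counts so that a rerun with identical inputs can be
#' verified to reproduce identical outputs for deterministic stages.
#'
#' @param config Configuration list echoed into the manifest.
#' @param seed Integer seed used for stochastic stages.
#' @param counts Named list of per-stage record counts.
#' @param input_files Optional character vector of files to hash (MD5).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, counts = list(),
                         input_files = character(0)) {
  hashes <- if (length(input_files)) {
    as.list(tools::md5sum(input_files))
  } else {
    list()
  }
  structure(list(
    tool = "fadyn",
    version = as.character(utils::packageVersion("fadyn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_hashes = hashes,
    counts = counts), class = "run_manifest")
}

#' Write a manifest (and any result tables) as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  m <- unclass(manifest)
  m$timestamp <- NULL  # timestamps would break byte-identical reruns
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the adhesion-size screen end to end
#'
#' Chains the synthetic screen generator (or precomputed per-adhesion
#' records), the per-gene signed KS comparisons and hit classification,
#' and the summary bookkeeping. When `render = TRUE` the per-well images
#' are segmented with [run_well()] and hit calling uses the
#' vinculin-channel records; otherwise the generator's ground-truth areas
#' are used directly.
#'
#' @param layout Plate layout tibble (`well`, `gene`, `is_control`).
#' @param effects Per-gene multiplier tibble (see
#'   [generate_screen_dataset()]).
#' @param thresholds A [hit_thresholds()].
#' @param deselect Genes removed from follow-up.
#' @param seed Integer seed.
#' @param n_images Fields per well.
#' @param base_config Template [fa_image_config()].
#' @param render Segment rendered images instead of using ground truth.
#' @param params A [segmentation_params()] (render mode only).
#' @return List with `calls` (per-gene tibble), `summary`
#'   ([summarize_screen()] result), `records`, `qc` (render mode),
#'   `manifest`.
#' @export
run_screen <- function(layout, effects = NULL,
                       thresholds = hit_thresholds(),
                       deselect = character(0), seed = 1L,
                       n_images = 3L, base_config = fa_image_config(),
                       render = FALSE,
                       params = segmentation_params()) {
  ds <- generate_screen_dataset(layout, effects, seed = seed,
                                n_images = n_images,
                                base_config = base_config, render = render)
  qc <- NULL
  if (render) {
    meta <- dplyr::distinct(ds$truth, .data$well, .data$replicate,
                            .data$gene, .data$is_control, .data$condition)
    rec_list <- vector("list", nrow(meta))
    qc_list <- vector("list", nrow(meta))
    for (k in seq_len(nrow(meta))) {
      keys <- paste(meta$well[k], meta$replicate[k], meta$condition[k],
                    sep = "_")
      imgs <- ds$images[startsWith(names(ds$images), paste0(keys, "_"))]
      rw <- run_well(imgs, params, base_config$pixel_size_um,
                     well = meta$well[k], condition = meta$condition[k])
      if (nrow(rw$records)) {
        rec_list[[k]] <- mutate(rw$records, gene = meta$gene[k],
                                is_control = meta$is_control[k],
                                replicate = meta$replicate[k])
      }
      qc_list[[k]] <- mutate(rw$qc, gene = meta$gene[k],
                             replicate = meta$replicate[k])
    }
    records <- bind_rows(rec_list)
    qc <- bind_rows(qc_list)
    areas <- records |>
      filter(.data$channel == "vinculin") |>
      select("gene", "condition", "area_um2", "is_control")
  } else {
    records <- ds$truth
    areas <- if (nrow(ds$truth)) {
      select(ds$truth, "gene", "condition", "area_um2", "is_control")
    } else {
      tibble(gene = character(0), condition = character(0),
             area_um2 = numeric(0), is_control = logical(0))
    }
  }
  if (!nrow(areas)) {
    empty_calls <- tibble(gene = character(0), category = character(0))
    return(list(calls = empty_calls,
                summary = summarize_screen(empty_calls, deselect),
                records = records, qc = qc,
                truth_categories = ds$categories,
                manifest = run_manifest(list(layout = layout), seed)))
  }
  calls <- score_screen(areas, thresholds)
  summary <- summarize_screen(select(calls, "gene", "category"), deselect)
  manifest <- run_manifest(
    config = list(thresholds = unclass(thresholds),
                  n_images = n_images, render = render,
                  n_wells = nrow(layout)),
    seed = seed,
    counts = list(adhesions = nrow(areas), genes = nrow(calls),
                  total_hits = summary$total_hits))
  list(calls = calls, summary = summary, records = records, qc = qc,
       truth_categories = ds$categories, manifest = manifest)
}

#' Run the traction-force arm end to end
#'
#' For each condition: simulate (or take) a pillar movie, fit the
#' reference grid on pillars outside the cell footprint, compute
#' deflections and forces, track pillars, select the top-deflected
#' cell-coupled set, and summarise forces and autocorrelation half-times.
#' Pairwise half-time comparisons are only made between conditions sharing
#' the frame interval.
#'
#' @param configs Named list of [pillar_sim_config()] objects (one per
#'   condition).
#' @param spec A [pillar_spec()].
#' @param fraction Top-deflection fraction (default 0.05).
#' @param use_rendered If `TRUE`, frames are rendered and pillars detected
#'   with [detect_pillars()]; otherwise the generator's detection table is
#'   used.
#' @return List with `conditions` (per-condition list: `summary`,
#'   `autocorr`, `selection`, `tracks`), `halftime_tests`, `force_tests`,
#'   `manifest`.
#' @export
run_tfm <- function(configs, spec = pillar_spec(), fraction = 0.05,
                    use_rendered = FALSE) {
  stopifnot(length(configs) >= 1, !is.null(names(configs)))
  k <- spec$bending_stiffness_nN_um
  conds <- lapply(configs, function(cfg) {
    mv <- generate_pillar_movie(cfg, render = use_rendered)
    det <- if (use_rendered) {
      bind_rows(lapply(seq_along(mv$frames), function(f) {
        mutate(detect_pillars(mv$frames[[f]],
                              pixel_size_um = cfg$pixel_size_um),
               frame = f)
      }))
    } else {
      mv$detections
    }
    fp <- mv$footprint
    first <- filter(det, .data$frame == min(.data$frame))
    inside1 <- sqrt((first$x_um - fp$center_um[1])^2 +
                      (first$y_um - fp$center_um[2])^2) <= fp$radius_um
    grid <- fit_reference_grid(first, pitch_um = cfg$grid_pitch_um,
                               exclude = inside1)
    tracks <- track_pillars(det) |>
      compute_deflections(grid, k)
    in_cell <- sqrt((tracks$x_um - fp$center_um[1])^2 +
                      (tracks$y_um - fp$center_um[2])^2) <= fp$radius_um
    selection <- select_top_deflected(tracks, in_cell, fraction = fraction)
    sel_tracks <- filter(tracks, .data$track %in%
                           selection$track[selection$selected])
    list(summary = force_timeseries_summary(sel_tracks),
         autocorr = force_autocorrelation(
           sel_tracks, frame_interval_min = cfg$frame_interval_min),
         selection = selection, tracks = tracks, grid = grid,
         frame_interval_min = cfg$frame_interval_min)
  })
  halftime_tests <- list()
  force_tests <- list()
  nm <- names(configs)
  if (length(nm) >= 2) {
    for (a in seq_along(nm)) {
      for (b in seq_along(nm)) {
        if (b <= a) next
        key <- paste(nm[a], nm[b], sep = "_vs_")
        if (conds[[a]]$frame_interval_min != conds[[b]]$frame_interval_min) {
          warn(sprintf(
            "%s: frame intervals differ; half-time comparison refused.", key))
          next
        }
        halftime_tests[[key]] <-
          compare_halftimes(conds[[a]]$autocorr, conds[[b]]$autocorr)
        force_tests[[key]] <- compare_forces(
          conds[[a]]$summary$per_pillar$mean_force_nN,
          conds[[b]]$summary$per_pillar$mean_force_nN)
      }
    }
  }
  manifest <- run_manifest(
    config = list(spec = unclass(spec), fraction = fraction,
                  conditions = lapply(configs, unclass)),
    seed = vapply(configs, function(cfg) cfg$seed, integer(1)),
    counts = lapply(conds, function(cd) nrow(cd$tracks)))
  list(conditions = conds, halftime_tests = halftime_tests,
       force_tests = force_tests, manifest = manifest)
}
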