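#' Signed two-sample Kolmogorov-Smirnov test in the log10 p domain
#'
#' Compares the adhesion-size distribution of a test sample against a
#' reference. The unsigned statistic is the classical two-sample D; its
#' sign is taken from the ECDF difference `F_ref - F_test` at the argmax,
#' so a positive value means the test sample is shifted towards larger
#' values. The p-value is computed from the asymptotic Kolmogorov
#' distribution entirely in the log10 domain, so extreme significance
#' levels (far below double-precision underflow, e.g. 1e-192) remain
#' representable. The score is the KS-test call used in screening: -1, 0 or
#' +1 for a significant decrease, no change, or significant increase.
#'
#' @param test,ref Numeric samples (non-empty).
#' @param alpha Significance level for the score (default 0.05).
#' @return A list of class `fadyn_ks` with `signed_d`, `log10_p`, `score`,
#'   `n_test`, `n_ref`.
#' @export
signed_ks_test <- function(test, ref, alpha = 0.05) {
  test <- test[is.finite(test)]
  ref <- ref[is.finite(ref)]
  if (!length(test) || !length(ref)) {
    abort("both samples must be non-empty.", class = "fadyn_input_error")
  }
  pts <- sort(unique(c(test, ref)))
  diff_ecdf <- ecdf(ref)(pts) - ecdf(test)(pts)  # right-continuous ECDFs
  k <- which.max(abs(diff_ecdf))
  signed_d <- diff_ecdf[k]
  d <- abs(signed_d)
  n1 <- length(test)
  n2 <- length(ref)
  n_eff <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * d
  log10_p <- kolmogorov_log10_sf(lambda)
  score <- if (log10_p < log10(alpha)) sign(signed_d) else 0
  structure(list(signed_d = signed_d, log10_p = log10_p,
                 score = as.integer(score),
                 n_test = n1, n_ref = n2, alpha = alpha),
            class = "fadyn_ks")
}

# log10 of the Kolmogorov distribution survival function
# Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2).
# For small lambda the complementary (Jacobi-transformed) series is used;
# for large lambda the alternating series is evaluated in the log domain so
# that values like 1e-192 do not underflow.
kolmogorov_log10_sf <- function(lambda) {
  if (lambda <= 0) return(0)
  if (lambda < 1.18) {
    # P(K <= lambda) via the theta-function form, accurate near p = 1
    t <- exp(-pi^2 / (8 * lambda^2))
    cdf <- sqrt(2 * pi) / lambda * (t + t^9 + t^25)
    return(log10(max(1 - cdf, .Machine$double.xmin)))
  }
  # log Q = log(2) - 2 lambda^2 + log(1 - e^{-6 lambda^2} + e^{-16 lambda^2})
  l2 <- lambda^2
  corr <- 1 - exp(-6 * l2) + exp(-16 * l2) - exp(-30 * l2)
  (log(2) - 2 * l2 + log(corr)) / log(10)
}

#' @export
print.fadyn_ks <- function(x, ...) {
  cat(sprintf(
    "Signed two-sample KS: D = %+.4f, log10(p) = %.2f, score = %+d (n = %d vs %d)\n",
    x$signed_d, x$log10_p, x$score, x$n_test, x$n_ref))
  invisible(x)
}

#' Hit-calling thresholds for the adhesion-size screen
#'
#' Size-increase hits require a signed D above `d_increase` with
#' `log10(p)` below `log10p_increase` (defaults D > 0.1, p < 1e-40);
#' size-decrease hits require signed D below `d_decrease` with p below
#' `10^log10p_decrease` (defaults D < -0.075, p < 1e-25). The "no change"
#' band used for assembly-/disassembly-blocked calls is |D| < `d_nochange`
#' or `log10(p)` above `log10p_nochange` (defaults 0.05 and -10); the
#' original study applied this call by visual inspection, so the band is an
#' explicit, configurable stand-in.
#'
#' @param d_increase,log10p_increase Increase-hit thresholds.
#' @param d_decrease,log10p_decrease Decrease-hit thresholds.
#' @param d_nochange,log10p_nochange "No change" band.
#' @param alpha_score Score significance level.
#' @return A list of class `hit_thresholds`.
#' @export
hit_thresholds <- function(d_increase = 0.1, log10p_increase = -40,
                           d_decrease = -0.075, log10p_decrease = -25,
                           d_nochange = 0.05, log10p_nochange = -10,
                           alpha_score = 0.05) {
  if (!(d_increase > 0 && 0 > d_decrease)) {
    abort("need d_increase > 0 > d_decrease.", class = "fadyn_config_error")
  }
  structure(list(d_increase = d_increase, log10p_increase = log10p_increase,
                 d_decrease = d_decrease, log10p_decrease = log10p_decrease,
                 d_nochange = d_nochange, log10p_nochange = log10p_nochange,
                 alpha_score = alpha_score),
            class = "hit_thresholds")
}

ks_is_nochange <- function(ks, thr) {
  abs(ks$signed_d) < thr$d_nochange || ks$log10_p > thr$log10p_nochange
}

#' Classify a gene from its three condition comparisons
#'
#' Categories are evaluated in priority order on the three signed KS
#' results: `increase`/`decrease` from the baseline-vs-control comparison;
#' otherwise `assembly_blocked` when the drug condition shows no change
#' against the gene's own baseline; otherwise `disassembly_blocked` when
#' the drug condition shows a significant increase but washout shows no
#' change against the drug condition; otherwise `none`.
#'
#' @param ks_dmso_vs_control,ks_noco_vs_dmso,ks_washout_vs_noco
#'   [signed_ks_test()] results for the three comparisons.
#' @param thresholds A [hit_thresholds()].
#' @return Category string.
#' @export
classify_gene <- function(ks_dmso_vs_control, ks_noco_vs_dmso,
                          ks_washout_vs_noco,
                          thresholds = hit_thresholds()) {
  for (ks in list(ks_dmso_vs_control, ks_noco_vs_dmso, ks_washout_vs_noco)) {
    if (is.null(ks) || !all(c("signed_d", "log10_p") %in% names(ks))) {
      abort("all three comparisons must carry `signed_d` and `log10_p`.",
            class = "fadyn_input_error")
    }
  }
  thr <- thresholds
  a <- ks_dmso_vs_control
  b <- ks_noco_vs_dmso
  c_ <- ks_washout_vs_noco
  if (a$signed_d > thr$d_increase && a$log10_p < thr$log10p_increase) {
    return("increase")
  }
  if (a$signed_d < thr$d_decrease && a$log10_p < thr$log10p_decrease) {
    return("decrease")
  }
  if (ks_is_nochange(b, thr)) return("assembly_blocked")
  if (b$signed_d > 0 && b$log10_p < log10(thr$alpha_score) &&
      ks_is_nochange(c_, thr)) {
    return("disassembly_blocked")
  }
  "none"
}

#' Score a whole screen of per-gene area distributions
#'
#' Runs the three condition comparisons for every gene and classifies it.
#' Adhesion-size samples of each gene's drug and washout conditions are
#' compared against the gene's own baseline/drug condition; the baseline is
#' compared against the pooled control-gene baseline.
#'
#' @param areas Tibble with columns `gene`, `condition`
#'   (`DMSO`/`nocodazole`/`washout`), `area_um2` and logical `is_control`.
#' @param thresholds A [hit_thresholds()].
#' @return Tibble with one row per non-control gene: three comparisons'
#'   `signed_d`/`log10_p`/`score` and `category`.
#' @export
score_screen <- function(areas, thresholds = hit_thresholds()) {
  areas <- as_tibble(areas)
  stopifnot(all(c("gene", "condition", "area_um2", "is_control")
                %in% names(areas)))
  ctrl <- areas$area_um2[areas$is_control & areas$condition == "DMSO"]
  genes <- unique(areas$gene[!areas$is_control])
  purrr::map_dfr(genes, function(g) {
    gd <- areas[areas$gene == g, ]
    sam <- split(gd$area_um2, gd$condition)
    need <- c("DMSO", "nocodazole", "washout")
    if (!all(need %in% names(sam)) || !length(ctrl)) {
      warn(sprintf("gene %s is missing a condition; skipped.", g))
      return(NULL)
    }
    k1 <- signed_ks_test(sam$DMSO, ctrl, thresholds$alpha_score)
    k2 <- signed_ks_test(sam$nocodazole, sam$DMSO, thresholds$alpha_score)
    k3 <- signed_ks_test(sam$washout, sam$nocodazole, thresholds$alpha_score)
    tibble(gene = g,
           d_dmso = k1$signed_d, log10p_dmso = k1$log10_p, score_dmso = k1$score,
           d_noco = k2$signed_d, log10p_noco = k2$log10_p, score_noco = k2$score,
           d_washout = k3$signed_d, log10p_washout = k3$log10_p,
           score_washout = k3$score,
           category = classify_gene(k1, k2, k3, thresholds))
  })
}

#' Summarise hit calls into category counts and a total
#'
#' Deselected genes (e.g. extensively studied genes removed from follow-up)
#' are flagged and removed from the `increase`/`decrease` totals; the grand
#' total is `increase + decrease - deselected_among_those +
#' assembly_blocked + disassembly_blocked`.
#'
#' @param calls Tibble with columns `gene` and `category`.
#' @param deselect Character vector of genes to deselect.
#' @return A list of class `screen_summary` with `counts` (tibble),
#'   `deselected`, `total_hits`.
#' @export
summarize_screen <- function(calls, deselect = character(0)) {
  calls <- as_tibble(calls)
  if (anyDuplicated(calls$gene)) {
    abort("gene ids must be unique.", class = "fadyn_input_error")
  }
  unknown <- setdiff(deselect, calls$gene)
  if (length(unknown)) {
    warn(sprintf("deselect genes not in calls: %s",
                 paste(unknown, collapse = ", ")))
  }
  cats <- c("increase", "decrease", "assembly_blocked",
            "disassembly_blocked", "none")
  counts <- tibble(category = cats,
                   n = vapply(cats, function(ct)
                     sum(calls$category == ct), integer(1),
                     USE.NAMES = FALSE))
  desel_hits <- sum(calls$gene %in% deselect &
                      calls$category %in% c("increase", "decrease"))
  total <- counts$n[counts$category == "increase"] +
    counts$n[counts$category == "decrease"] - desel_hits +
    counts$n[counts$category == "assembly_blocked"] +
    counts$n[counts$category == "disassembly_blocked"]
  structure(list(counts = counts,
                 deselected = intersect(deselect, calls$gene),
                 total_hits = as.integer(total)),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("Screen summary\n")
  for (k in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-20s %d\n", x$counts$category[k], x$counts$n[k]))
  }
  if (length(x$deselected)) {
    cat("  deselected:", paste(x$deselected, collapse = ", "), "\n")
  }
  cat(sprintf("  total hits: %d\n", x$total_hits))
  invisible(x)
}
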