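#' Tidy a signed KS result
#'
#' @param x A [signed_ks_test()] result.
#' @param ... Unused.
#' @return One-row tibble with `signed_d`, `log10_p`, `score`, `n_test`,
#'   `n_ref`.
#' @method tidy fadyn_ks
#' @export
tidy.fadyn_ks <- function(x, ...) {
  tibble(signed_d = x$signed_d, log10_p = x$log10_p, score = x$score,
         n_test = x$n_test, n_ref = x$n_ref)
}

#' Tidy a screen summary into category counts
#'
#' @param x A [summarize_screen()] result.
#' @param ... Unused.
#' @return Tibble of category counts.
#' @method tidy screen_summary
#' @export
tidy.screen_summary <- function(x, ...) x$counts

#' One-row overview of a screen summary
#'
#' @param x A [summarize_screen()] result.
#' @param ... Unused.
#' @return One-row tibble with `total_hits` and `n_deselected`.
#' @method glance screen_summary
#' @export
glance.screen_summary <- function(x, ...) {
  tibble(total_hits = x$total_hits, n_deselected = length(x$deselected))
}

#' Tidy an autocorrelation fit into its curve
#'
#' @param x A [force_autocorrelation()] result.
#' @param ... Unused.
#' @return Tibble with `lag_min`, `autocorr`, `fitted`.
#' @method tidy autocorr_fit
#' @export
tidy.autocorr_fit <- function(x, ...) {
  tibble(lag_min = x$lags_min, autocorr = x$mean_autocorr,
         fitted = x$amplitude * exp(-x$lambda_per_min * x$lags_min))
}

#' One-row overview of an autocorrelation fit
#'
#' @param x A [force_autocorrelation()] result.
#' @param ... Unused.
#' @return One-row tibble with `amplitude`, `lambda_per_min`,
#'   `halftime_min`, `sse`, `n_pillars`.
#' @method glance autocorr_fit
#' @export
glance.autocorr_fit <- function(x, ...) {
  tibble(amplitude = x$amplitude, lambda_per_min = x$lambda_per_min,
         halftime_min = x$halftime_min, sse = x$sse,
         n_pillars = x$n_pillars)
}

#' Tidy the pairwise table of a group comparison
#'
#' @param x A [compare_speed_populations()] result.
#' @param ... Unused.
#' @return Tibble of Dunn pairwise comparisons.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$pairs

#' One-row overview of a group comparison
#'
#' @param x A [compare_speed_populations()] result.
#' @param ... Unused.
#' @return One-row tibble with the Kruskal-Wallis `h`, `df`, `p`.
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(h = x$h, df = x$df, p = x$p)
}

#' Tidy a half-time F-test
#'
#' @param x A [compare_halftimes()] result.
#' @param ... Unused.
#' @return One-row tibble with `f`, `df1`, `df2`, `p` and both half-times.
#' @method tidy halftime_ftest
#' @export
tidy.halftime_ftest <- function(x, ...) {
  tibble(f = x$f, df1 = x$df1, df2 = x$df2, p = x$p,
         halftime1_min = x$halftime1_min, halftime2_min = x$halftime2_min)
}
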