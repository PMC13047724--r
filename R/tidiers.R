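# broom-style tidiers for fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a repeated-evaluation result
#'
#' @param x A `sers_eval` from [evaluate_multirun()].
#' @param ... Unused.
#' @return Per-run metrics tibble (`run`, `seed`, `accuracy`, macro
#'   precision/recall/F1).
#' @method tidy sers_eval
#' @export
tidy.sers_eval <- function(x, ...) x$runs

#' @rdname tidy.sers_eval
#' @return For `glance()`: a one-row summary (`mean_accuracy`, `sd_accuracy`,
#'   `n_runs`, macro metrics).
#' @method glance sers_eval
#' @export
glance.sers_eval <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd_accuracy,
                 n_runs = nrow(x$runs),
                 macro_precision = mean(x$per_class$precision),
                 macro_recall = mean(x$per_class$recall),
                 macro_f1 = mean(x$per_class$f1))
}

#' Tidy an accuracy-vs-N curve
#'
#' @param x An `accuracy_curve` from [accuracy_vs_n()].
#' @param ... Unused.
#' @return The per-`n_events` curve tibble; `glance()` gives a one-row
#'   summary with the threshold-crossing N.
#' @method tidy accuracy_curve
#' @export
tidy.accuracy_curve <- function(x, ...) x$curve

#' @rdname tidy.accuracy_curve
#' @method glance accuracy_curve
#' @export
glance.accuracy_curve <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, n_at_threshold = x$n_at_threshold,
                 max_accuracy = max(x$curve$mean_accuracy))
}

#' Tidy a ratio histogram
#'
#' @param x A `ratio_histogram`.
#' @param ... Unused.
#' @return The bins tibble; `glance()` gives the mode and run counts.
#' @method tidy ratio_histogram
#' @export
tidy.ratio_histogram <- function(x, ...) x$bins

#' @rdname tidy.ratio_histogram
#' @method glance ratio_histogram
#' @export
glance.ratio_histogram <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_included = x$n_included,
                 n_excluded = x$n_excluded,
                 ratio_mean = mean(x$ratios), ratio_sd = stats::sd(x$ratios))
}

#' Tidy photon statistics
#'
#' @param x A `photon_stats` from [photon_statistics()].
#' @param ... Unused.
#' @return The histogram tibble; `glance()` gives the summary row.
#' @method tidy photon_stats
#' @export
tidy.photon_stats <- function(x, ...) x$histogram

#' @rdname tidy.photon_stats
#' @method glance photon_stats
#' @export
glance.photon_stats <- function(x, ...) {
  tibble::tibble(n = x$n, mean = x$mean, median = x$median, sd = x$sd)
}
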