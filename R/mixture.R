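# Mixture-composition estimation by misclassification redistribution.
#
# Three classes are trained (pure OT, pure VP, and the mixture as its own
# class MIX). Mixture-labelled TEST spectra that the classifier redistributes
# into the pure classes carry the composition signal: across many random
# splits, the most frequently recurring VP:OT redistribution ratio estimates
# the true concentration ratio, with run-to-run fluctuation referenced to a
# hypergeometric (sampling-without-replacement) model.

#' One run of the three-class mixture protocol
#'
#' Combines pure-OT, pure-VP and mixture spectrum tables into a three-class
#' dataset (labels `OT`, `VP`, `MIX`), performs one stratified 70/30 split at
#' `seed`, fits the transform/PCA/forest pipeline on the training fold of all
#' three classes, and tallies the mixture-labelled test spectra by predicted
#' class. The ratio uses the two redistributed counts only; a run with
#' `m_ot = 0` has an undefined ratio and is flagged excluded.
#'
#' @param pure_ot,pure_vp,mixture Spectrum tables; labels are overwritten
#'   with `OT`, `VP` and `MIX` respectively.
#' @param cfg A [protocol_config()].
#' @param seed Integer seed for this run's split and forest.
#' @return One-row tibble: `seed`, `m_ot`, `m_vp`, `m_mix`, `n_mix_test`,
#'   `ratio` (`m_vp / m_ot`, NA when undefined), `excluded`.
#' @export
run_mixture_protocol <- function(pure_ot, pure_vp, mixture,
                                 cfg = protocol_config(), seed = 1) {
  feat <- Reduce(intersect, list(spectrum_channels(pure_ot),
                                 spectrum_channels(pure_vp),
                                 spectrum_channels(mixture)))
  if (length(feat) == 0) stop("no common channel columns", call. = FALSE)
  x <- rbind(as.matrix(pure_ot[feat]), as.matrix(pure_vp[feat]),
             as.matrix(mixture[feat]))
  labels <- c(rep("OT", nrow(pure_ot)), rep("VP", nrow(pure_vp)),
              rep("MIX", nrow(mixture)))
  tr <- withr::with_seed(seed, .stratified_split(labels, cfg$train_fraction))
  te <- setdiff(seq_along(labels), tr)
  fit <- .fit_pipeline(x[tr, , drop = FALSE], labels[tr], cfg, seed = seed)
  pred <- .predict_pipeline(fit, x[te, , drop = FALSE])
  mix_te <- labels[te] == "MIX"
  m_ot <- sum(pred[mix_te] == "OT")
  m_vp <- sum(pred[mix_te] == "VP")
  m_mix <- sum(pred[mix_te] == "MIX")
  tibble::tibble(seed = seed, m_ot = m_ot, m_vp = m_vp, m_mix = m_mix,
                 n_mix_test = sum(mix_te),
                 ratio = if (m_ot > 0) m_vp / m_ot else NA_real_,
                 excluded = m_ot == 0)
}

#' Repeat the mixture protocol over many seeds
#'
#' @inheritParams run_mixture_protocol
#' @param seeds Integer vector of run seeds (default `1:300`).
#' @return Tibble with one [run_mixture_protocol()] row per seed.
#' @export
mixture_ratio_runs <- function(pure_ot, pure_vp, mixture,
                               cfg = protocol_config(), seeds = 1:300) {
  purrr::map_dfr(seeds, function(s)
    run_mixture_protocol(pure_ot, pure_vp, mixture, cfg, seed = s))
}

# Bin edges: linear bins of width `bin_width` up to ~`linear_max`, then
# logarithmic bins of constant log-width `bin_width` above. Linear bins are
# centered on multiples of `bin_width` (edges at half-widths), so simple
# composition ratios (1, 2, ...) are representable as bin centers; a narrow
# first bin [0, bin_width/2] closes the range at zero.
.ratio_bin_edges <- function(max_ratio, bin_width = 0.2, linear_max = 3) {
  edges <- c(0, seq(bin_width / 2, linear_max + bin_width / 2, by = bin_width))
  top <- edges[length(edges)]
  while (top <= max_ratio) {
    top <- top * exp(bin_width)
    edges <- c(edges, top)
  }
  edges
}

#' Histogram of redistribution ratios
#'
#' Bins the defined VP:OT ratios across runs. Bins are linear (width
#' `bin_width`) up to `linear_max` and logarithmic (constant relative width)
#' above, so small and large concentration ratios resolve comparably. The
#' histogram mode — the center of the maximal bin, ties broken toward the
#' bin nearest the median ratio — is the composition estimate.
#'
#' @param runs A tibble from [mixture_ratio_runs()] (uses its `ratio` and
#'   `excluded` columns) or a bare numeric vector of ratios.
#' @param bin_width Linear bin width / logarithmic bin log-width.
#' @param linear_max Ratio at which binning switches to logarithmic.
#' @param min_runs Minimum number of included (defined-ratio) runs.
#' @return Object of class `ratio_histogram`: `bins` tibble (`lower`,
#'   `upper`, `center`, `count`), `mode`, `n_included`, `n_excluded`,
#'   `ratios`, `bin_width`, `linear_max`.
#' @export
ratio_histogram <- function(runs, bin_width = 0.2, linear_max = 3,
                            min_runs = 30) {
  ratios <- if (is.data.frame(runs)) runs$ratio else as.numeric(runs)
  n_excluded <- sum(!is.finite(ratios))
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) == 0)
    stop("estimation failure: all runs have undefined ratios", call. = FALSE)
  if (length(ratios) < min_runs)
    stop("need at least ", min_runs, " included runs (got ", length(ratios),
         ")", call. = FALSE)
  edges <- .ratio_bin_edges(max(ratios), bin_width, linear_max)
  idx <- findInterval(ratios, edges, left.open = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  lower <- utils::head(edges, -1); upper <- edges[-1]
  center <- ifelse(lower >= linear_max + bin_width / 2 - 1e-12,
                   sqrt(lower * upper),       # geometric center (log bins)
                   (lower + upper) / 2)       # arithmetic center (linear bins)
  maximal <- which(counts == max(counts))
  if (length(maximal) > 1) {                  # tie: bin nearest median ratio
    med <- stats::median(ratios)
    maximal <- maximal[which.min(abs(center[maximal] - med))]
  }
  structure(
    list(bins = tibble::tibble(lower = lower, upper = upper, center = center,
                               count = counts),
         mode = center[maximal], n_included = length(ratios),
         n_excluded = n_excluded, ratios = ratios,
         bin_width = bin_width, linear_max = linear_max),
    class = "ratio_histogram")
}

#' @export
print.ratio_histogram <- function(x, ...) {
  cat(sprintf("<ratio_histogram> %d runs (%d excluded): mode VP:OT = %.3g\n",
              x$n_included, x$n_excluded, x$mode))
  invisible(x)
}

#' Exact hypergeometric distribution of the redistribution ratio
#'
#' Reference model for the run-to-run histogram spread: drawing `draw` items
#' without replacement from a pool of `pool_a` type-A and `pool_b` type-B
#' items, the type-A count `k` is hypergeometric and induces the ratio
#' `r = (draw - k) / k` (type-B over type-A). Exact enumeration over all
#' achievable `k`.
#'
#' @param pool_a,pool_b Pool sizes (non-negative integers).
#' @param draw Number drawn (<= `pool_a + pool_b`).
#' @return Tibble with `k`, `ratio` (`Inf` at `k = 0`), `prob`.
#' @export
#' @examples
#' hypergeometric_ratio_pmf(2, 3, 2)
hypergeometric_ratio_pmf <- function(pool_a, pool_b, draw) {
  stopifnot(pool_a >= 0, pool_b >= 0, draw >= 0, draw <= pool_a + pool_b)
  k <- max(0, draw - pool_b):min(draw, pool_a)
  tibble::tibble(k = k,
                 ratio = ifelse(k > 0, (draw - k) / k, Inf),
                 prob = stats::dhyper(k, pool_a, pool_b, draw))
}

#' Estimate mixture composition from the ratio histogram
#'
#' Converts the histogram mode `m` (VP:OT) into class fractions
#' `(1/(1+m), m/(1+m))`; given a spiked reference concentration for the OT
#' class, absolute concentrations follow by scaling.
#'
#' @param hist A `ratio_histogram`.
#' @param spike_concentration Optional known concentration of the OT (spike)
#'   component; units propagate to the `concentration` column.
#' @param classes Names for the two components (default `c("OT", "VP")`).
#' @return Tibble with `class`, `fraction` and (if a spike is given)
#'   `concentration`.
#' @export
estimate_composition <- function(hist, spike_concentration = NULL,
                                 classes = c("OT", "VP")) {
  stopifnot(inherits(hist, "ratio_histogram"), length(classes) == 2)
  m <- hist$mode
  if (!is.finite(m)) stop("estimation failure: undefined mode", call. = FALSE)
  out <- tibble::tibble(class = classes,
                        fraction = c(1 / (1 + m), m / (1 + m)))
  if (!is.null(spike_concentration)) {
    # spike = known concentration of the first (OT) component
    out$concentration <- spike_concentration * out$fraction / out$fraction[1]
  }
  out
}
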