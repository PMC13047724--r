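# Translocation-event detection and single-event spectrum extraction.
#
# The photon time trace is the per-frame sum across kept channels; slow
# background is removed by subtracting each fixed-length segment's median;
# events are maximal runs above a robust-scale threshold; spectra are summed
# from the UNsmoothed integer counts over each detected interval.

#' Detection configuration
#'
#' @param segment_len Segment length (frames) for the local median baseline;
#'   default 1000 frames (0.1 s), long enough that a handful of event frames
#'   cannot bias a median yet short against the background drift period.
#' @param threshold_k Threshold in multiples of the robust scale
#'   (1.4826 x MAD) of the corrected trace; default 5.
#' @param min_gap Intervals separated by at most this many sub-threshold
#'   frames are merged (default 1).
#' @return A validated list of class `detection_config`.
#' @export
detection_config <- function(segment_len = 1000, threshold_k = 5, min_gap = 1) {
  stopifnot(segment_len >= 2, threshold_k > 0, min_gap >= 0)
  structure(list(segment_len = as.integer(segment_len),
                 threshold_k = threshold_k, min_gap = as.integer(min_gap)),
            class = "detection_config")
}

#' Build the photon time trace
#'
#' Sums photon counts across all kept spectral channels for each frame.
#'
#' @param stream A `clean_stream` (typically Wiener-smoothed for detection).
#' @return A tibble of class `time_trace` with columns `frame` and `photons`;
#'   the frame duration is carried in the `frame_dt` attribute.
#' @export
#' @examples
#' sim <- generate_frame_stream(generator_config(n_frames = 1000, seed = 1))
#' tr <- sim$stream |> remove_bad_pixels() |> build_time_trace()
#' head(tr)
build_time_trace <- function(stream) {
  stopifnot(inherits(stream, "clean_stream"))
  out <- tibble::tibble(frame = seq_len(nrow(stream$counts)),
                        photons = rowSums(stream$counts))
  attr(out, "frame_dt") <- stream$frame_dt
  class(out) <- c("time_trace", class(out))
  out
}

#' Subtract a segmented median baseline
#'
#' Divides the trace into consecutive non-overlapping segments of
#' `segment_len` frames (a final partial segment is its own segment) and
#' subtracts each segment's median, compensating slow background drift while
#' leaving sparse event spikes nearly untouched (median robustness). A
#' `segment_len` longer than the trace falls back to a single whole-trace
#' segment.
#'
#' @param trace A `time_trace` from [build_time_trace()].
#' @param segment_len Segment length in frames (>= 2).
#' @return The trace tibble with added columns `baseline` and `corrected`.
#' @export
subtract_segmented_baseline <- function(trace, segment_len = 1000) {
  stopifnot(inherits(trace, "time_trace"), segment_len >= 2)
  # consecutive fixed-length segments; a final partial segment stands alone,
  # and segment_len > length(trace) degenerates to a whole-trace median
  seg <- (trace$frame - 1L) %/% as.integer(segment_len) + 1L
  baseline <- stats::ave(trace$photons, seg, FUN = stats::median)
  out <- dplyr::mutate(trace, baseline = baseline,
                       corrected = .data$photons - baseline)
  attr(out, "frame_dt") <- attr(trace, "frame_dt")
  class(out) <- unique(c("time_trace", class(out)))
  out
}

.merge_intervals <- function(start, end, min_gap) {
  if (length(start) <= 1)
    return(list(start = start, end = end))
  ms <- start[1]; me <- end[1]
  out_s <- integer(); out_e <- integer()
  for (i in 2:length(start)) {
    if (start[i] - me - 1L <= min_gap) {
      me <- end[i]
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Detect translocation events by robust thresholding
#'
#' Applies a threshold `theta = threshold_k * 1.4826 * MAD(corrected)` to the
#' baseline-corrected trace; maximal runs of frames strictly above `theta`
#' become candidate intervals, and intervals separated by at most `min_gap`
#' sub-threshold frames are merged. A constant trace (zero robust scale)
#' yields no events with a warning.
#'
#' @param trace A `time_trace`; the `corrected` column is used if present,
#'   otherwise `photons`.
#' @param config A [detection_config()].
#' @param threshold Optional explicit threshold overriding the robust-scale
#'   rule (useful for testing and diagnostics).
#' @return Tibble with columns `event_id`, `start_frame`, `end_frame`; the
#'   threshold used is attached as the `threshold` attribute.
#' @export
detect_events <- function(trace, config = detection_config(),
                          threshold = NULL) {
  stopifnot(inherits(trace, "time_trace"), inherits(config, "detection_config"))
  x <- if ("corrected" %in% names(trace)) trace$corrected else trace$photons
  if (is.null(threshold)) {
    s <- stats::mad(x)  # 1.4826 * median absolute deviation
    if (s == 0) {
      warning("robust scale of the trace is zero; no events detected",
              call. = FALSE)
      out <- tibble::tibble(event_id = character(), start_frame = integer(),
                            end_frame = integer())
      attr(out, "threshold") <- NA_real_
      return(out)
    }
    threshold <- config$threshold_k * s
  }
  above <- x > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values
  iv <- .merge_intervals(starts[sel], ends[sel], config$min_gap)
  out <- tibble::tibble(
    event_id = if (length(iv$start)) sprintf("det%05d", seq_along(iv$start)) else character(),
    start_frame = as.integer(iv$start), end_frame = as.integer(iv$end))
  attr(out, "threshold") <- threshold
  out
}

#' Extract single-event spectra from the raw stream
#'
#' For each detected interval, sums the *unsmoothed* integer photon counts of
#' the raw stream (restricted to kept channels) over the event duration,
#' yielding one single-molecule SERS spectrum per event. Keeping the raw
#' counts preserves the Poisson photon statistics that smoothing would
#' distort.
#'
#' @param stream The raw `frame_stream`.
#' @param events Tibble of intervals with `start_frame`, `end_frame` (and
#'   optionally `event_id`, `label`).
#' @param bad Channels to drop before summation; defaults to the stream's
#'   declared bad pixels.
#' @return A spectrum-table tibble: `event_id`, `label`, `start_frame`,
#'   `end_frame`, `total_photons`, then `c0..c{K-1}` kept-channel counts.
#' @export
extract_events <- function(stream, events, bad = stream$bad_pixels) {
  stopifnot(inherits(stream, "frame_stream"), is.data.frame(events))
  n <- nrow(stream$counts)
  if (nrow(events) > 0 &&
      (any(events$start_frame < 1) || any(events$end_frame > n) ||
       any(events$start_frame > events$end_frame)))
    stop("event intervals out of stream bounds", call. = FALSE)
  kept <- setdiff(seq_len(ncol(stream$counts)), as.integer(bad))
  k <- length(kept)
  spec <- matrix(0L, nrow = nrow(events), ncol = k)
  for (i in seq_len(nrow(events))) {
    rows <- events$start_frame[i]:events$end_frame[i]
    spec[i, ] <- as.integer(colSums(stream$counts[rows, kept, drop = FALSE]))
  }
  out <- tibble::tibble(
    event_id = if ("event_id" %in% names(events) && nrow(events) > 0)
      events$event_id else sprintf("det%05d", seq_len(nrow(events))),
    label = if ("label" %in% names(events)) events$label else NA_character_,
    start_frame = as.integer(events$start_frame),
    end_frame = as.integer(events$end_frame),
    total_photons = as.integer(rowSums(spec)))
  mat <- tibble::as_tibble(as.data.frame(spec), .name_repair = "minimal")
  names(mat) <- sprintf("c%d", seq_len(k) - 1L)
  dplyr::bind_cols(out, mat)
}

#' Run the full detection chain on a raw stream
#'
#' Convenience wrapper: bad-pixel removal, Wiener smoothing, time trace,
#' segmented median baseline, robust thresholding, and raw-count spectrum
#' extraction.
#'
#' @param stream A raw `frame_stream`.
#' @param config A [detection_config()].
#' @param window Wiener window (channels) used for the detection trace.
#' @return List with `trace` (corrected time trace), `intervals` (detected
#'   intervals) and `spectra` (extracted spectrum table).
#' @export
#' @examples
#' sim <- generate_frame_stream(generator_config(n_frames = 20000, seed = 1))
#' det <- run_event_detection(sim$stream)
#' nrow(det$spectra)
run_event_detection <- function(stream, config = detection_config(),
                                window = 5) {
  trace <- stream |>
    remove_bad_pixels() |>
    wiener_smooth(window = window) |>
    build_time_trace() |>
    subtract_segmented_baseline(segment_len = config$segment_len)
  intervals <- detect_events(trace, config)
  spectra <- extract_events(stream, intervals)
  list(trace = trace, intervals = intervals, spectra = spectra)
}

#' Match detected intervals against ground truth
#'
#' Greedy one-to-one interval matching by start frame: a detection matches a
#' ground-truth event if their frame intervals overlap and neither is already
#' matched. Returns detection precision, recall and F1.
#'
#' @param detected,truth Tibbles with `start_frame`, `end_frame`.
#' @return One-row tibble: `n_detected`, `n_truth`, `n_matched`, `precision`,
#'   `recall`, `f1`.
#' @export
match_events <- function(detected, truth) {
  nd <- nrow(detected); nt <- nrow(truth)
  matched <- 0L
  if (nd > 0 && nt > 0) {
    truth <- truth[order(truth$start_frame), ]
    detected <- detected[order(detected$start_frame), ]
    used <- rep(FALSE, nt)
    for (i in seq_len(nd)) {
      hit <- which(!used & truth$start_frame <= detected$end_frame[i] &
                     truth$end_frame >= detected$start_frame[i])
      if (length(hit)) { used[hit[1]] <- TRUE; matched <- matched + 1L }
    }
  }
  precision <- if (nd > 0) matched / nd else NA_real_
  recall <- if (nt > 0) matched / nt else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  tibble::tibble(n_detected = nd, n_truth = nt, n_matched = matched,
                 precision = precision, recall = recall, f1 = f1)
}

#' Photon statistics of detected events
#'
#' Summaries of the total-photon distribution across events (the
#' photons-per-event histogram of the experiment).
#'
#' @param spectra A spectrum table with a `total_photons` column.
#' @param bin_width Histogram bin width in photons (default 10).
#' @return List of class `photon_stats`: `n`, `mean`, `median`, `sd`, and a
#'   `histogram` tibble (`lower`, `upper`, `center`, `count`).
#' @export
photon_statistics <- function(spectra, bin_width = 10) {
  if (!is.data.frame(spectra) || nrow(spectra) == 0)
    stop("`spectra` must contain at least one event", call. = FALSE)
  x <- spectra$total_photons
  breaks <- seq(0, max(x) + bin_width, by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  structure(
    list(n = length(x), mean = mean(x), median = stats::median(x),
         sd = stats::sd(x),
         histogram = tibble::tibble(lower = utils::head(h$breaks, -1),
                                    upper = h$breaks[-1], center = h$mids,
                                    count = h$counts)),
    class = "photon_stats")
}

#' @export
print.photon_stats <- function(x, ...) {
  cat(sprintf("<photon_stats> %d events: mean %.1f, median %.1f, sd %.1f photons/event\n",
              x$n, x$mean, x$median, x$sd))
  invisible(x)
}

#' Cumulative (averaged) spectrum over events
#'
#' Channel-wise arithmetic mean over single-event spectra, optionally per
#' label group: the averaged SERS spectrum that many single-molecule spectra
#' converge to.
#'
#' @param spectra A spectrum table.
#' @param by_label Average within `label` groups (default `TRUE` when labels
#'   are present and non-missing).
#' @return Long tibble with `label` (or `"all"`), `channel` (0-based),
#'   `mean_photons`.
#' @export
cumulative_spectrum <- function(spectra,
                                by_label = !all(is.na(spectra$label))) {
  if (!is.data.frame(spectra) || nrow(spectra) == 0)
    stop("`spectra` must contain at least one event", call. = FALSE)
  feat <- spectrum_channels(spectra)
  g <- if (by_label) spectra$label else rep("all", nrow(spectra))
  out <- lapply(split(seq_len(nrow(spectra)), g), function(idx) {
    tibble::tibble(channel = seq_along(feat) - 1L,
                   mean_photons = colMeans(as.matrix(spectra[idx, feat])))
  })
  dplyr::bind_rows(out, .id = "label")
}

#' Channel columns of a spectrum table
#'
#' @param spectra A spectrum table.
#' @return Character vector of the `c<j>` channel column names, in order.
#' @export
spectrum_channels <- function(spectra) {
  nm <- grep("^c[0-9]+$", names(spectra), value = TRUE)
  nm[order(as.integer(sub("^c", "", nm)))]
}
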