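# Preprocessing of raw frame streams: faulty-channel removal and adaptive
# Wiener smoothing along the spectral axis of each frame.

.new_clean_stream <- function(counts, kept_channels, axis, frame_dt,
                              provenance, smoothed = FALSE) {
  structure(
    list(counts = counts, kept_channels = as.integer(kept_channels),
         axis = axis, frame_dt = frame_dt, provenance = provenance,
         smoothed = smoothed),
    class = "clean_stream"
  )
}

#' @export
print.clean_stream <- function(x, ...) {
  cat(sprintf("<clean_stream> %d frames x %d kept channels%s\n",
              nrow(x$counts), ncol(x$counts),
              if (isTRUE(x$smoothed)) " (Wiener-smoothed)" else ""))
  invisible(x)
}

#' Remove faulty detector channels
#'
#' Drops the listed channels from a raw frame stream. Channels are removed,
#' never interpolated: interpolation would fabricate photons. The kept-channel
#' index map and the wavenumber axis are updated accordingly.
#'
#' @param stream A `frame_stream` from [generate_frame_stream()] or
#'   [read_frame_stream()].
#' @param bad Integer channel indices (1-based) to drop; defaults to the
#'   stream's declared bad pixels.
#' @return A `clean_stream`: real-valued counts restricted to kept channels,
#'   the kept-channel index map, and the restricted axis.
#' @export
#' @examples
#' sim <- generate_frame_stream(generator_config(n_frames = 1000, seed = 1))
#' remove_bad_pixels(sim$stream)
remove_bad_pixels <- function(stream, bad = stream$bad_pixels) {
  stopifnot(inherits(stream, "frame_stream"))
  k <- ncol(stream$counts)
  bad <- as.integer(bad)
  if (any(bad < 1 | bad > k))
    stop("`bad` must be a subset of channel indices 1..", k, call. = FALSE)
  kept <- setdiff(seq_len(k), bad)
  if (length(kept) == 0)
    stop("removing all channels leaves an empty stream", call. = FALSE)
  counts <- stream$counts[, kept, drop = FALSE]
  storage.mode(counts) <- "double"
  .new_clean_stream(counts, kept, stream$axis[kept], stream$frame_dt,
                    stream$provenance)
}

# Rolling mean along the columns (spectral axis) of a matrix, window w,
# mirror reflection at the edges (edge sample not duplicated).
.roll_mean_spectral <- function(x, w) {
  if (w == 1) return(x)
  k <- ncol(x)
  h <- (w - 1L) / 2L
  pad_left <- (h + 1L):2L
  pad_right <- (k - 1L):(k - h)
  xp <- x[, c(pad_left, seq_len(k), pad_right), drop = FALSE]
  acc <- matrix(0, nrow = nrow(x), ncol = k)
  for (j in 0:(w - 1L)) acc <- acc + xp[, j + seq_len(k), drop = FALSE]
  acc / w
}

#' Adaptive Wiener smoothing of each frame
#'
#' Smooths every temporal frame along its spectral axis with the adaptive
#' (locally linear minimum-MSE) Wiener estimate: with local mean `m` and
#' local variance `v` over a `window`-channel neighbourhood and noise power
#' `nu` equal to the mean of all local variances in the frame, the output is
#' `m + max(v - nu, 0) / max(v, nu) * (x - m)`. Edges are handled by mirror
#' reflection. Smoothing is intended for event *detection*; event spectra are
#' extracted from the unsmoothed integer counts to preserve photon statistics.
#'
#' @param stream A `clean_stream` from [remove_bad_pixels()].
#' @param window Odd positive window size in channels (default 5), at most
#'   the number of kept channels.
#' @return A `clean_stream` with smoothed (real-valued) counts.
#' @export
#' @examples
#' sim <- generate_frame_stream(generator_config(n_frames = 1000, seed = 1))
#' sim$stream |> remove_bad_pixels() |> wiener_smooth()
wiener_smooth <- function(stream, window = 5) {
  stopifnot(inherits(stream, "clean_stream"))
  if (length(window) != 1 || window < 1 || window != round(window) ||
      window %% 2 == 0)
    stop("`window` must be an odd positive integer", call. = FALSE)
  if (window > ncol(stream$counts))
    stop("`window` exceeds the number of kept channels", call. = FALSE)
  x <- stream$counts
  if (window == 1) {
    out <- x
  } else {
    m <- .roll_mean_spectral(x, window)
    v <- pmax(.roll_mean_spectral(x^2, window) - m^2, 0)
    nu <- rowMeans(v)                     # per-frame noise power
    nu_m <- matrix(nu, nrow = nrow(x), ncol = ncol(x))
    denom <- pmax(v, nu_m)
    gain <- ifelse(denom > 0, pmax(v - nu_m, 0) / denom, 0)
    out <- m + gain * (x - m)
  }
  .new_clean_stream(out, stream$kept_channels, stream$axis, stream$frame_dt,
                    stream$provenance, smoothed = TRUE)
}
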