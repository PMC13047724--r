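# Synthetic SPAD frame-stream generator.
#
# Emulates the statistics of the flow-through experiment: a slowly drifting
# Poisson photon background on every live detector channel, translocation
# events arriving as a Poisson process, each event scattering ~Poisson(Lambda)
# photons allocated multinomially over the channels according to a per-event
# Dirichlet-perturbed copy of the peptide's emission fingerprint, spread
# uniformly over a geometric number of 100 us frames. Faulty detector
# channels are stamped with a dead (all-zero) or stuck-high signature.

#' Generator configuration
#'
#' Bundles and validates every knob of the synthetic stream generator.
#' Defaults reproduce the experiment's observable scales: 100 us frames, a
#' mean photon budget of 120 Raman photons per translocation event, 64
#' spectral channels over 1000-1600 cm^-1, a weak slowly drifting Poisson
#' background, and three dead detector channels.
#'
#' @param n_frames Number of acquisition frames (default 200000, i.e. 20 s).
#' @param frame_dt Frame duration in seconds (default 1e-4).
#' @param n_channels Number of spectral channels (default 64).
#' @param background_rate Mean background counts per channel per frame.
#' @param drift_amplitude Sinusoidal background drift amplitude, as a
#'   fraction of `background_rate`.
#' @param drift_period Drift period in frames.
#' @param event_rate Translocation events per second.
#' @param photon_budget Mean Raman photons per event (Poisson mean Lambda).
#' @param duration_mean Mean event duration in frames (geometric law, >= 1).
#' @param fluctuation Per-event spectral fluctuation eta: the event's channel
#'   probabilities are drawn from Dirichlet(emission / eta); `0` disables the
#'   perturbation.
#' @param separation Class-separation parameter delta passed to
#'   [peptide_templates()]; default frozen by calibration.
#' @param bad_pixels Integer indices (1-based) of faulty channels.
#' @param bad_pixel_mode `"dead"` (channel reads 0) or `"stuck"` (channel
#'   reads a constant high count every frame).
#' @param stuck_value Constant count used by stuck-high channels.
#' @param composition Named non-negative class fractions summing to 1.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A validated list of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_frames = 5000, seed = 1)
#' cfg$photon_budget
generator_config <- function(n_frames = 200000,
                             frame_dt = 1e-4,
                             n_channels = 64,
                             background_rate = 0.02,
                             drift_amplitude = 0.3,
                             drift_period = 5000,
                             event_rate = 100,
                             photon_budget = 120,
                             duration_mean = 2,
                             fluctuation = 0.02,
                             separation = default_separation(),
                             bad_pixels = c(7, 31, 50),
                             bad_pixel_mode = c("dead", "stuck"),
                             stuck_value = 10,
                             composition = c(OT = 0.5, VP = 0.5),
                             seed = NULL) {
  bad_pixel_mode <- match.arg(bad_pixel_mode)
  stopifnot(n_frames >= 1, n_frames == round(n_frames))
  if (!is.numeric(frame_dt) || frame_dt <= 0)
    stop("`frame_dt` must be > 0", call. = FALSE)
  for (nm in c("background_rate", "event_rate", "photon_budget", "fluctuation",
               "drift_amplitude")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop(sprintf("`%s` must be a single non-negative number", nm), call. = FALSE)
  }
  stopifnot(duration_mean >= 1, drift_period >= 2)
  if (length(bad_pixels) > 0) {
    bad_pixels <- as.integer(bad_pixels)
    if (any(bad_pixels < 1 | bad_pixels > n_channels) || anyDuplicated(bad_pixels))
      stop("`bad_pixels` must be distinct channel indices in 1..n_channels",
           call. = FALSE)
  }
  if (is.null(names(composition)) || any(names(composition) == ""))
    stop("`composition` must be a named vector of class fractions", call. = FALSE)
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9)
    stop("`composition` entries must be >= 0 and sum to 1", call. = FALSE)
  structure(
    list(n_frames = as.integer(n_frames), frame_dt = frame_dt,
         n_channels = as.integer(n_channels),
         background_rate = background_rate,
         drift_amplitude = drift_amplitude, drift_period = drift_period,
         event_rate = event_rate, photon_budget = photon_budget,
         duration_mean = duration_mean, fluctuation = fluctuation,
         separation = separation,
         bad_pixels = as.integer(bad_pixels), bad_pixel_mode = bad_pixel_mode,
         stuck_value = as.integer(stuck_value),
         composition = composition,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  %d frames x %d channels, frame_dt = %g s\n",
              x$n_frames, x$n_channels, x$frame_dt))
  cat(sprintf("  background %.3g cts/ch/frame (drift %.0f%%, period %d frames)\n",
              x$background_rate, 100 * x$drift_amplitude, as.integer(x$drift_period)))
  cat(sprintf("  events: %.3g /s, Lambda = %.3g photons, mean duration %.3g frames\n",
              x$event_rate, x$photon_budget, x$duration_mean))
  cat(sprintf("  fluctuation eta = %.3g, separation delta = %.4g\n",
              x$fluctuation, x$separation))
  cat(sprintf("  composition: %s; bad pixels: %s (%s)\n",
              paste(sprintf("%s=%.3g", names(x$composition), x$composition),
                    collapse = ", "),
              if (length(x$bad_pixels)) paste(x$bad_pixels, collapse = ",") else "none",
              x$bad_pixel_mode))
  invisible(x)
}

.new_frame_stream <- function(counts, axis, frame_dt, bad_pixels, provenance) {
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts, axis = axis, frame_dt = frame_dt,
         bad_pixels = as.integer(bad_pixels), provenance = provenance),
    class = "frame_stream"
  )
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("<frame_stream> %d frames x %d channels, frame_dt = %g s, %d bad pixel(s)\n",
              nrow(x$counts), ncol(x$counts), x$frame_dt, length(x$bad_pixels)))
  cat(sprintf("  total photons: %.0f\n", sum(x$counts)))
  invisible(x)
}

# Dirichlet perturbation of an emission vector; eta = 0 returns it unchanged.
.perturb_emission <- function(emission, eta) {
  if (eta <= 0) return(emission)
  g <- stats::rgamma(length(emission), shape = emission / eta)
  s <- sum(g)
  if (s == 0) return(emission)  # numerically degenerate draw
  g / s
}

#' Sample the photon counts of a single translocation event
#'
#' Draws one event: a Poisson total photon count with mean `photon_budget`,
#' allocated multinomially across spectral channels according to a per-event
#' Dirichlet-perturbed copy of the template emission vector, then split
#' uniformly over `duration` frames.
#'
#' @param template A `peptide_template` from [peptide_templates()].
#' @param photon_budget Mean total photons (Poisson mean Lambda).
#' @param fluctuation Dirichlet fluctuation eta (0 disables perturbation).
#' @param duration Event duration in frames (>= 1).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Integer matrix `duration x n_channels` of photon counts.
#' @export
#' @examples
#' tpl <- peptide_templates()
#' ev <- sample_event_spectrum(tpl$OT, duration = 2, seed = 1)
#' sum(ev)
sample_event_spectrum <- function(template, photon_budget = 120,
                                  fluctuation = 0.02, duration = 1,
                                  seed = NULL) {
  stopifnot(inherits(template, "peptide_template"))
  if (photon_budget < 0 || fluctuation < 0 || duration < 1)
    stop("`photon_budget` and `fluctuation` must be >= 0, `duration` >= 1",
         call. = FALSE)
  draw <- function() {
    k <- length(template$emission)
    n <- stats::rpois(1, photon_budget)
    if (n == 0) return(matrix(0L, nrow = duration, ncol = k))
    p <- .perturb_emission(template$emission, fluctuation)
    channel <- stats::rmultinom(1, n, p)[, 1]
    if (duration == 1) return(matrix(as.integer(channel), nrow = 1))
    out <- matrix(0L, nrow = duration, ncol = k)
    nz <- which(channel > 0)
    for (j in nz)
      out[, j] <- stats::rmultinom(1, channel[j], rep(1, duration))[, 1]
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

.sample_duration <- function(n, duration_mean) {
  if (duration_mean <= 1) return(rep(1L, n))
  1L + stats::rgeom(n, prob = 1 / duration_mean)
}

#' Generate a synthetic SPAD frame stream with ground truth
#'
#' Simulates the full instrument record: drifting Poisson background on every
#' live channel, translocation events placed by a Poisson process (events
#' whose frames would overlap an earlier event are dropped, preserving the
#' single-molecule reading of the stream), per-event class labels drawn from
#' `config$composition`, and faulty channels stamped dead or stuck-high.
#' Output is a pure function of `(config, templates)` when `config$seed` is
#' set.
#'
#' @param config A [generator_config()].
#' @param templates Optional named list of `peptide_template`s keyed by the
#'   classes in `config$composition`; defaults to [peptide_templates()] at
#'   `config$separation` (classes `OT`/`VP`).
#' @return A list with `stream` (a `frame_stream`: integer counts matrix,
#'   axis, frame duration, bad pixels, and provenance recording the config,
#'   seed, background photon total, and dropped-event count) and `events`, a
#'   tibble of ground-truth events with columns `event_id`, `label`,
#'   `start_frame`, `end_frame`, `photons_emitted` (photons landing on live
#'   channels).
#' @export
#' @examples
#' sim <- generate_frame_stream(generator_config(n_frames = 2000, seed = 1))
#' sim$stream
#' head(sim$events)
generate_frame_stream <- function(config = generator_config(),
                                  templates = NULL) {
  stopifnot(inherits(config, "generator_config"))
  axis <- wavenumber_axis(config$n_channels)
  if (is.null(templates))
    templates <- peptide_templates(config$separation, axis)
  classes <- names(config$composition)
  if (!all(classes %in% names(templates)))
    stop("`templates` must provide a template for every composition class",
         call. = FALSE)
  for (cl in classes) {
    if (length(templates[[cl]]$emission) != config$n_channels)
      stop("template `", cl, "` is not on the configured axis", call. = FALSE)
  }

  # Expected fraction of events whose interval collides with another event:
  # an event of mean length D frames is hit when another start falls within
  # ~2D frames of its own start (rate r events/frame).
  p_overlap <- 1 - exp(-config$event_rate * config$frame_dt *
                         2 * config$duration_mean)
  if (p_overlap > 0.10)
    warning("single-molecule condition violated: expected event overlap fraction ",
            sprintf("%.1f%%", 100 * p_overlap), call. = FALSE)

  run <- function() {
    n <- config$n_frames
    k <- config$n_channels
    good <- setdiff(seq_len(k), config$bad_pixels)

    # background with sinusoidally drifting rate, live channels only
    rate_t <- config$background_rate *
      (1 + config$drift_amplitude * sin(2 * pi * seq_len(n) / config$drift_period))
    counts <- matrix(0L, nrow = n, ncol = k)
    bg <- matrix(stats::rpois(n * length(good), rate_t), nrow = n)
    counts[, good] <- bg
    background_total <- sum(bg)

    # Poisson-process event placement; overlapping intervals are dropped
    n_ev <- stats::rpois(1, config$event_rate * n * config$frame_dt)
    truth <- tibble::tibble(event_id = character(), label = character(),
                            start_frame = integer(), end_frame = integer(),
                            photons_emitted = integer())
    n_dropped <- 0L
    if (n_ev > 0) {
      starts <- sort(sample.int(n, n_ev, replace = TRUE))
      durs <- .sample_duration(n_ev, config$duration_mean)
      labels <- sample(classes, n_ev, replace = TRUE,
                       prob = unname(config$composition))
      keep_start <- integer(); keep_end <- integer(); keep_lab <- character()
      phot <- integer()
      last_end <- 0L
      for (i in seq_len(n_ev)) {
        s <- starts[i]; e <- min(s + durs[i] - 1L, n)
        if (s <= last_end) { n_dropped <- n_dropped + 1L; next }
        ev <- sample_event_spectrum(templates[[labels[i]]],
                                    photon_budget = config$photon_budget,
                                    fluctuation = config$fluctuation,
                                    duration = e - s + 1L)
        counts[s:e, ] <- counts[s:e, , drop = FALSE] + ev
        keep_start <- c(keep_start, s); keep_end <- c(keep_end, e)
        keep_lab <- c(keep_lab, labels[i])
        phot <- c(phot, sum(ev[, good]))
        last_end <- e
      }
      if (length(keep_start))
        truth <- tibble::tibble(
          event_id = sprintf("ev%05d", seq_along(keep_start)),
          label = keep_lab, start_frame = keep_start, end_frame = keep_end,
          photons_emitted = as.integer(phot))
    }

    # faulty-channel signature is stamped last so it overwrites everything
    if (length(config$bad_pixels)) {
      counts[, config$bad_pixels] <-
        if (config$bad_pixel_mode == "dead") 0L else config$stuck_value
    }

    provenance <- list(config = unclass(config), seed = config$seed,
                       background_total = background_total,
                       n_events_dropped = n_dropped)
    list(stream = .new_frame_stream(counts, axis, config$frame_dt,
                                    config$bad_pixels, provenance),
         events = truth)
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

#' Generate labelled single-event spectra directly
#'
#' Shortcut generator for classification-scale datasets: draws event spectra
#' (class, duration, Dirichlet perturbation, Poisson photons, in-window
#' Poisson background on live channels) without materialising the full frame
#' stream, and returns them in the spectrum-table layout used across the
#' package (`event_id`, `label`, `true_label`, `start_frame`, `end_frame`,
#' `total_photons`, then one `c<j>` column per kept channel).
#'
#' @param n Number of event spectra to draw.
#' @param config A [generator_config()]; supplies photon budget, fluctuation,
#'   background, bad pixels and default composition.
#' @param composition Named class fractions (default `config$composition`).
#' @param label Optional fixed value for the `label` column (e.g. `"MIX"` for
#'   mixture datasets); by default the drawn class. The drawn class is always
#'   kept in `true_label`.
#' @param exact If `TRUE`, class counts are allocated deterministically as
#'   `n * composition` (largest-remainder rounding, shuffled order) instead
#'   of sampled — use for fixed-size per-class training datasets.
#' @param templates Optional template list, as in [generate_frame_stream()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A tibble with one row per event.
#' @export
#' @examples
#' d <- generate_event_spectra(10, generator_config(), seed = 1)
#' dplyr::count(d, label)
generate_event_spectra <- function(n, config = generator_config(),
                                   composition = config$composition,
                                   label = NULL, exact = FALSE,
                                   templates = NULL, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"), n >= 1)
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9)
    stop("`composition` entries must be >= 0 and sum to 1", call. = FALSE)
  axis <- wavenumber_axis(config$n_channels)
  if (is.null(templates))
    templates <- peptide_templates(config$separation, axis)
  classes <- names(composition)
  good <- setdiff(seq_len(config$n_channels), config$bad_pixels)

  run <- function() {
    if (exact) {
      base <- floor(n * composition)
      rem <- n - sum(base)
      if (rem > 0) {  # largest-remainder allocation of the leftover rows
        frac <- n * composition - base
        top <- order(frac, decreasing = TRUE)[seq_len(rem)]
        base[top] <- base[top] + 1
      }
      cls <- sample(rep(classes, times = base))
    } else {
      cls <- sample(classes, n, replace = TRUE, prob = unname(composition))
    }
    durs <- .sample_duration(n, config$duration_mean)
    spectra <- matrix(0L, nrow = n, ncol = length(good))
    for (i in seq_len(n)) {
      ev <- sample_event_spectrum(templates[[cls[i]]],
                                  photon_budget = config$photon_budget,
                                  fluctuation = config$fluctuation,
                                  duration = 1L)  # summed spectrum; duration
      sp <- ev[1, good]                           # only splits frames
      bg <- stats::rpois(length(good), config$background_rate * durs[i])
      spectra[i, ] <- sp + bg
    }
    out <- tibble::tibble(
      event_id = sprintf("ev%05d", seq_len(n)),
      label = if (is.null(label)) cls else rep(label, n),
      true_label = cls,
      start_frame = NA_integer_, end_frame = NA_integer_,
      total_photons = as.integer(rowSums(spectra)))
    mat <- tibble::as_tibble(as.data.frame(spectra),
                             .name_repair = "minimal")
    names(mat) <- sprintf("c%d", seq_along(good) - 1L)
    dplyr::bind_cols(out, mat)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Calibrate the class-separation parameter
#'
#' Bisection on the separation parameter delta: at each trial value, fresh
#' 400-per-class datasets are generated and the full discrimination protocol
#' ([evaluate_multirun()]) is run; the search returns the delta whose mean
#' held-out accuracy is within `tol` of `target_accuracy`. The packaged
#' default [default_separation()] was frozen with this function.
#'
#' @param target_accuracy Target mean held-out accuracy, in (0.5, 1).
#' @param config A [generator_config()] providing all non-delta settings.
#' @param cfg A [protocol_config()] for the classification protocol.
#' @param n_per_class Spectra generated per class at each trial (default 400).
#' @param range Bisection bracket for delta.
#' @param tol Accuracy tolerance around the target (default 0.02).
#' @param max_iter Maximum bisection steps.
#' @param n_replicates Dataset replicates averaged per trial delta.
#' @param seed Base integer seed for the calibration datasets.
#' @param eval_fn Protocol handle: a function `(data, cfg) -> mean accuracy`;
#'   the default runs [evaluate_multirun()] and extracts the mean accuracy.
#' @return List with `separation` (delta*), `accuracy` at delta*, and a
#'   `trace` tibble of all bisection trials.
#' @export
calibrate_separation <- function(target_accuracy = 0.705,
                                 config = generator_config(),
                                 cfg = protocol_config(),
                                 n_per_class = 400,
                                 range = c(0.02, 2.5),
                                 tol = 0.02, max_iter = 14,
                                 n_replicates = 2, seed = 101,
                                 eval_fn = NULL) {
  if (target_accuracy <= 0.5 || target_accuracy >= 1)
    stop("`target_accuracy` must lie strictly inside (0.5, 1)", call. = FALSE)
  if (is.null(eval_fn))
    eval_fn <- function(data, cfg) glance(evaluate_multirun(data, cfg))$mean_accuracy

  acc_at <- function(delta) {
    accs <- vapply(seq_len(n_replicates), function(r) {
      cfg_r <- config
      cfg_r$separation <- delta
      cfg_r$seed <- seed + r - 1L
      d <- generate_event_spectra(2L * n_per_class, cfg_r,
                                  composition = c(OT = 0.5, VP = 0.5),
                                  exact = TRUE)
      eval_fn(d, cfg)
    }, numeric(1))
    mean(accs)
  }

  lo <- range[1]; hi <- range[2]
  acc_lo <- acc_at(lo); acc_hi <- acc_at(hi)
  trace <- tibble::tibble(delta = c(lo, hi), accuracy = c(acc_lo, acc_hi))
  if (acc_lo > target_accuracy || acc_hi < target_accuracy)
    stop("calibration-failure: search range does not bracket the target accuracy",
         call. = FALSE)
  best <- if (abs(acc_lo - target_accuracy) < abs(acc_hi - target_accuracy))
    list(delta = lo, acc = acc_lo) else list(delta = hi, acc = acc_hi)
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)  # accuracy responds roughly log-linearly in delta
    acc_mid <- acc_at(mid)
    trace <- dplyr::bind_rows(trace,
                              tibble::tibble(delta = mid, accuracy = acc_mid))
    if (abs(acc_mid - target_accuracy) < abs(best$acc - target_accuracy))
      best <- list(delta = mid, acc = acc_mid)
    if (abs(acc_mid - target_accuracy) <= tol) break
    if (acc_mid < target_accuracy) lo <- mid else hi <- mid
  }
  list(separation = best$delta, accuracy = best$acc, trace = trace)
}
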