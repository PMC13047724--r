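# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; no data files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A 20k-frame default-parameter stream with ~200 ground-truth events.
sim_fixture <- function() {
  fixture("sim20k", function() {
    generate_frame_stream(generator_config(n_frames = 20000, seed = 3))
  })
}

# Detection output for the same stream.
detection_fixture <- function() {
  fixture("det20k", function() run_event_detection(sim_fixture()$stream))
}

# Balanced two-class dataset at the calibrated default separation.
dataset_fixture <- function(n_per_class = 200, seed = 5) {
  key <- sprintf("ds_%d_%d", n_per_class, seed)
  fixture(key, function() {
    generate_event_spectra(2 * n_per_class, generator_config(seed = seed),
                           composition = c(OT = 0.5, VP = 0.5), exact = TRUE)
  })
}

# Hand-built clean stream (bypasses the generator) for filter unit tests.
make_clean_stream <- function(counts, frame_dt = 1e-4) {
  counts <- as.matrix(counts)
  sersflow:::.new_clean_stream(
    `storage.mode<-`(counts, "double"), seq_len(ncol(counts)),
    seq(1000, 1600, length.out = ncol(counts)), frame_dt,
    provenance = list())
}

# Hand-built corrected time trace for threshold/merge unit tests.
make_trace <- function(x, corrected = TRUE) {
  tr <- tibble::tibble(frame = seq_along(x), photons = x)
  if (corrected) tr$corrected <- x
  attr(tr, "frame_dt") <- 1e-4
  class(tr) <- c("time_trace", class(tr))
  tr
}
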