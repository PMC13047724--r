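# File formats: the frame-stream text dialect, the spectrum-table CSV, and
# run-configuration JSON. All artifacts embed the configuration and seed that
# produced them, so any file can be traced back to its run.

#' Write a frame stream to the text interchange format
#'
#' Header lines prefixed `#` carry a single JSON metadata object (frame
#' duration, axis centers, bad pixels, kept channels where applicable, seed
#' and a config echo); the body holds one line per frame of space-separated
#' integer counts. The write/read round trip is bit-exact.
#'
#' @param stream A `frame_stream` or `clean_stream`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_stream <- function(stream, path) {
  is_clean <- inherits(stream, "clean_stream")
  if (!is_clean && !inherits(stream, "frame_stream"))
    stop("`stream` must be a frame_stream or clean_stream", call. = FALSE)
  meta <- list(frame_dt = stream$frame_dt, wavenumbers = stream$axis)
  if (is_clean) meta$kept_channels <- stream$kept_channels
  else meta$bad_pixels <- stream$bad_pixels
  if (!is.null(stream$provenance$seed)) meta$seed <- stream$provenance$seed
  if (!is.null(stream$provenance$config)) meta$config <- stream$provenance$config
  header <- paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                          null = "null"))
  body <- apply(stream$counts, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a frame stream from the text interchange format
#'
#' Inverse of [write_frame_stream()]. Malformed headers, ragged rows and
#' negative counts raise parse errors naming the offending line.
#'
#' @param path Input file path.
#' @return A `frame_stream` (or `clean_stream` if the header declares
#'   `kept_channels`).
#' @export
read_frame_stream <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (length(hdr) == 0 || hdr[1] != 1)
    stop("line 1: missing `#` JSON metadata header", call. = FALSE)
  meta <- tryCatch(
    jsonlite::fromJSON(sub("^#\\s*", "", paste(lines[hdr], collapse = ""))),
    error = function(e) stop("line 1: malformed JSON header (",
                             conditionMessage(e), ")", call. = FALSE))
  if (is.null(meta$frame_dt) || is.null(meta$wavenumbers))
    stop("line 1: header must declare frame_dt and wavenumbers", call. = FALSE)
  body <- lines[-hdr]
  k <- length(meta$wavenumbers)
  toks <- strsplit(trimws(body), "\\s+")
  bad_len <- which(lengths(toks) != k)
  if (length(bad_len))
    stop("line ", length(hdr) + bad_len[1], ": expected ", k,
         " integer counts", call. = FALSE)
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  counts <- matrix(vals, nrow = length(body), ncol = k, byrow = TRUE)
  bad_row <- function(test) length(hdr) + which(apply(test, 1, any))[1]
  if (anyNA(vals))
    stop("line ", bad_row(is.na(counts)), ": non-numeric count", call. = FALSE)
  if (any(vals < 0))
    stop("line ", bad_row(counts < 0), ": negative counts are not allowed",
         call. = FALSE)
  if (any(vals != round(vals)))
    stop("line ", bad_row(counts != round(counts)),
         ": counts must be integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  provenance <- list(seed = meta$seed, config = meta$config)
  if (!is.null(meta$kept_channels)) {
    .new_clean_stream(`storage.mode<-`(counts, "double"),
                      meta$kept_channels, meta$wavenumbers, meta$frame_dt,
                      provenance)
  } else {
    .new_frame_stream(counts, meta$wavenumbers, meta$frame_dt,
                      meta$bad_pixels %||% integer(), provenance)
  }
}

.spectra_required_cols <- c("event_id", "label", "start_frame", "end_frame",
                            "total_photons")

#' Write a spectrum table to CSV
#'
#' Event-spectrum interchange format: header
#' `event_id,label,start_frame,end_frame,total_photons,c0,...,c{K-1}`.
#' Auxiliary columns (e.g. `true_label`) are preserved after the channel
#' block.
#'
#' @param spectra A spectrum table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(is.data.frame(spectra))
  feat <- spectrum_channels(spectra)
  missing <- setdiff(.spectra_required_cols, names(spectra))
  if (length(missing))
    stop("spectrum table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(spectra), c(.spectra_required_cols, feat))
  readr::write_csv(spectra[c(.spectra_required_cols, feat, extra)], path)
  invisible(path)
}

#' Read a spectrum table from CSV
#'
#' @param path Input file path.
#' @return A spectrum-table tibble.
#' @export
read_spectra <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(.spectra_required_cols, names(out))
  if (length(missing))
    stop("spectrum CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(spectrum_channels(out)) == 0)
    stop("spectrum CSV has no channel columns (c0, c1, ...)", call. = FALSE)
  out
}

#' Assemble a run configuration
#'
#' Bundles the stage configurations, output directory and global seed into a
#' single object that serialises losslessly to one JSON document.
#'
#' @param generator A [generator_config()].
#' @param detection A [detection_config()].
#' @param protocol A [protocol_config()].
#' @param mixture List of mixture-stage settings (`n_seeds`, `bin_width`,
#'   `linear_max`).
#' @param out_dir Output directory recorded with the run.
#' @param seed Global integer seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       detection = detection_config(),
                       protocol = protocol_config(),
                       mixture = list(n_seeds = 300, bin_width = 0.2,
                                      linear_max = 3),
                       out_dir = ".", seed = 1) {
  structure(list(generator = unclass(generator),
                 detection = unclass(detection),
                 protocol = unclass(protocol),
                 mixture = mixture, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   returns the recovered `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- unclass(config)
  # named atomic vectors serialise as bare arrays; keep the class names
  obj$generator$composition <- as.list(obj$generator$composition)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  raw$generator$composition <- unlist(raw$generator$composition)
  gen <- do.call(generator_config, raw$generator)
  det <- do.call(detection_config, raw$detection)
  prot_args <- raw$protocol
  run_config(generator = gen, detection = det,
             protocol = do.call(protocol_config, prot_args),
             mixture = raw$mixture, out_dir = raw$out_dir, seed = raw$seed)
}
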