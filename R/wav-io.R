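#' In-memory audio recording
#'
#' Container for one channel of a session recording: normalized amplitude
#' samples, sample rate, and which physical channel the signal represents.
#'
#' @param samples Numeric vector of finite amplitudes (nominally in [-1, 1]).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param channel_label One of \code{"light"}, \code{"sound"},
#'   \code{"vibration_mic"}.
#' @return An object of class \code{"recording"}.
#' @export
recording <- function(samples, sample_rate,
                      channel_label = c("light", "sound", "vibration_mic")) {
  channel_label <- match.arg(channel_label)
  stopifnot(is.numeric(samples), all(is.finite(samples)),
            is.numeric(sample_rate), length(sample_rate) == 1L,
            sample_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 channel_label = channel_label),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %s channel, %d samples at %g Hz (%.2f s)\n",
              x$channel_label, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Write a recording as mono 16-bit PCM WAV
#'
#' Minimal RIFF/WAVE writer (mono, 16-bit linear PCM). Samples are clipped to
#' [-1, 1] and quantized to int16.
#'
#' @param rec A \code{\link{recording}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  x <- pmax(-1, pmin(1, rec$samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(rec$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the files written by \code{\link{write_wav}}
#' (mono, 16-bit linear PCM; other chunks are skipped). Samples are rescaled
#' to [-1, 1].
#'
#' @param path WAV file path.
#' @param channel_label Channel label to attach to the recording.
#' @return A \code{\link{recording}}.
#' @export
read_wav <- function(path, channel_label = "sound") {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sample_rate <- NULL; pcm <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only linear PCM supported")
      if (fmt[2] != 1L) stop("only mono supported")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), n = 1, size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit PCM supported")
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz / 2, size = 2,
                     signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, raw(), n = sz + sz %% 2))
    }
  }
  if (is.null(sample_rate) || is.null(pcm))
    stop("malformed WAV: missing fmt or data chunk")
  recording(pcm / 32767, sample_rate, channel_label)
}

#' Event markers of a recorded session
#'
#' Trigger timestamps (trial onset at 0 ms, stimulus onset at 300 ms, trial
#' offset at 700 ms of each trial) plus per-channel device markers
#' (threshold-crossing times). All times in seconds; streams must be strictly
#' increasing and each stimulus onset must lie within its trial.
#'
#' @param trial_onsets,stimulus_onsets,trial_offsets Numeric vectors of equal
#'   length (seconds).
#' @param device_markers Named list of numeric vectors (seconds), one per
#'   channel label.
#' @return An object of class \code{"event_markers"}.
#' @export
event_markers <- function(trial_onsets, stimulus_onsets, trial_offsets,
                          device_markers = list()) {
  stopifnot(length(trial_onsets) == length(stimulus_onsets),
            length(trial_onsets) == length(trial_offsets))
  for (v in list(trial_onsets, stimulus_onsets, trial_offsets))
    if (is.unsorted(v, strictly = TRUE))
      stop("marker streams must be strictly increasing")
  if (any(stimulus_onsets < trial_onsets | stimulus_onsets > trial_offsets))
    stop("each stimulus onset must lie within its trial")
  for (dm in device_markers)
    if (is.unsorted(dm, strictly = TRUE))
      stop("device marker streams must be strictly increasing")
  structure(list(trial_onsets = trial_onsets,
                 stimulus_onsets = stimulus_onsets,
                 trial_offsets = trial_offsets,
                 device_markers = device_markers),
            class = "event_markers")
}

#' Write event markers as JSON
#' @param markers An \code{\link{event_markers}} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_events_json <- function(markers, path) {
  stopifnot(inherits(markers, "event_markers"))
  jsonlite::write_json(unclass(markers), path, digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

#' Read event markers from JSON
#' @param path JSON path written by \code{\link{write_events_json}}.
#' @return An \code{\link{event_markers}} object.
#' @export
read_events_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  event_markers(x$trial_onsets, x$stimulus_onsets, x$trial_offsets,
                as.list(x$device_markers))
}
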