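#' Normalized RMS envelope of a recording
#'
#' Frame-wise root-mean-square amplitude with the standard analysis frames
#' (length 2048 samples, hop 512), normalized so the peak frame is 1 (an
#' all-zero signal stays all-zero). Frame times are frame centers. Computed
#' in O(n) via a cumulative sum of squares.
#'
#' @param rec A \code{\link{recording}} at least one frame long.
#' @param frame Frame length in samples, default 2048.
#' @param hop Hop length in samples, default 512.
#' @return List with \code{envelope} (normalized RMS per frame), \code{time}
#'   (frame-center seconds), \code{frame_start} (0-based start sample of each
#'   frame), \code{frame}, \code{hop}, \code{sample_rate}, and \code{peak_rms}
#'   (the raw RMS used for normalization).
#' @export
rms_envelope <- function(rec, frame = 2048, hop = 512) {
  stopifnot(inherits(rec, "recording"), frame >= 1, hop >= 1)
  x <- rec$samples
  n <- length(x)
  if (n < frame)
    stop("recording shorter than one frame (", n, " < ", frame, " samples)")
  starts <- seq(0L, n - frame, by = hop)        # 0-based
  cs <- c(0, cumsum(x^2))
  ssq <- cs[starts + frame + 1] - cs[starts + 1]
  env <- sqrt(ssq / frame)
  peak <- max(env)
  if (peak > 0) env <- env / peak
  list(envelope = env,
       time = (starts + frame / 2) / rec$sample_rate,
       frame_start = starts, frame = frame, hop = hop,
       sample_rate = rec$sample_rate, peak_rms = peak)
}

#' Detect stimulus onsets from the RMS envelope
#'
#' Default pluggable detector: an upward crossing of the normalized RMS
#' envelope above \code{threshold}, honouring a refractory interval between
#' detections. Because an analysis frame crosses the threshold as soon as it
#' overlaps the first few samples of a burst, the frame-level crossing only
#' brackets the onset; the reported time is refined to the first raw sample
#' whose absolute amplitude exceeds \code{threshold} times the recording's
#' peak amplitude, searched over the ambiguous span (from the start of the
#' last sub-threshold frame to the end of the crossing frame). This keeps the
#' recovery error within one hop for abrupt bursts and yields the analytic
#' threshold-crossing delay for ramped bursts. Each onset is annotated with
#' the envelope of the last analysis frame ending at or before the onset
#' time (the pre-onset noise floor; frames are long and overlap, so frames
#' straddling the onset already contain burst energy). This floor is what
#' the spurious-onset filter inspects.
#'
#' A different detector (e.g., a neural-network onset picker) can be swapped
#' in by supplying its output to \code{\link{filter_spurious_onsets}} and
#' \code{\link{match_markers_to_onsets}} directly.
#'
#' @param rec A \code{\link{recording}}.
#' @param threshold Normalized envelope threshold, default 0.05.
#' @param refractory Minimum separation between detections in seconds,
#'   default 0.1.
#' @param frame,hop Envelope analysis parameters (see
#'   \code{\link{rms_envelope}}).
#' @return Data frame with columns \code{time} (seconds),
#'   \code{envelope_at_onset} (normalized, in [0, 1]) and \code{accepted}
#'   (all TRUE; see \code{\link{filter_spurious_onsets}}). Zero rows when no
#'   onset is found.
#' @export
detect_onsets <- function(rec, threshold = 0.05, refractory = 0.1,
                          frame = 2048, hop = 512) {
  stopifnot(inherits(rec, "recording"), threshold > 0, threshold < 1)
  env <- rms_envelope(rec, frame = frame, hop = hop)
  e <- env$envelope
  above <- e > threshold
  # an onset is a transition from below to above; a signal already above the
  # threshold in its first frame has no detectable onset there
  cross <- which(above & !c(TRUE, above[-length(above)]))
  empty <- data.frame(time = numeric(0), envelope_at_onset = numeric(0),
                      accepted = logical(0))
  if (!length(cross)) return(empty)
  peak_amp <- max(abs(rec$samples))
  amp_thr <- threshold * peak_amp
  sr <- rec$sample_rate
  times <- numeric(0); floors <- numeric(0); last_t <- -Inf
  for (j in cross) {
    prev_start <- if (j > 1) env$frame_start[j - 1] else 0L
    span_end <- env$frame_start[j] + frame - 1L
    idx <- (prev_start + 1L):(span_end + 1L)              # 1-based samples
    hit <- idx[abs(rec$samples[idx]) > amp_thr][1]
    t <- if (is.na(hit)) (env$frame_start[j] + frame - hop) / sr else
      (hit - 1L) / sr
    if (t - last_t < refractory) next
    last_t <- t
    times <- c(times, t)
    # pre-onset noise floor: last frame wholly before the onset sample
    k <- floor((t * sr - frame) / hop) + 1          # frame index, 1-based
    floors <- c(floors, if (k >= 1) e[min(k, length(e))] else 0)
  }
  if (!length(times)) return(empty)
  data.frame(time = times, envelope_at_onset = floors,
             accepted = rep(TRUE, length(times)))
}

#' Reject spurious onsets by pre-onset amplitude
#'
#' An onset flagged where the signal amplitude was already high is considered
#' spurious: any onset whose annotated pre-onset envelope exceeds
#' \code{max_envelope} (strictly) is marked rejected. An envelope of exactly
#' \code{max_envelope} is accepted.
#'
#' @param onsets Data frame from \code{\link{detect_onsets}} (or any detector
#'   providing \code{envelope_at_onset}).
#' @param max_envelope Normalized envelope ceiling, default 0.01.
#' @return The onsets with the \code{accepted} flag updated.
#' @export
filter_spurious_onsets <- function(onsets, max_envelope = 0.01) {
  stopifnot(is.data.frame(onsets), "envelope_at_onset" %in% names(onsets))
  onsets$accepted <- onsets$envelope_at_onset <= max_envelope
  onsets
}
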