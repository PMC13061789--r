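#' Configuration of the synthetic timing-session generator
#'
#' Emulates the bench-test session used to characterise browser stimulus
#' timing: 700-ms trials repeated in blocks, a 300-ms foreperiod, 200-ms
#' stimuli, trigger timestamps at 0/300/700 ms of each trial, a 440-Hz tone
#' burst on the sound channel, a square pulse on the light (photodiode)
#' channel, and an amplitude-ramped low-frequency burst on the
#' vibration-microphone channel. Channel lags default to the published bench
#' measurements (light 35.9 +/- 4.3 ms, sound 40.9 +/- 3.4 ms); the vibration
#' physical-onset lag and ramp duration (30.46 +/- 5.28 ms) are set so the
#' vibration device marker, which fires at the end of the ramp, lands near
#' the published 78.6 ms.
#'
#' @param n_trials Number of trials, default 1000.
#' @param block_size Trials per block (metadata only), default 250.
#' @param trial_length,foreperiod,stim_duration Trial timing in seconds
#'   (defaults 0.7, 0.3, 0.2; foreperiod + duration must fit in the trial).
#' @param sample_rate Recording rate in Hz, default 44100.
#' @param lag_ms Named list of c(mean, sd) onset lags in ms per channel.
#' @param ramp_ms c(mean, sd) of the vibration linear amplitude-ramp
#'   duration in ms.
#' @param tone_freq,vib_freq Tone and vibration carrier frequencies (Hz).
#' @param noise_floor SD of the Gaussian background noise (amplitude units;
#'   bursts have amplitude ~0.8), default 0.003.
#' @param marker_threshold Fraction of the burst amplitude at which the
#'   device marker fires (evaluated on the amplitude envelope), default 1.0:
#'   the marker fires when the ramp completes.
#' @param drift_ms_per_trial Optional linear drift added to every channel's
#'   lag (ms per trial), default 0 (i.i.d. lags).
#' @return An object of class \code{"session_gen_config"}.
#' @export
session_gen_config <- function(n_trials = 1000, block_size = 250,
                               trial_length = 0.7, foreperiod = 0.3,
                               stim_duration = 0.2, sample_rate = 44100,
                               lag_ms = list(light = c(35.9, 4.3),
                                             sound = c(40.9, 3.4),
                                             vibration_mic = c(48.1, 3.0)),
                               ramp_ms = c(30.46, 5.28),
                               tone_freq = 440, vib_freq = 180,
                               noise_floor = 0.003, marker_threshold = 1.0,
                               drift_ms_per_trial = 0) {
  stopifnot(n_trials >= 1, block_size >= 1, sample_rate > 0,
            foreperiod + stim_duration <= trial_length,
            all(ramp_ms >= 0), ramp_ms[1] >= 0,
            marker_threshold > 0, marker_threshold <= 1,
            noise_floor >= 0)
  stopifnot(all(c("light", "sound", "vibration_mic") %in% names(lag_ms)))
  structure(as.list(environment())[c(
    "n_trials", "block_size", "trial_length", "foreperiod", "stim_duration",
    "sample_rate", "lag_ms", "ramp_ms", "tone_freq", "vib_freq",
    "noise_floor", "marker_threshold", "drift_ms_per_trial")],
    class = "session_gen_config")
}

#' Generate a synthetic session recording with complete ground truth
#'
#' Builds one waveform per channel, the trigger streams (trial onset,
#' stimulus onset at the foreperiod, trial offset), and per-channel device
#' markers. Physical onsets are stimulus trigger + a sampled channel lag; the
#' vibration burst's amplitude ramps linearly over a sampled ramp duration.
#' Device markers are the first time the channel's amplitude envelope crosses
#' \code{marker_threshold} times the burst amplitude (for a linear ramp this
#' is onset + threshold x ramp, quantized to the sample grid; instantaneous
#' bursts trigger at onset). Background Gaussian noise is added last.
#' Everything is deterministic under the seed and all ground truth (onsets,
#' lags, ramps, markers) is returned.
#'
#' @param config A \code{\link{session_gen_config}}.
#' @param seed Integer seed.
#' @param channels Channels to synthesise, default all three.
#' @return List with \code{recordings} (named list of
#'   \code{\link{recording}}), \code{markers} (an
#'   \code{\link{event_markers}}), and \code{truth} (data frame per trial:
#'   trigger, per-channel onset/lag, ramp duration, per-channel marker) plus
#'   the config and seed.
#' @export
gen_session_recording <- function(config = session_gen_config(), seed = 1L,
                                  channels = c("light", "sound",
                                               "vibration_mic")) {
  stopifnot(inherits(config, "session_gen_config"))
  set.seed(seed)
  sr <- config$sample_rate
  n <- config$n_trials
  trial_start <- (seq_len(n) - 1) * config$trial_length
  trigger <- trial_start + config$foreperiod
  dur <- config$stim_duration
  amp <- 0.8
  drift <- config$drift_ms_per_trial * (seq_len(n) - 1)
  lags <- list()
  for (ch in channels) {
    p <- config$lag_ms[[ch]]
    lags[[ch]] <- (stats::rnorm(n, p[1], p[2]) + drift) / 1000
    if (any(lags[[ch]] < 0))
      stop("config error: sampled negative lag on channel ", ch)
    if (any(lags[[ch]] + dur > config$trial_length - config$foreperiod))
      stop("config error: bursts would overlap across trials on channel ", ch)
  }
  tau <- pmax(0, stats::rnorm(n, config$ramp_ms[1], config$ramp_ms[2])) / 1000
  if (any(tau >= dur))
    stop("config error: ramp duration must be shorter than the stimulus")

  n_samp <- ceiling((n * config$trial_length + 0.5) * sr)
  t_burst <- seq_len(ceiling(dur * sr)) / sr  # time within burst, one grid
  recordings <- list(); device <- list(); onset <- list()
  for (ch in channels) {
    x <- numeric(n_samp)
    on_t <- trigger + lags[[ch]]
    mark <- numeric(n)
    for (i in seq_len(n)) {
      idx <- ceiling(on_t[i] * sr) + seq_along(t_burst)  # 1-based samples
      tt <- (idx - 1) / sr - on_t[i]          # time since onset, >= 0
      if (ch == "light") {
        burst <- rep(amp, length(idx))
        envl <- rep(1, length(idx))
      } else if (ch == "sound") {
        burst <- amp * sin(2 * pi * config$tone_freq * tt)
        envl <- rep(1, length(idx))
      } else {
        envl <- pmin(1, tt / max(tau[i], 1e-12))
        burst <- envl * amp *
          (0.9 * sin(2 * pi * config$vib_freq * tt) +
             0.15 * stats::rnorm(length(idx)))
      }
      x[idx] <- x[idx] + burst
      # marker: first sample where the amplitude envelope reaches
      # marker_threshold (exact closed form for the linear ramp)
      cross <- if (ch == "vibration_mic" && tau[i] > 0)
        on_t[i] + config$marker_threshold * tau[i] else on_t[i]
      mark[i] <- ceiling(cross * sr) / sr
    }
    if (config$noise_floor > 0)
      x <- x + stats::rnorm(n_samp, 0, config$noise_floor)
    recordings[[ch]] <- recording(x, sr, ch)
    device[[ch]] <- mark
    onset[[ch]] <- on_t
  }
  truth <- data.frame(trial = seq_len(n),
                      block = (seq_len(n) - 1) %/% config$block_size + 1,
                      trigger = trigger, ramp = tau)
  for (ch in channels) {
    truth[[paste0("onset_", ch)]] <- onset[[ch]]
    truth[[paste0("lag_", ch)]] <- lags[[ch]]
    truth[[paste0("marker_", ch)]] <- device[[ch]]
  }
  markers <- event_markers(trial_start, trigger,
                           trial_start + config$trial_length, device)
  list(recordings = recordings, markers = markers, truth = truth,
       config = config, seed = seed)
}
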