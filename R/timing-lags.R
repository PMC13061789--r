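#' Match event markers to detected physical onsets
#'
#' Pairs each marker timestamp with the nearest accepted detected onset
#' within \code{max_gap}. Lag is marker minus physical onset, so a positive
#' lag means the marker trails the physical event. Unmatched markers are
#' returned separately (reported, never fatal).
#'
#' @param markers Numeric vector of marker times (seconds, sorted).
#' @param onsets Data frame from \code{\link{detect_onsets}} /
#'   \code{\link{filter_spurious_onsets}}; only rows with
#'   \code{accepted == TRUE} are used.
#' @param max_gap Maximum marker-to-onset distance in seconds, default 0.15.
#' @return List with \code{matched} (data frame: marker, onset, lag in
#'   seconds) and \code{unmatched} (marker times).
#' @export
match_markers_to_onsets <- function(markers, onsets, max_gap = 0.15) {
  stopifnot(is.numeric(markers), is.data.frame(onsets))
  ot <- onsets$time[onsets$accepted]
  if (!length(ot) || !length(markers))
    return(list(matched = data.frame(marker = numeric(0), onset = numeric(0),
                                     lag = numeric(0)),
                unmatched = markers))
  nearest <- findInterval(markers, ot)
  lo <- pmax(nearest, 1L)
  hi <- pmin(nearest + 1L, length(ot))
  pick <- ifelse(abs(markers - ot[lo]) <= abs(markers - ot[hi]), lo, hi)
  gap <- abs(markers - ot[pick])
  ok <- gap <= max_gap
  list(matched = data.frame(marker = markers[ok], onset = ot[pick[ok]],
                            lag = markers[ok] - ot[pick[ok]]),
       unmatched = markers[!ok])
}

#' Summarise lags into a distribution table
#'
#' Mean, SD and raw-data percentiles of a set of lags, in milliseconds.
#' Percentiles use linear interpolation between order statistics
#' (\code{stats::quantile} type 7), so published table cells are exactly
#' reproducible.
#'
#' @param lags_ms Numeric vector of lags in milliseconds (>= 1 value).
#' @param label Event label for the table row.
#' @return One-row data frame of class \code{"timing_lags"}: event, n_events,
#'   mean, sd, min, p25, p50, p75, max (all ms).
#' @examples
#' lag_summary(c(10, 20, 30, 40), "example")  # median 25
#' @export
lag_summary <- function(lags_ms, label = "event") {
  if (!length(lags_ms)) stop("no lags to summarise")
  q <- stats::quantile(lags_ms, c(0, 0.25, 0.5, 0.75, 1), names = FALSE,
                       type = 7)
  out <- data.frame(event = label, n_events = length(lags_ms),
                    mean = mean(lags_ms),
                    sd = if (length(lags_ms) > 1) stats::sd(lags_ms) else 0,
                    min = q[1], p25 = q[2], p50 = q[3], p75 = q[4],
                    max = q[5])
  class(out) <- c("timing_lags", "data.frame")
  out
}

#' Cross-modal asynchrony relative to the visual onset
#'
#' Per-trial asynchrony of a channel's physical onsets relative to the visual
#' (reference) onsets of the same trials, summarised as a lag table in ms.
#'
#' @param channel_onsets,reference_onsets Paired per-trial onset times in
#'   seconds (equal length).
#' @param label Event label for the table row.
#' @return A \code{\link{lag_summary}} table of channel minus reference, ms.
#' @export
asynchrony_summary <- function(channel_onsets, reference_onsets,
                               label = "event") {
  if (length(channel_onsets) != length(reference_onsets))
    stop("channel and reference onsets must be paired (equal length)")
  lag_summary((channel_onsets - reference_onsets) * 1000, label)
}

#' Regress cross-modal asynchrony on vibration ramp lag
#'
#' Ordinary least squares of asynchrony (ms) on ramp lag (ms) with classical
#' standard errors, t-tests and 95% confidence intervals for slope and
#' intercept, plus the overall F and R-squared. A significant positive slope
#' indicates that the motor's amplitude ramp delays the measured vibration
#' onset relative to the visual stimulus.
#'
#' @param ramp_lags_ms Predictor: per-trial ramp (marker minus detected
#'   onset) in ms.
#' @param asynchronies_ms Response: per-trial visual-vibration asynchrony in
#'   ms.
#' @return An object of class \code{"timing_regression"} wrapping the
#'   coefficient table, CIs, R-squared, F and dfs (and the underlying
#'   \code{lm} fit).
#' @export
regress_asynchrony_on_ramp <- function(ramp_lags_ms, asynchronies_ms) {
  if (length(ramp_lags_ms) != length(asynchronies_ms))
    stop("predictor and response must have equal length")
  if (length(ramp_lags_ms) < 3) stop("need at least 3 observations")
  if (stats::var(ramp_lags_ms) == 0)
    stop("degenerate fit: zero variance in the ramp predictor")
  fit <- stats::lm(asynchronies_ms ~ ramp_lags_ms)
  sm <- summary(fit)
  ci <- stats::confint(fit)
  co <- sm$coefficients
  structure(list(
    slope = co[2, 1], slope_se = co[2, 2], slope_t = co[2, 3],
    slope_p = co[2, 4], slope_ci95 = unname(ci[2, ]),
    intercept = co[1, 1], intercept_se = co[1, 2], intercept_t = co[1, 3],
    intercept_p = co[1, 4], intercept_ci95 = unname(ci[1, ]),
    r_squared = sm$r.squared,
    f_value = unname(sm$fstatistic[1]),
    df1 = unname(sm$fstatistic[2]), df2 = unname(sm$fstatistic[3]),
    fit = fit), class = "timing_regression")
}

#' @export
print.timing_regression <- function(x, ...) {
  cat(sprintf("asynchrony ~ ramp lag: F(%d, %d) = %.1f, R^2 = %.3f\n",
              x$df1, x$df2, x$f_value, x$r_squared))
  cat(sprintf("  slope     b1 = %.3f (SE %.3f), t = %.2f, p = %.3g, 95%% CI [%.3f, %.3f]\n",
              x$slope, x$slope_se, x$slope_t, x$slope_p,
              x$slope_ci95[1], x$slope_ci95[2]))
  cat(sprintf("  intercept b0 = %.2f (SE %.2f), t = %.2f, p = %.3g, 95%% CI [%.2f, %.2f]\n",
              x$intercept, x$intercept_se, x$intercept_t, x$intercept_p,
              x$intercept_ci95[1], x$intercept_ci95[2]))
  invisible(x)
}

# Per-trial alignment: nearest value of `times` to each trigger, NA when
# nothing falls within max_gap.
align_to_triggers <- function(times, triggers, max_gap) {
  if (!length(times)) return(rep(NA_real_, length(triggers)))
  nearest <- findInterval(triggers, times)
  lo <- pmax(nearest, 1L)
  hi <- pmin(nearest + 1L, length(times))
  pick <- ifelse(abs(triggers - times[lo]) <= abs(triggers - times[hi]),
                 lo, hi)
  out <- times[pick]
  out[abs(triggers - out) > max_gap] <- NA_real_
  out
}

#' Full timing analysis of a recorded session
#'
#' Runs the channel pipeline end to end. For every channel the normalized RMS
#' envelope is computed, onsets detected and spurious ones rejected, and both
#' the detected onsets and the channel's device markers are aligned per trial
#' to the stimulus-onset trigger stream. From these the function builds:
#'
#' \itemize{
#'   \item \code{lag_tables}: device-marker lag relative to the trigger
#'     (the published onset-lag table shape), per channel, in ms;
#'   \item \code{onset_lag_tables}: detected physical onset minus trigger;
#'   \item \code{asynchrony_tables}: per-trial device-marker asynchrony of
#'     each channel relative to the reference (visual) channel;
#'   \item \code{marker_lag_tables}: device marker minus detected onset (for
#'     a ramped vibration this is the ramp period seen by the marker);
#'   \item \code{regression}: OLS of visual-vibration asynchrony on the
#'     per-trial ramp lag, when a vibration channel is present.
#' }
#'
#' @param recordings Named list of \code{\link{recording}} objects (names are
#'   channel labels, e.g. \code{light}, \code{sound}, \code{vibration_mic}).
#' @param markers An \code{\link{event_markers}} object.
#' @param reference Channel used as the asynchrony reference, default
#'   \code{"light"}.
#' @param threshold,refractory,frame,hop Detector settings (see
#'   \code{\link{detect_onsets}}).
#' @param max_gap Matching window in seconds, default 0.15.
#' @return Object of class \code{"timing_analysis"}; see Details. Also
#'   carries per-trial \code{onsets} and \code{device} times per channel and
#'   \code{unmatched} trigger counts.
#' @export
analyze_session <- function(recordings, markers, reference = "light",
                            threshold = 0.05, refractory = 0.1,
                            frame = 2048, hop = 512, max_gap = 0.15) {
  stopifnot(inherits(markers, "event_markers"), is.list(recordings),
            !is.null(names(recordings)))
  trig <- markers$stimulus_onsets
  chan_onset <- list(); chan_dev <- list()
  lag_tables <- list(); onset_lag_tables <- list()
  marker_lag_tables <- list(); unmatched <- list()
  for (ch in names(recordings)) {
    ons <- detect_onsets(recordings[[ch]], threshold = threshold,
                         refractory = refractory, frame = frame, hop = hop)
    ons <- filter_spurious_onsets(ons)
    det <- align_to_triggers(ons$time[ons$accepted], trig, max_gap)
    chan_onset[[ch]] <- det
    unmatched[[ch]] <- sum(is.na(det))
    if (any(!is.na(det)))
      onset_lag_tables[[ch]] <-
        lag_summary((det[!is.na(det)] - trig[!is.na(det)]) * 1000, ch)
    dm <- markers$device_markers[[ch]]
    if (!is.null(dm)) {
      dev <- align_to_triggers(dm, trig, max_gap)
      chan_dev[[ch]] <- dev
      if (any(!is.na(dev)))
        lag_tables[[ch]] <-
          lag_summary((dev[!is.na(dev)] - trig[!is.na(dev)]) * 1000, ch)
      both <- !is.na(dev) & !is.na(det)
      if (any(both))
        marker_lag_tables[[ch]] <-
          lag_summary((dev[both] - det[both]) * 1000, paste0(ch, " marker"))
    }
  }
  asynchrony_tables <- list()
  regression <- NULL
  if (reference %in% names(chan_dev)) {
    ref <- chan_dev[[reference]]
    for (ch in setdiff(names(chan_dev), reference)) {
      both <- !is.na(ref) & !is.na(chan_dev[[ch]])
      if (any(both))
        asynchrony_tables[[ch]] <-
          asynchrony_summary(chan_dev[[ch]][both], ref[both], ch)
    }
    vib <- grep("vibration", names(chan_dev), value = TRUE)
    if (length(vib) == 1) {
      dev <- chan_dev[[vib]]; det <- chan_onset[[vib]]
      ok <- !is.na(dev) & !is.na(det) & !is.na(ref)
      if (sum(ok) >= 3 && stats::var(dev[ok] - det[ok]) > 0)
        regression <- regress_asynchrony_on_ramp(
          (dev[ok] - det[ok]) * 1000, (dev[ok] - ref[ok]) * 1000)
    }
  }
  rbind_or_null <- function(l) if (length(l)) do.call(rbind, l) else NULL
  structure(list(lag_tables = rbind_or_null(lag_tables),
                 onset_lag_tables = rbind_or_null(onset_lag_tables),
                 asynchrony_tables = rbind_or_null(asynchrony_tables),
                 marker_lag_tables = rbind_or_null(marker_lag_tables),
                 regression = regression,
                 onsets = chan_onset, device = chan_dev,
                 unmatched = unlist(unmatched)),
            class = "timing_analysis")
}

#' @export
print.timing_analysis <- function(x, ...) {
  if (!is.null(x$lag_tables)) {
    cat("Stimulus onset lag vs trigger, device markers (ms):\n")
    print(format(x$lag_tables, digits = 4), row.names = FALSE)
  }
  if (!is.null(x$onset_lag_tables)) {
    cat("Detected physical onset lag vs trigger (ms):\n")
    print(format(x$onset_lag_tables, digits = 4), row.names = FALSE)
  }
  if (!is.null(x$asynchrony_tables)) {
    cat("Asynchrony vs reference channel (ms):\n")
    print(format(x$asynchrony_tables, digits = 4), row.names = FALSE)
  }
  if (!is.null(x$marker_lag_tables)) {
    cat("Device marker lag vs detected onset (ms):\n")
    print(format(x$marker_lag_tables, digits = 4), row.names = FALSE)
  }
  if (!is.null(x$regression)) print(x$regression)
  if (any(x$unmatched > 0))
    cat("Unmatched triggers:",
        paste(names(x$unmatched), x$unmatched, sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}
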