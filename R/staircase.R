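#' Configuration of the 1-up-1-down intensity-matching staircase
#'
#' Parameters of the adaptive staircase used to match the perceived intensity
#' of a comparison stimulus (visual contrast or auditory volume) to a
#' reference vibration. Intensity is normalized to [0, 1]; the 5% step is a
#' fraction of that full range. The track terminates after
#' \code{max_reversals} reversals, \code{max_trials} trials, or when the
#' maximum intensity has been presented on every one of the last
#' \code{max_plateau_window} trials (ceiling plateau).
#'
#' @param start_value Initial comparison intensity in [min_value, max_value].
#' @param step Step size as a fraction of the intensity range, default 0.05.
#' @param min_value,max_value Intensity bounds, defaults 0 and 1.
#' @param max_reversals Reversal count terminating the track, default 8.
#' @param max_trials Trial count terminating the track, default 50.
#' @param max_plateau_window Number of trailing trials that must all sit at
#'   \code{max_value} to trigger the plateau rule, default 10.
#' @param n_reversals_for_pse Number of final reversals averaged for the PSE,
#'   default 6.
#' @return An object of class \code{"staircase_config"}.
#' @export
staircase_config <- function(start_value = 0.5, step = 0.05,
                             min_value = 0, max_value = 1,
                             max_reversals = 8, max_trials = 50,
                             max_plateau_window = 10,
                             n_reversals_for_pse = 6) {
  stopifnot(min_value < max_value, step > 0, step < max_value - min_value,
            start_value >= min_value, start_value <= max_value,
            max_reversals >= 1, max_trials >= 1, max_plateau_window >= 1,
            n_reversals_for_pse >= 1,
            n_reversals_for_pse <= max_reversals)
  structure(as.list(environment()), class = "staircase_config")
}

#' Start a new staircase track
#'
#' @param config A \code{\link{staircase_config}}.
#' @return A \code{"staircase_state"}: current value, per-trial history
#'   (presented value, response, intended direction), reversal values,
#'   direction, finished flag and termination reason.
#' @export
staircase_new <- function(config = staircase_config()) {
  stopifnot(inherits(config, "staircase_config"))
  structure(list(config = config,
                 current_value = config$start_value,
                 presented = numeric(0), responses = character(0),
                 directions = character(0),
                 reversal_values = numeric(0),
                 direction = "undefined",
                 finished = FALSE, termination_reason = NA_character_),
            class = "staircase_state")
}

#' Advance a staircase by one response
#'
#' Applies the 1-up-1-down rule: when the comparison is judged more intense
#' its intensity is decreased by one step; when the vibration is judged more
#' intense the comparison is increased. Values are clamped to the bounds. A
#' reversal is recorded when the intended movement direction flips relative
#' to the previous trial's; clamped moves at a bound count only through that
#' direction flip, not through the (unchanged) presented value.
#'
#' @param state A \code{"staircase_state"} that is not finished.
#' @param response One of \code{"comparison_more_intense"} or
#'   \code{"vibration_more_intense"}.
#' @return The updated state (with termination rules re-evaluated).
#' @examples
#' s <- staircase_new(staircase_config(start_value = 0.5))
#' s <- step_staircase(s, "comparison_more_intense")
#' s$current_value  # 0.45
#' @export
step_staircase <- function(state, response) {
  stopifnot(inherits(state, "staircase_state"))
  if (state$finished) stop("cannot step a finished staircase")
  response <- match.arg(response,
                        c("comparison_more_intense", "vibration_more_intense"))
  cfg <- state$config
  presented <- state$current_value
  dir <- if (response == "comparison_more_intense") "down" else "up"
  state$presented <- c(state$presented, presented)
  state$responses <- c(state$responses, response)
  state$directions <- c(state$directions, dir)
  if (state$direction != "undefined" && dir != state$direction)
    state$reversal_values <- c(state$reversal_values, presented)
  state$direction <- dir
  delta <- if (dir == "down") -cfg$step else cfg$step
  state$current_value <- min(cfg$max_value,
                             max(cfg$min_value, presented + delta))
  fin <- staircase_finished(state, cfg)
  state$finished <- fin$finished
  state$termination_reason <- fin$reason
  state
}

#' Check staircase termination rules
#'
#' Rules, in precedence order: (1) at least \code{max_reversals} reversals;
#' (2) at least \code{max_trials} trials; (3) the maximum intensity was
#' presented on all of the last \code{max_plateau_window} trials. The plateau
#' rule applies at the ceiling only (the floor case is not a stopping rule).
#'
#' @param state A \code{"staircase_state"}.
#' @param config A \code{\link{staircase_config}} (defaults to the state's).
#' @return List with \code{finished} (logical) and \code{reason} (one of
#'   \code{"reversals"}, \code{"trials"}, \code{"plateau"}, or NA).
#' @export
staircase_finished <- function(state, config = state$config) {
  n_trials <- length(state$presented)
  if (length(state$reversal_values) >= config$max_reversals)
    return(list(finished = TRUE, reason = "reversals"))
  if (n_trials >= config$max_trials)
    return(list(finished = TRUE, reason = "trials"))
  w <- config$max_plateau_window
  if (n_trials >= w &&
      all(state$presented[(n_trials - w + 1):n_trials] == config$max_value))
    return(list(finished = TRUE, reason = "plateau"))
  list(finished = FALSE, reason = NA_character_)
}

#' Point of subjective equality from terminal reversals
#'
#' Arithmetic mean of the final \code{n_reversals_for_pse} (default six)
#' reversal intensities. When the track terminated with fewer reversals than
#' that, all available reversals are averaged and the estimate is flagged as
#' degraded.
#'
#' @param state A \code{"staircase_state"} with at least one reversal.
#' @param config A \code{\link{staircase_config}} (defaults to the state's).
#' @return List with \code{pse}, \code{n_reversals_used}, \code{degraded}.
#' @export
pse_from_reversals <- function(state, config = state$config) {
  rv <- state$reversal_values
  if (length(rv) == 0)
    stop("cannot estimate PSE: the staircase produced no reversals (",
         length(state$presented), " trials, terminated by ",
         state$termination_reason, ")")
  k <- config$n_reversals_for_pse
  use <- if (length(rv) >= k) utils::tail(rv, k) else rv
  list(pse = mean(use), n_reversals_used = length(use),
       degraded = length(rv) < k)
}

#' Simulated observer for staircase recovery tests
#'
#' Psychometric model of a participant judging which stimulus is more
#' intense. The probability that the comparison is judged more intense at
#' intensity x is \code{lapse + (1 - 2*lapse) * plogis((x - pse)/slope)};
#' \code{slope = 0} gives a deterministic threshold observer (0.5 at
#' \code{x == pse}).
#'
#' @param pse True point of subjective equality, in [0, 1].
#' @param slope Logistic scale parameter in intensity units (>= 0).
#' @param lapse_rate Lapse probability in [0, 0.5].
#' @return An object of class \code{"simulated_observer"}.
#' @export
simulated_observer <- function(pse, slope = 0.05, lapse_rate = 0) {
  stopifnot(slope >= 0, lapse_rate >= 0, lapse_rate <= 0.5)
  structure(list(pse = pse, slope = slope, lapse_rate = lapse_rate),
            class = "simulated_observer")
}

p_comparison_more_intense <- function(observer, value) {
  base <- if (observer$slope == 0) {
    ifelse(value > observer$pse, 1, ifelse(value < observer$pse, 0, 0.5))
  } else {
    stats::plogis((value - observer$pse) / observer$slope)
  }
  observer$lapse_rate + (1 - 2 * observer$lapse_rate) * base
}

#' Run a full staircase against a simulated observer
#'
#' Loops the step / termination / estimation cycle with responses drawn from
#' the observer's psychometric function. Deterministic under a fixed seed.
#'
#' @param observer A \code{\link{simulated_observer}}.
#' @param config A \code{\link{staircase_config}}.
#' @param seed Optional integer seed set before the run.
#' @return An object of class \code{"staircase_run"}: \code{pse_estimate},
#'   \code{n_trials}, \code{termination_reason}, \code{n_reversals},
#'   \code{degraded}, plus the final \code{state}.
#' @examples
#' obs <- simulated_observer(pse = 0.6, slope = 0)
#' run_simulated_staircase(obs, staircase_config(start_value = 0.2), seed = 1)
#' @export
run_simulated_staircase <- function(observer, config = staircase_config(),
                                    seed = NULL) {
  stopifnot(inherits(observer, "simulated_observer"))
  if (!is.null(seed)) set.seed(seed)
  st <- staircase_new(config)
  while (!st$finished) {
    p <- p_comparison_more_intense(observer, st$current_value)
    resp <- if (stats::runif(1) < p) "comparison_more_intense" else
      "vibration_more_intense"
    st <- step_staircase(st, resp)
  }
  est <- if (length(st$reversal_values)) pse_from_reversals(st) else
    list(pse = NA_real_, n_reversals_used = 0L, degraded = TRUE)
  structure(list(pse_estimate = est$pse,
                 n_trials = length(st$presented),
                 termination_reason = st$termination_reason,
                 n_reversals = length(st$reversal_values),
                 degraded = est$degraded, state = st),
            class = "staircase_run")
}

#' @export
print.staircase_run <- function(x, ...) {
  cat(sprintf(
    "staircase run: PSE = %.3f after %d trials (%d reversals, stopped by %s%s)\n",
    x$pse_estimate, x$n_trials, x$n_reversals, x$termination_reason,
    if (x$degraded) ", degraded estimate" else ""))
  invisible(x)
}

#' Replicate staircase simulations
#'
#' Convenience harness: runs \code{n_reps} independent simulated staircases
#' and returns one row per replicate (the CLI's staircase-sim output shape).
#'
#' @param observer A \code{\link{simulated_observer}}.
#' @param config A \code{\link{staircase_config}}.
#' @param n_reps Number of replicates.
#' @param seed Seed for the whole batch.
#' @return Data frame: replicate, pse_estimate, n_trials, termination_reason,
#'   n_reversals, degraded.
#' @export
replicate_staircases <- function(observer, config = staircase_config(),
                                 n_reps = 500, seed = 1L) {
  set.seed(seed)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    r <- run_simulated_staircase(observer, config)
    rows[[i]] <- data.frame(replicate = i, pse_estimate = r$pse_estimate,
                            n_trials = r$n_trials,
                            termination_reason = r$termination_reason,
                            n_reversals = r$n_reversals,
                            degraded = r$degraded)
  }
  do.call(rbind, rows)
}
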