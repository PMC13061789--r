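#' Hierarchical LATER population parameters
#'
#' Defines the population from which simulated participants are drawn under
#' the LATER (Linear Approach to Threshold with Ergodic Rate) model. Each
#' trial's decision rate \eqn{v} is drawn from a participant-specific normal
#' distribution truncated at zero, with mean \eqn{\mu_i} and standard
#' deviation \eqn{\sigma_i}; the reaction time is \eqn{RT = 1/v}. Participant
#' means are drawn as \eqn{\mu_i \sim N(\mu_{base}, \sigma_\mu)} and
#' participant rate-SDs as \eqn{\sigma_i = |N(\sigma_{base}, \sigma_\sigma)|}.
#'
#' @param mu_base Population mean of the participant drift-rate means
#'   (1/seconds). Default 2.5 (corresponding to a 400 ms modal RT).
#' @param sigma_mu SD of participant drift-rate means (1/seconds), default 0.3.
#' @param sigma_base Population mean of the participant rate-SDs (1/seconds),
#'   default 0.4.
#' @param sigma_sigma SD of the participant rate-SDs (1/seconds), default 0.1.
#' @return An object of class \code{"later_population"}.
#' @examples
#' later_population()                  # defaults used throughout
#' later_population(2.5, 0, 0.4, 0)    # zero-variance hyperpriors
#' @export
later_population <- function(mu_base = 2.5, sigma_mu = 0.3,
                             sigma_base = 0.4, sigma_sigma = 0.1) {
  stopifnot(is.numeric(mu_base), length(mu_base) == 1L, mu_base > 0,
            is.numeric(sigma_mu), length(sigma_mu) == 1L, sigma_mu >= 0,
            is.numeric(sigma_base), length(sigma_base) == 1L, sigma_base > 0,
            is.numeric(sigma_sigma), length(sigma_sigma) == 1L,
            sigma_sigma >= 0)
  structure(list(mu_base = mu_base, sigma_mu = sigma_mu,
                 sigma_base = sigma_base, sigma_sigma = sigma_sigma),
            class = "later_population")
}

#' @export
print.later_population <- function(x, ...) {
  cat("LATER population (rates in 1/s):\n")
  cat(sprintf("  mu_i    ~ N(%g, %g)\n", x$mu_base, x$sigma_mu))
  cat(sprintf("  sigma_i ~ |N(%g, %g)|\n", x$sigma_base, x$sigma_sigma))
  invisible(x)
}

#' Draw simulated participants from a LATER population
#'
#' @param pop A \code{\link{later_population}}.
#' @param n Number of participants (>= 1).
#' @return A data frame with columns \code{mu_i} and \code{sigma_i}, one row
#'   per participant. \code{sigma_i} is the absolute value of a normal draw,
#'   so it is always >= 0.
#' @examples
#' set.seed(1)
#' draw_participants(later_population(), 20)
#' @export
draw_participants <- function(pop, n) {
  stopifnot(inherits(pop, "later_population"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  data.frame(
    mu_i = stats::rnorm(n, pop$mu_base, pop$sigma_mu),
    sigma_i = abs(stats::rnorm(n, pop$sigma_base, pop$sigma_sigma))
  )
}

# Vectorised truncated-normal rates by rejection: redraw nonpositive values.
# mu, sigma recycled against n. Truncation at zero leaves the positive tail
# undistorted, matching the model definition.
rtrunc_rate <- function(n, mu, sigma) {
  v <- stats::rnorm(n, mu, sigma)
  bad <- which(v <= 0)
  while (length(bad)) {
    v[bad] <- stats::rnorm(length(bad),
                           if (length(mu) > 1) mu[bad] else mu,
                           if (length(sigma) > 1) sigma[bad] else sigma)
    bad <- bad[v[bad] <= 0]
  }
  v
}

#' Simulate per-participant condition mean RTs under the LATER model
#'
#' For each participant, draws \code{n_trials} rates per condition from a
#' zero-truncated normal (control: mean \code{mu_i}; experimental: mean
#' \code{mu_i - delta_mu}), converts to reaction times \eqn{RT = 1/v}, adds
#' zero-mean Gaussian stimulus-onset noise per trial to both conditions, and
#' returns the per-participant mean RT in each condition.
#'
#' @param participants Data frame with columns \code{mu_i}, \code{sigma_i}
#'   (see \code{\link{draw_participants}}).
#' @param delta_mu Drift-rate decrement applied in the experimental condition
#'   (1/seconds, >= 0). Models slower evidence accumulation.
#' @param onset_noise_sd SD of per-trial stimulus-onset jitter, in
#'   milliseconds (converted to seconds before addition; RTs are not clipped).
#' @param n_trials Trials per condition per participant.
#' @return Data frame with columns \code{mean_control} and
#'   \code{mean_experimental} (seconds), one row per participant.
#' @examples
#' p <- data.frame(mu_i = 2.5, sigma_i = 0)
#' simulate_condition_means(p, delta_mu = 1.25, onset_noise_sd = 0,
#'                          n_trials = 10)  # means exactly 0.4 and 0.8 s
#' @export
simulate_condition_means <- function(participants, delta_mu = 0,
                                     onset_noise_sd = 0, n_trials = 100) {
  stopifnot(is.data.frame(participants),
            all(c("mu_i", "sigma_i") %in% names(participants)))
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1)
    stop("`n_trials` must be a positive count")
  if (delta_mu < 0) stop("`delta_mu` must be >= 0")
  mu_exp <- participants$mu_i - delta_mu
  if (any(mu_exp <= 0))
    stop("degenerate effect: mu_i - delta_mu must be > 0 for all participants")
  n_p <- nrow(participants)
  noise_sd_s <- onset_noise_sd / 1000
  one_cond <- function(mu) {
    v <- rtrunc_rate(n_p * n_trials, rep(mu, n_trials),
                     rep(participants$sigma_i, n_trials))
    rt <- 1 / v
    if (noise_sd_s > 0)
      rt <- rt + stats::rnorm(length(rt), 0, noise_sd_s)
    rowMeans(matrix(rt, nrow = n_p))
  }
  data.frame(mean_control = one_cond(participants$mu_i),
             mean_experimental = one_cond(mu_exp))
}

#' Convert a drift-rate decrement to an approximate RT shift
#'
#' Translates a drift-rate effect \code{delta_mu} into the RT-space slowdown
#' at the population mean rate:
#' \eqn{|1/\mu_{base} - 1/(\mu_{base} - \Delta\mu)| \times 1000} ms.
#' The decrement slows responding, so the returned magnitude is a slowdown.
#'
#' @param mu_base Baseline mean drift rate (1/seconds).
#' @param delta_mu Drift-rate decrement, with \code{0 <= delta_mu < mu_base}.
#' @return RT change in milliseconds (positive = slowdown).
#' @examples
#' delta_mu_to_rt_shift(2.5, 1.25)    # 400 ms
#' delta_mu_to_rt_shift(2.5, 0.0421)  # ~6.85 ms
#' @export
delta_mu_to_rt_shift <- function(mu_base, delta_mu) {
  stopifnot(is.numeric(mu_base), mu_base > 0, is.numeric(delta_mu))
  if (any(delta_mu < 0) || any(delta_mu >= mu_base))
    stop("`delta_mu` must satisfy 0 <= delta_mu < mu_base")
  abs(1 / mu_base - 1 / (mu_base - delta_mu)) * 1000
}
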