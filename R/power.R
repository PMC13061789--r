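#' Design of a LATER Monte Carlo power analysis
#'
#' Bundles the simulated experiment (participants, trials, onset jitter), the
#' effect grid and the Monte Carlo settings. Defaults mirror a typical remote
#' reaction-time study: 20 participants, 100 trials per condition, two-sided
#' Wilcoxon signed-rank on paired participant mean RTs at alpha = .05, and an
#' 80% power target.
#'
#' @param n_participants Simulated participants per replicate experiment.
#' @param n_trials Trials per condition per participant.
#' @param onset_noise_sd SD of per-trial stimulus-onset jitter, milliseconds.
#' @param delta_mu_grid Ordered, strictly increasing grid of drift-rate
#'   decrements (1/seconds, >= 0) at which power is estimated.
#' @param n_reps Monte Carlo replicate experiments per grid point.
#' @param alpha Significance level of the Wilcoxon test.
#' @param power_target Target power used by \code{\link{min_effect_at_power}}.
#' @param seed Top-level RNG seed; independent substreams are spawned per
#'   grid point so curves are reproducible point-by-point.
#' @param population A \code{\link{later_population}}.
#' @return An object of class \code{"power_design"}.
#' @export
power_design <- function(n_participants = 20, n_trials = 100,
                         onset_noise_sd = 0,
                         delta_mu_grid = seq(0, 0.08, by = 0.005),
                         n_reps = 10000, alpha = 0.05, power_target = 0.8,
                         seed = 1L, population = later_population()) {
  stopifnot(n_participants >= 2, n_trials >= 1, onset_noise_sd >= 0,
            n_reps >= 1, alpha > 0, alpha < 1,
            power_target > 0, power_target < 1)
  if (length(delta_mu_grid) < 1 || any(delta_mu_grid < 0) ||
      is.unsorted(delta_mu_grid, strictly = TRUE))
    stop("`delta_mu_grid` must be strictly increasing and >= 0")
  structure(list(n_participants = n_participants, n_trials = n_trials,
                 onset_noise_sd = onset_noise_sd,
                 delta_mu_grid = delta_mu_grid, n_reps = n_reps,
                 alpha = alpha, power_target = power_target,
                 seed = as.integer(seed), population = population),
            class = "power_design")
}

# Derive per-grid-point seeds from the design seed (kept below 2^31).
spawn_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Estimate power at one drift-rate decrement
#'
#' Runs \code{n_reps} replicate experiments. Each replicate draws a fresh set
#' of participants from the population (the hierarchy is part of the simulated
#' experiment), simulates paired condition mean RTs under the LATER model with
#' onset noise, and applies the two-sided Wilcoxon signed-rank test to the
#' paired participant means. Power is the proportion of replicates with
#' p < alpha; the Monte Carlo standard error is \eqn{\sqrt{p(1-p)/n_{reps}}}.
#'
#' @param design A \code{\link{power_design}}.
#' @param delta_mu Drift-rate decrement (1/seconds, >= 0).
#' @param seed Optional seed for this grid point; defaults to the design seed.
#' @return A list with \code{delta_mu}, \code{power}, \code{mc_se},
#'   \code{n_reps}.
#' @export
estimate_power <- function(design, delta_mu, seed = design$seed) {
  stopifnot(inherits(design, "power_design"), delta_mu >= 0)
  set.seed(seed)
  n_p <- design$n_participants
  n_t <- design$n_trials
  pop <- design$population
  noise_sd_s <- design$onset_noise_sd / 1000
  reps_left <- design$n_reps
  chunk <- 250L
  n_sig <- 0L
  while (reps_left > 0L) {
    b <- min(chunk, reps_left)
    # fresh participants every replicate: b x n_p hierarchical draws
    mu_i <- matrix(stats::rnorm(b * n_p, pop$mu_base, pop$sigma_mu), b, n_p)
    sg_i <- matrix(abs(stats::rnorm(b * n_p, pop$sigma_base,
                                    pop$sigma_sigma)), b, n_p)
    if (any(mu_i - delta_mu <= 0))
      stop("degenerate effect: mu_i - delta_mu must be > 0")
    cond_mean <- function(mu) {
      v <- rtrunc_rate(b * n_p * n_t, rep(mu, n_t), rep(sg_i, n_t))
      rt <- 1 / v
      if (noise_sd_s > 0) rt <- rt + stats::rnorm(length(rt), 0, noise_sd_s)
      # dims (b*n_p) x n_t -> mean over trials
      rowMeans(matrix(rt, nrow = b * n_p))
    }
    m_ctl <- matrix(cond_mean(mu_i), b, n_p)
    m_exp <- matrix(cond_mean(mu_i - delta_mu), b, n_p)
    p <- wilcoxon_p_rows(m_ctl - m_exp)
    n_sig <- n_sig + sum(p < design$alpha)
    reps_left <- reps_left - b
  }
  pw <- n_sig / design$n_reps
  list(delta_mu = delta_mu, power = pw,
       mc_se = sqrt(pw * (1 - pw) / design$n_reps), n_reps = design$n_reps)
}

#' Empirical power curve over the design's effect grid
#'
#' Estimates power at every \code{delta_mu} on the design grid, spawning an
#' independent RNG substream per grid point from the design seed, and
#' interpolates the minimum detectable effect at the design's power target
#' when it is bracketed.
#'
#' @param design A \code{\link{power_design}}.
#' @return An object of class \code{"later_power_curve"}: a list with
#'   \code{points} (data frame: delta_mu, power, mc_se, n_reps),
#'   \code{design}, and \code{delta_mu_star} (NA when the target power is not
#'   bracketed by the grid).
#' @examples
#' \donttest{
#' d <- power_design(n_reps = 500, delta_mu_grid = seq(0, 0.08, 0.01))
#' pc <- power_curve(d)
#' print(pc)
#' }
#' @export
power_curve <- function(design) {
  stopifnot(inherits(design, "power_design"))
  grid <- design$delta_mu_grid
  seeds <- spawn_seeds(design$seed, length(grid))
  pts <- vector("list", length(grid))
  for (i in seq_along(grid))
    pts[[i]] <- as.data.frame(estimate_power(design, grid[i], seeds[i]))
  pts <- do.call(rbind, pts)
  out <- structure(list(points = pts, design = design,
                        delta_mu_star = NA_real_),
                   class = "later_power_curve")
  star <- try(min_effect_at_power(out, design$power_target), silent = TRUE)
  if (!inherits(star, "try-error")) out$delta_mu_star <- star
  out
}

#' Minimum effect achieving a target power
#'
#' Piecewise-linear interpolation on (delta_mu, power): returns the
#' interpolated delta_mu between the first adjacent grid pair bracketing the
#' target. A grid point landing exactly on the target is returned as is.
#'
#' @param curve A \code{"later_power_curve"}.
#' @param target Target power, within the curve's achieved power range.
#' @return The interpolated drift-rate decrement (1/seconds).
#' @examples
#' pts <- data.frame(delta_mu = c(0, 0.1), power = c(0.05, 1),
#'                   mc_se = 0, n_reps = 1)
#' curve <- structure(list(points = pts), class = "later_power_curve")
#' min_effect_at_power(curve, 0.8)  # 0.0789...
#' @export
min_effect_at_power <- function(curve, target) {
  stopifnot(inherits(curve, "later_power_curve"))
  pts <- curve$points
  if (nrow(pts) < 2) stop("power curve needs at least 2 points")
  hit <- which(pts$power == target)
  if (length(hit)) return(pts$delta_mu[hit[1]])
  for (i in seq_len(nrow(pts) - 1)) {
    p0 <- pts$power[i]; p1 <- pts$power[i + 1]
    if ((p0 < target && p1 > target) || (p0 > target && p1 < target)) {
      w <- (target - p0) / (p1 - p0)
      return(pts$delta_mu[i] + w * (pts$delta_mu[i + 1] - pts$delta_mu[i]))
    }
  }
  stop(sprintf(
    "target power %.3f not bracketed: achieved power range [%.3f, %.3f]",
    target, min(pts$power), max(pts$power)))
}

#' @export
print.later_power_curve <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "LATER Monte Carlo power curve (%d participants x %d trials/condition,\n",
    d$n_participants, d$n_trials))
  cat(sprintf("  onset noise SD %g ms, %d reps/point, alpha = %g)\n",
              d$onset_noise_sd, d$n_reps, d$alpha))
  print(x$points, row.names = FALSE, digits = 4)
  if (!is.na(x$delta_mu_star))
    cat(sprintf(
      "Minimum effect for %.0f%% power: delta_mu* = %.4f (~%.2f ms RT shift)\n",
      100 * d$power_target, x$delta_mu_star,
      delta_mu_to_rt_shift(d$population$mu_base, x$delta_mu_star)))
  invisible(x)
}

#' @export
summary.later_power_curve <- function(object, ...) {
  d <- object$design
  out <- list(
    delta_mu_star = object$delta_mu_star,
    rt_shift_ms = if (is.na(object$delta_mu_star)) NA_real_ else
      delta_mu_to_rt_shift(d$population$mu_base, object$delta_mu_star),
    power_target = d$power_target,
    onset_noise_sd = d$onset_noise_sd,
    n_reps = d$n_reps)
  class(out) <- "summary.later_power_curve"
  out
}

#' @export
print.summary.later_power_curve <- function(x, ...) {
  cat(sprintf("delta_mu* = %.4f at %.0f%% power (onset noise %g ms)\n",
              x$delta_mu_star, 100 * x$power_target, x$onset_noise_sd))
  cat(sprintf("approximate RT shift: %.2f ms\n", x$rt_shift_ms))
  invisible(x)
}

#' @export
plot.later_power_curve <- function(x, ...) {
  pts <- x$points
  graphics::plot(pts$delta_mu, pts$power, type = "b", pch = 16,
                 xlab = expression(Delta * mu ~ "(1/s)"),
                 ylab = "Empirical power", ylim = c(0, 1), ...)
  graphics::abline(h = x$design$power_target, lty = 2)
  if (!is.na(x$delta_mu_star))
    graphics::abline(v = x$delta_mu_star, lty = 3)
  invisible(x)
}
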