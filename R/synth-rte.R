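#' Configuration of the synthetic redundant-target trial generator
#'
#' Emulates the remote RTE session: per participant, 30 catch trials with no
#' target plus 10 trials of each of the 7 target conditions (100 trials
#' total), a 1.7-s response window, and trial RTs contaminated at low rates
#' with anticipations, slow outliers and misses. Per-condition means and SDs
#' default to the published group table for this paradigm (between-participant
#' values, seconds); participant condition means are drawn from a correlated
#' multivariate normal around them.
#'
#' @param n_participants Number of participants, default 32.
#' @param composition Named counts of trials per condition per participant.
#' @param cond_means,cond_sds Named per-condition mean/SD of participant-level
#'   mean RTs, seconds (names must cover the 7 target conditions).
#' @param within_correlation Correlation of a participant's condition means
#'   across conditions, default 0.8.
#' @param trial_sd Within-participant trial-to-trial SD, seconds, default 0.1.
#' @param anticipation_rate Probability a target trial is replaced by a fast
#'   guess (uniform on 0-0.09 s), default 0.02.
#' @param slow_outlier_rate Probability of a slow outlier (uniform on 1.05 s
#'   to the response window), default 0.02.
#' @param miss_rate Probability of no response on a target trial, default
#'   0.02.
#' @param response_window Response deadline in seconds, default 1.7.
#' @return An object of class \code{"rte_gen_config"}.
#' @export
rte_gen_config <- function(n_participants = 32,
                           composition = c(none = 30, V = 10, A = 10, T = 10,
                                           AV = 10, VT = 10, AT = 10,
                                           AVT = 10),
                           cond_means = c(V = 0.476, A = 0.514, T = 0.478,
                                          AV = 0.431, VT = 0.412, AT = 0.432,
                                          AVT = 0.403),
                           cond_sds = c(V = 0.093, A = 0.140, T = 0.097,
                                        AV = 0.100, VT = 0.092, AT = 0.113,
                                        AVT = 0.114),
                           within_correlation = 0.8, trial_sd = 0.1,
                           anticipation_rate = 0.02,
                           slow_outlier_rate = 0.02, miss_rate = 0.02,
                           response_window = 1.7) {
  targets <- setdiff(rte_conditions(), "none")
  stopifnot(n_participants >= 1,
            all(names(composition) %in% rte_conditions()),
            all(targets %in% names(cond_means)),
            all(targets %in% names(cond_sds)),
            within_correlation >= 0, within_correlation < 1,
            trial_sd > 0, response_window > 1,
            anticipation_rate >= 0, anticipation_rate <= 1,
            slow_outlier_rate >= 0, slow_outlier_rate <= 1,
            miss_rate >= 0, miss_rate <= 1,
            anticipation_rate + slow_outlier_rate + miss_rate <= 1)
  structure(as.list(environment())[c(
    "n_participants", "composition", "cond_means", "cond_sds",
    "within_correlation", "trial_sd", "anticipation_rate",
    "slow_outlier_rate", "miss_rate", "response_window")],
    class = "rte_gen_config")
}

#' Generate a synthetic redundant-target trial table with ground truth
#'
#' Participant condition means are drawn from a multivariate normal around
#' the configured means with equicorrelated covariance
#' (\code{sd_j sd_k (rho + (1-rho) I)}); trial RTs are normal around the
#' participant mean with SD \code{trial_sd}, then contaminated at the
#' configured rates. Catch trials carry no response. Deterministic under the
#' seed.
#'
#' @param config An \code{\link{rte_gen_config}}.
#' @param seed Integer seed.
#' @return List with \code{trials} (data frame: participant, condition, rt,
#'   responded, contaminant) and \code{truth} (participant-by-condition
#'   matrix of generating means plus the config).
#' @export
gen_rte_trials <- function(config = rte_gen_config(), seed = 1L) {
  stopifnot(inherits(config, "rte_gen_config"))
  set.seed(seed)
  targets <- setdiff(rte_conditions(), "none")
  mu <- config$cond_means[targets]
  sd_ <- config$cond_sds[targets]
  rho <- config$within_correlation
  k <- length(targets)
  sigma <- outer(sd_, sd_) * (rho + (1 - rho) * diag(k))
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-12)) stop("infeasible covariance for participant means")
  pm <- MASS::mvrnorm(config$n_participants, mu, sigma)
  if (config$n_participants == 1) pm <- matrix(pm, 1)
  dimnames(pm) <- list(sprintf("p%02d", seq_len(config$n_participants)),
                       targets)
  comp <- config$composition
  rows <- vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    conds <- rep(names(comp), comp)
    rt <- rep(NA_real_, length(conds))
    responded <- rep(FALSE, length(conds))
    contaminant <- rep("none_trial", length(conds))
    for (j in which(conds != "none")) {
      u <- stats::runif(1)
      if (u < config$miss_rate) {
        contaminant[j] <- "miss"
      } else if (u < config$miss_rate + config$anticipation_rate) {
        rt[j] <- stats::runif(1, 0, 0.09)
        responded[j] <- TRUE
        contaminant[j] <- "anticipation"
      } else if (u < config$miss_rate + config$anticipation_rate +
                 config$slow_outlier_rate) {
        rt[j] <- stats::runif(1, 1.05, config$response_window)
        responded[j] <- TRUE
        contaminant[j] <- "slow_outlier"
      } else {
        rt[j] <- stats::rnorm(1, pm[i, conds[j]], config$trial_sd)
        responded[j] <- TRUE
        contaminant[j] <- "clean"
      }
    }
    rows[[i]] <- data.frame(participant = rownames(pm)[i],
                            condition = conds, rt = rt,
                            responded = responded,
                            contaminant = contaminant)
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  list(trials = trials,
       truth = list(participant_means = pm, config = config, seed = seed))
}
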