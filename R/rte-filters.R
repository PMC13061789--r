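#' Condition codes of the redundant-target task
#'
#' Seven target conditions (unimodal visual/auditory/tactile, the three
#' bimodal pairs, and the trimodal combination) plus catch trials with no
#' target.
#' @return Character vector of the eight condition codes.
#' @export
rte_conditions <- function() c("V", "A", "T", "AV", "VT", "AT", "AVT", "none")

check_trials <- function(trials) {
  need <- c("participant", "condition", "rt", "responded")
  if (!is.data.frame(trials) || !all(need %in% names(trials)))
    stop("`trials` must be a data frame with columns: ",
         paste(need, collapse = ", "))
  bad <- setdiff(unique(as.character(trials$condition)), rte_conditions())
  if (length(bad))
    stop("unknown condition codes: ", paste(bad, collapse = ", "))
  invisible(trials)
}

#' Filter reaction times by range and per-cell deviation
#'
#' Two fixed-order stages applied to responded target trials. Stage 1 removes
#' reaction times below 0.100 s (anticipations) or above 1.000 s (delayed
#' responses). Stage 2, on the survivors, removes trials deviating from their
#' participant-by-condition cell mean by more than 2.5 sample standard
#' deviations (single pass, n-1 denominator). Catch ("none") trials and
#' misses are tabulated in the report but excluded from the RT analysis.
#'
#' @param trials Data frame with columns \code{participant},
#'   \code{condition}, \code{rt} (seconds, NA when no response),
#'   \code{responded} (logical).
#' @param sd_criterion Deviation criterion in SD units, default 2.5.
#' @return List with \code{trials} (retained rows) and \code{report}: a data
#'   frame per participant x condition with columns \code{n_input},
#'   \code{n_removed_fast}, \code{n_removed_slow}, \code{n_removed_sd},
#'   \code{n_retained}, plus attributes \code{n_misses} and
#'   \code{n_none_trials}.
#' @examples
#' tr <- data.frame(participant = "p1", condition = "V",
#'                  rt = c(0.05, 0.3, 0.95, 1.2), responded = TRUE)
#' apply_rt_filters(tr)$trials$rt  # 0.30 0.95
#' @export
apply_rt_filters <- function(trials, sd_criterion = 2.5) {
  check_trials(trials)
  trials$condition <- as.character(trials$condition)
  is_target <- trials$condition != "none"
  misses <- is_target & !trials$responded
  analysed <- trials[is_target & trials$responded & !is.na(trials$rt), ,
                     drop = FALSE]
  cell <- interaction(analysed$participant, analysed$condition, drop = TRUE)

  fast <- analysed$rt < 0.100
  slow <- analysed$rt > 1.000
  stage1 <- analysed[!fast & !slow, , drop = FALSE]
  cell1 <- interaction(stage1$participant, stage1$condition, drop = TRUE)

  # stage 2: single pass, per participant x condition, sample SD
  keep <- rep(TRUE, nrow(stage1))
  for (lv in levels(cell1)) {
    idx <- which(cell1 == lv)
    if (length(idx) < 2) next                    # SD undefined, keep all
    m <- mean(stage1$rt[idx]); s <- stats::sd(stage1$rt[idx])
    if (s == 0) next
    keep[idx] <- abs(stage1$rt[idx] - m) <= sd_criterion * s
  }
  retained <- stage1[keep, , drop = FALSE]

  cells <- unique(data.frame(participant = analysed$participant,
                             condition = analysed$condition))
  cells <- cells[order(cells$participant, cells$condition), , drop = FALSE]
  count_in <- function(df, p, co)
    sum(df$participant == p & df$condition == co)
  report <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    p <- cells$participant[i]; co <- cells$condition[i]
    in_cell <- analysed$participant == p & analysed$condition == co
    n_in <- sum(in_cell)
    n_f <- sum(in_cell & fast)
    n_s <- sum(in_cell & slow)
    n_ret <- count_in(retained, p, co)
    if (n_in - n_f - n_s == 0)
      warning(sprintf("cell %s x %s empty after range filter", p, co),
              call. = FALSE)
    data.frame(participant = p, condition = co, n_input = n_in,
               n_removed_fast = n_f, n_removed_slow = n_s,
               n_removed_sd = n_in - n_f - n_s - n_ret,
               n_retained = n_ret)
  }))
  rownames(report) <- NULL
  attr(report, "n_misses") <- sum(misses)
  attr(report, "n_none_trials") <- sum(!is_target)
  attr(report, "n_none_responses") <- sum(!is_target & trials$responded)
  list(trials = retained, report = report)
}

#' Per-condition group summaries of reaction times
#'
#' Participant-level condition means are computed first; the group mean, SD
#' and SE are then taken over participants, so \code{n} counts participants
#' (the shape of a published condition-summary table). Conditions with no
#' participants are omitted with a warning; a single-participant condition
#' reports an undefined (NA) SD.
#'
#' @param trials Retained trials (see \code{\link{apply_rt_filters}}).
#' @param conditions Conditions to summarise, default the seven target codes.
#' @return Data frame: condition, n, mean, sd, se (seconds).
#' @export
condition_summary <- function(trials,
                              conditions = setdiff(rte_conditions(), "none")) {
  check_trials(trials)
  out <- lapply(conditions, function(co) {
    sub <- trials[trials$condition == co & trials$responded &
                    !is.na(trials$rt), , drop = FALSE]
    if (!nrow(sub)) {
      warning(sprintf("condition %s has no participants; omitted", co),
              call. = FALSE)
      return(NULL)
    }
    pm <- tapply(sub$rt, sub$participant, mean)
    pm <- pm[!is.na(pm)]
    n <- length(pm)
    s <- if (n > 1) stats::sd(pm) else NA_real_
    data.frame(condition = co, n = n, mean = mean(pm), sd = s,
               se = s / sqrt(n))
  })
  do.call(rbind, out)
}

#' Participant-by-condition matrix of mean reaction times
#'
#' Pivots retained trials into the complete participants x conditions matrix
#' consumed by \code{\link{rm_anova_gg}}. Errors if any cell is empty,
#' instructing listwise deletion upstream.
#'
#' @inheritParams condition_summary
#' @return Numeric matrix, rows = participants, columns = conditions.
#' @export
participant_condition_matrix <- function(trials,
                                         conditions = setdiff(rte_conditions(),
                                                              "none")) {
  check_trials(trials)
  parts <- sort(unique(trials$participant))
  m <- matrix(NA_real_, length(parts), length(conditions),
              dimnames = list(as.character(parts), conditions))
  for (co in conditions) {
    sub <- trials[trials$condition == co, , drop = FALSE]
    pm <- tapply(sub$rt, sub$participant, mean)
    m[names(pm), co] <- pm
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("empty participant x condition cells (e.g. ",
         rownames(m)[bad[1, 1]], " x ", conditions[bad[1, 2]],
         "); remove incomplete participants upstream (listwise deletion)")
  }
  m
}
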