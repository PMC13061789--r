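#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical univariate repeated-measures ANOVA on a complete participants x
#' conditions matrix of mean reaction times. Sums of squares are partitioned
#' into condition, subject and error terms; the Greenhouse-Geisser epsilon is
#' estimated from the sample covariance of the condition columns and applied
#' to both degrees of freedom; Mauchly's sphericity test is computed from the
#' orthonormal-contrast covariance with the standard chi-square
#' approximation. Both classical eta-squared (SS_cond / SS_total) and partial
#' eta-squared (SS_cond / (SS_cond + SS_error)) are reported, since published
#' analyses differ in which variant they print.
#'
#' @param m Numeric matrix, rows = participants (>= 3), columns = conditions
#'   (>= 2), no missing cells.
#' @param pairwise Logical; also run Holm-corrected pairwise paired t-tests
#'   (see \code{\link{holm_pairwise}}). Default TRUE.
#' @return An object of class \code{"rte_anova"}: F statistic, uncorrected
#'   and GG-corrected dfs and p-values, \code{epsilon_gg}, Mauchly W and p,
#'   both effect sizes, the SS partition, and (optionally) the pairwise
#'   table.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(15, 0.45, 0.05), 5, 3)
#' rm_anova_gg(m)
#' @export
rm_anova_gg <- function(m, pairwise = TRUE) {
  m <- as.matrix(m)
  if (anyNA(m))
    stop("missing cells: apply listwise deletion upstream")
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("need >= 3 participants")
  if (k < 2) stop("need >= 2 conditions")
  g <- mean(m)
  cm <- colMeans(m)
  rm_ <- rowMeans(m)
  ss_cond <- n * sum((cm - g)^2)
  ss_subj <- k * sum((rm_ - g)^2)
  ss_tot <- sum((m - g)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  # a zero effect SS is F = 0 even when the error SS is also zero
  f <- if (ss_cond == 0) 0 else (ss_cond / df1) / (ss_err / df2)

  # Greenhouse-Geisser epsilon from the sample covariance of conditions
  s <- stats::cov(m)
  sbar <- mean(s)
  dbar <- mean(diag(s))
  rbar <- rowMeans(s)
  eps <- (k^2 * (dbar - sbar)^2) /
    ((k - 1) * (sum(s^2) - 2 * k * sum(rbar^2) + k^2 * sbar^2))
  if (!is.finite(eps)) eps <- 1   # degenerate (e.g. constant) covariance
  eps <- min(1, max(1 / (k - 1), eps))

  # Mauchly's sphericity test on the contrast space orthogonal to the
  # intercept (stats::mauchly.test); undefined when the contrast covariance
  # is singular (fewer participants than conditions)
  if (k > 2 && n > k - 1) {
    mt <- tryCatch(stats::mauchly.test(stats::lm(m ~ 1), X = ~1),
                   error = function(e) NULL)
    if (!is.null(mt) && is.finite(mt$statistic)) {
      w <- unname(mt$statistic); mauchly_p <- mt$p.value
    } else {
      w <- NA_real_; mauchly_p <- NA_real_
    }
  } else if (k == 2) {
    w <- 1; mauchly_p <- NA_real_
  } else {
    w <- NA_real_; mauchly_p <- NA_real_
  }

  out <- structure(list(
    f_value = f,
    df_effect = df1, df_error = df2,
    p_uncorrected = stats::pf(f, df1, df2, lower.tail = FALSE),
    epsilon_gg = eps,
    df_effect_gg = eps * df1, df_error_gg = eps * df2,
    p_value = stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE),
    eta_squared = ss_cond / ss_tot,
    partial_eta_squared = ss_cond / (ss_cond + ss_err),
    mauchly_w = w, mauchly_p = mauchly_p,
    ss = c(condition = ss_cond, subject = ss_subj, error = ss_err,
           total = ss_tot),
    n_participants = n, n_conditions = k,
    pairwise = NULL), class = "rte_anova")
  if (pairwise) out$pairwise <- holm_pairwise(m)
  out
}

#' Holm-corrected pairwise paired t-tests
#'
#' All condition pairs are compared with two-sided paired t-tests on the
#' participant-level means; p-values are adjusted with Holm's step-down
#' procedure (\code{stats::p.adjust}), which keeps adjusted p-values monotone
#' in the raw ranking.
#'
#' @param m Participants x conditions matrix as in \code{\link{rm_anova_gg}}.
#' @return Data frame: pair, mean_diff, t, df, p_raw, p_holm, ordered by
#'   column pairs.
#' @export
holm_pairwise <- function(m) {
  m <- as.matrix(m)
  k <- ncol(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(k))
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tt <- stats::t.test(m[, i1], m[, i2], paired = TRUE)
    data.frame(pair = paste(colnames(m)[i1], colnames(m)[i2], sep = " - "),
               mean_diff = mean(m[, i1] - m[, i2]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_raw, method = "holm")
  out
}

#' @export
print.rte_anova <- function(x, digits = 4, ...) {
  cat("Repeated-measures ANOVA (", x$n_participants, " participants x ",
      x$n_conditions, " conditions)\n", sep = "")
  cat(sprintf("  F(%.3f, %.3f) = %.3f, p = %.4g  [Greenhouse-Geisser, eps = %.3f]\n",
              x$df_effect_gg, x$df_error_gg, x$f_value, x$p_value,
              x$epsilon_gg))
  cat(sprintf("  uncorrected: F(%d, %d), p = %.4g\n",
              x$df_effect, x$df_error, x$p_uncorrected))
  cat(sprintf("  eta^2 = %.3f, partial eta^2 = %.3f\n",
              x$eta_squared, x$partial_eta_squared))
  if (!is.na(x$mauchly_p))
    cat(sprintf("  Mauchly W = %.3f, p = %.4g\n", x$mauchly_w, x$mauchly_p))
  if (!is.null(x$pairwise)) {
    cat("Holm-corrected pairwise comparisons:\n")
    print(format(x$pairwise, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Full redundant-target analysis pipeline
#'
#' Convenience wrapper: range and deviation filtering, per-condition group
#' summaries, the participants x conditions matrix, and the GG-corrected
#' repeated-measures ANOVA with Holm pairwise table.
#'
#' @inheritParams apply_rt_filters
#' @return List of class \code{"rte_analysis"} with \code{filter_report},
#'   \code{summary} (condition table), \code{matrix} and \code{anova}.
#' @export
rte_analyze <- function(trials, sd_criterion = 2.5) {
  flt <- apply_rt_filters(trials, sd_criterion = sd_criterion)
  m <- participant_condition_matrix(flt$trials)
  structure(list(filter_report = flt$report,
                 summary = condition_summary(flt$trials),
                 matrix = m,
                 anova = rm_anova_gg(m)),
            class = "rte_analysis")
}

#' @export
print.rte_analysis <- function(x, ...) {
  cat("Condition summaries (seconds, n = participants):\n")
  print(format(x$summary, digits = 3), row.names = FALSE)
  cat("\n")
  print(x$anova)
  invisible(x)
}
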