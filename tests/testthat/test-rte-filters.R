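test_that("the range filter removes anticipations and late responses", {
  tr <- make_trials("p1", "V", c(0.05, 0.3, 0.95, 1.2))
  out <- apply_rt_filters(tr)
  expect_equal(sort(out$trials$rt), c(0.3, 0.95))
  expect_equal(out$report$n_removed_fast, 1L)
  expect_equal(out$report$n_removed_slow, 1L)
  expect_equal(out$report$n_removed_sd, 0L)
  # re-running the range filter removes nothing (idempotence)
  out2 <- apply_rt_filters(out$trials)
  expect_equal(nrow(out2$trials), nrow(out$trials))
})

test_that("the 2.5 SD rule removes exactly the constructed outlier", {
  rts <- c(rep(0.30, 10), 0.90)
  # worked example: deviation 0.545 > 2.5 x sample SD 0.181
  expect_gt(abs(0.90 - mean(rts)), 2.5 * sd(rts))
  tr <- make_trials("p1", "T", rts)
  out <- apply_rt_filters(tr)
  expect_equal(nrow(out$trials), 10L)
  expect_false(0.90 %in% out$trials$rt)
  expect_equal(out$report$n_removed_sd, 1L)

  # identical RTs: SD = 0, nothing removed in stage 2
  tr <- make_trials("p1", "A", rep(0.4, 8))
  expect_equal(nrow(apply_rt_filters(tr)$trials), 8L)
})

test_that("filters are per participant x condition and counts are additive", {
  set.seed(14)
  tr <- rbind(
    make_trials("p1", "V", c(rnorm(10, 0.3, 0.01), 0.9)),
    make_trials("p2", "V", rnorm(10, 0.9, 0.01)),     # own cell: all retained
    make_trials("p1", "A", c(0.05, 1.5, rnorm(8, 0.5, 0.02))))
  out <- apply_rt_filters(tr)
  rep_ <- out$report
  expect_true(all(rep_$n_input == rep_$n_removed_fast + rep_$n_removed_slow +
                    rep_$n_removed_sd + rep_$n_retained))
  p2 <- rep_[rep_$participant == "p2" & rep_$condition == "V", ]
  expect_equal(p2$n_retained, 10L)  # 0.9 s is normal for p2, outlier for p1
  p1v <- rep_[rep_$participant == "p1" & rep_$condition == "V", ]
  expect_equal(p1v$n_removed_sd, 1L)
})

test_that("misses and catch trials are tabulated but not analysed", {
  tr <- rbind(make_trials("p1", "V", c(0.4, NA), responded = c(TRUE, FALSE)),
              make_trials("p1", "none", c(NA, NA), responded = FALSE))
  out <- apply_rt_filters(tr)
  expect_equal(nrow(out$trials), 1L)
  expect_equal(attr(out$report, "n_misses"), 1L)
  expect_equal(attr(out$report, "n_none_trials"), 2L)
})

test_that("condition summaries are participant-level means first", {
  tr <- rbind(make_trials("p1", "V", c(0.35, 0.45)),  # participant mean 0.4
              make_trials("p2", "V", c(0.5, 0.5)))    # participant mean 0.5
  s <- condition_summary(tr, "V")
  expect_equal(s$n, 2L)
  expect_equal(s$mean, 0.45)
  expect_equal(s$sd, sd(c(0.4, 0.5)))
  expect_equal(s$se, s$sd / sqrt(2))

  # single participant: SD undefined
  s1 <- condition_summary(make_trials("p1", "A", 0.5), "A")
  expect_true(is.na(s1$sd))

  expect_warning(condition_summary(tr, c("V", "T")), "no participants")
})

test_that("the participant x condition matrix demands complete cells", {
  tr <- rbind(make_trials("p1", "V", 0.4), make_trials("p1", "A", 0.5),
              make_trials("p2", "V", 0.45))
  expect_error(participant_condition_matrix(tr, c("V", "A")), "listwise")
  tr2 <- rbind(tr, make_trials("p2", "A", 0.55))
  m <- participant_condition_matrix(tr2, c("V", "A"))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["p2", "A"], 0.55)
})
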