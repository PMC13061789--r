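test_that("marker-onset matching pairs nearest onsets within the window", {
  ons <- data.frame(time = c(0.97, 1.99), accepted = TRUE,
                    envelope_at_onset = 0)
  got <- match_markers_to_onsets(c(1.00, 2.00), ons)
  expect_equal(got$matched$lag, c(0.03, 0.01))
  expect_equal(length(got$unmatched), 0L)

  # a marker with nothing nearby is reported unmatched, not fatal
  got <- match_markers_to_onsets(c(1.00, 5.00), ons, max_gap = 0.15)
  expect_equal(got$unmatched, 5.00)
  expect_equal(nrow(got$matched), 1L)
})

test_that("lag tables use linear-interpolation percentiles and order them", {
  t1 <- lag_summary(rep(30, 5), "constant")
  expect_equal(t1$mean, 30); expect_equal(t1$sd, 0)
  expect_true(all(unlist(t1[c("min", "p25", "p50", "p75", "max")]) == 30))

  t2 <- lag_summary(c(10, 20, 30, 40), "spread")
  expect_equal(t2$p50, 25)
  expect_equal(t2$p25, 17.5)  # type-7 linear interpolation
  q <- unlist(t2[c("min", "p25", "p50", "p75", "max")])
  expect_true(all(diff(q) >= 0))

  expect_error(lag_summary(numeric(0)), "no lags")
})

test_that("asynchrony is channel minus reference, per paired trial", {
  t3 <- asynchrony_summary(c(1.040, 2.043), c(1.000, 2.001), "sound")
  expect_equal(t3$mean, mean(c(40, 42)))
  expect_error(asynchrony_summary(1:3, 1:2), "paired")
})

test_that("the ramp regression recovers an exact line and rejects noise", {
  x <- seq(20, 40, length.out = 50)
  y <- 0.342 * x + 32.23
  # lm warns about the (intentionally) perfect fit
  r <- suppressWarnings(regress_asynchrony_on_ramp(x, y))
  expect_equal(r$slope, 0.342, tolerance = 1e-12)
  expect_equal(r$intercept, 32.23, tolerance = 1e-10)
  expect_equal(r$r_squared, 1)

  # permuted responses: slope near zero on average
  set.seed(41)
  slopes <- replicate(200, {
    regress_asynchrony_on_ramp(x, sample(y))$slope
  })
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(200))

  expect_error(regress_asynchrony_on_ramp(rep(1, 10), rnorm(10)),
               "degenerate")
  expect_error(regress_asynchrony_on_ramp(1:2, 1:2), "at least 3")
})

test_that("session analysis recovers generator lags end to end", {
  cfg <- session_gen_config(n_trials = 60, sample_rate = 22050)
  sess <- gen_session_recording(cfg, seed = 9)
  res <- analyze_session(sess$recordings, sess$markers)

  # device-marker lag tables: closed-form expectations from the config
  lt <- res$lag_tables
  expect_equal(sort(lt$event), sort(c("light", "sound", "vibration_mic")))
  for (ch in c("light", "sound")) {
    row <- lt[lt$event == ch, ]
    expected <- cfg$lag_ms[[ch]][1]
    expect_lt(abs(row$mean - expected), 3 * row$sd / sqrt(row$n_events))
  }
  vib <- lt[lt$event == "vibration_mic", ]
  expected_vib <- cfg$lag_ms$vibration_mic[1] +
    cfg$marker_threshold * cfg$ramp_ms[1]
  expect_lt(abs(vib$mean - expected_vib), 3 * vib$sd / sqrt(vib$n_events))

  # detected onsets track true physical onsets within one hop each
  for (ch in c("light", "sound")) {
    det <- res$onsets[[ch]]
    err <- det - sess$truth[[paste0("onset_", ch)]]
    expect_true(all(abs(err[!is.na(err)]) < 512 / cfg$sample_rate))
  }

  # percentile ordering in every emitted table
  for (tab in list(res$lag_tables, res$onset_lag_tables,
                   res$asynchrony_tables, res$marker_lag_tables)) {
    q <- as.matrix(tab[, c("min", "p25", "p50", "p75", "max")])
    expect_true(all(q[, -1] - q[, -5] >= 0))
  }

  # the internal ramp regression exists and shows the ramp effect
  expect_false(is.null(res$regression))
  expect_gt(res$regression$slope, 0)
  expect_lt(res$regression$slope_p, 0.001)
})
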