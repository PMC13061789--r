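test_that("the trial generator honours the session composition exactly", {
  cfg <- rte_gen_config(n_participants = 3)
  g <- gen_rte_trials(cfg, seed = 2)
  tab <- table(g$trials$participant, g$trials$condition)
  expect_true(all(tab[, "none"] == 30))
  for (co in setdiff(rte_conditions(), "none"))
    expect_true(all(tab[, co] == 10))
  expect_equal(nrow(g$trials), 3 * 100)
  # catch trials never carry a response
  expect_true(all(!g$trials$responded[g$trials$condition == "none"]))
  # determinism
  g2 <- gen_rte_trials(cfg, seed = 2)
  expect_identical(g$trials, g2$trials)
})

test_that("clean configurations survive the filters nearly untouched", {
  cfg <- rte_gen_config(n_participants = 8, anticipation_rate = 0,
                        slow_outlier_rate = 0, miss_rate = 0)
  g <- gen_rte_trials(cfg, seed = 5)
  out <- apply_rt_filters(g$trials)
  # range filter can only catch rare tail draws; the loss must be tiny
  expect_gt(nrow(out$trials) / sum(g$trials$condition != "none"), 0.97)
})

test_that("the pipeline recovers the configured condition structure", {
  cfg <- rte_gen_config()  # 32 participants, published means/SDs
  g <- gen_rte_trials(cfg, seed = 1)
  res <- rte_analyze(g$trials)
  s <- res$summary
  # group means within 3 SEs of the configured generating means
  for (i in seq_len(nrow(s))) {
    target <- cfg$cond_means[[s$condition[i]]]
    expect_lt(abs(s$mean[i] - target), 3 * s$se[i])
  }
  # redundant-target ordering: the trimodal condition is fastest on average,
  # multimodal conditions beat unimodal ones
  uni <- s$mean[s$condition %in% c("V", "A", "T")]
  multi <- s$mean[s$condition %in% c("AV", "VT", "AT", "AVT")]
  expect_lt(mean(multi), mean(uni))
  expect_lt(s$mean[s$condition == "AVT"], min(uni))
  # a strong main effect is detected at this sample size
  expect_lt(res$anova$p_value, 0.001)
})

test_that("the session generator meets its structural contract", {
  cfg <- session_gen_config(n_trials = 12, sample_rate = 8000)
  sess <- gen_session_recording(cfg, seed = 7)
  expect_equal(length(sess$markers$trial_onsets), 12L)
  expect_equal(sess$markers$stimulus_onsets,
               sess$markers$trial_onsets + 0.3)
  expect_equal(sess$markers$trial_offsets,
               sess$markers$trial_onsets + 0.7)
  for (ch in names(sess$recordings)) {
    expect_s3_class(sess$recordings[[ch]], "recording")
    expect_true(all(diff(sess$markers$device_markers[[ch]]) > 0))
  }
  # determinism
  sess2 <- gen_session_recording(cfg, seed = 7)
  expect_identical(sess$recordings$sound$samples,
                   sess2$recordings$sound$samples)
  expect_identical(sess$truth, sess2$truth)
})

test_that("noise-free instantaneous bursts put markers at the true onset", {
  cfg <- session_gen_config(n_trials = 5, sample_rate = 8000,
                            lag_ms = list(light = c(35.9, 0),
                                          sound = c(40.9, 0),
                                          vibration_mic = c(48.1, 0)),
                            ramp_ms = c(0, 0), noise_floor = 0)
  sess <- gen_session_recording(cfg, seed = 1)
  for (ch in c("light", "sound", "vibration_mic")) {
    err <- sess$truth[[paste0("marker_", ch)]] -
      sess$truth[[paste0("onset_", ch)]]
    expect_true(all(err >= 0 & err <= 1 / 8000))
  }
})

test_that("marker lag follows the closed-form ramp crossing time", {
  cfg <- session_gen_config(n_trials = 40, sample_rate = 22050,
                            marker_threshold = 0.6)
  sess <- gen_session_recording(cfg, seed = 11)
  lag <- sess$truth$marker_vibration_mic - sess$truth$onset_vibration_mic
  pred <- 0.6 * sess$truth$ramp
  expect_true(all(abs(lag - pred) <= 1 / 22050))
})

test_that("infeasible session configurations are refused", {
  expect_error(session_gen_config(foreperiod = 0.6, stim_duration = 0.2),
               "trial_length|foreperiod")
  expect_error(
    gen_session_recording(
      session_gen_config(n_trials = 3, sample_rate = 8000,
                         lag_ms = list(light = c(450, 0),
                                       sound = c(40.9, 0),
                                       vibration_mic = c(48.1, 0))),
      seed = 1),
    "overlap")
})
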