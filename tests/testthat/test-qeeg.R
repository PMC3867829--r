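# Conditioning, burst detection, epoch classification and recovery metrics.

test_that("conditioning preserves the passband and removes DC and high frequencies", {
  r <- sine_record(10, amp = 50)
  y <- condition(r)$left[3000:15000]  # away from record edges
  expect_gte(max(abs(y)), 49.5)
  expect_lte(max(abs(y)), 50.5)

  dc <- eeg_record(rep(100, 60 * FS), rep(100, 60 * FS), FS)
  expect_lt(abs(mean(condition(dc)$left)), 1)

  hf <- sine_record(100, amp = 50)
  ratio <- sqrt(mean(condition(hf)$left^2)) / sqrt(mean(hf$left^2))
  expect_lt(ratio, 0.10)
})

test_that("conditioning warns and clamps when the low-pass corner is unreachable", {
  t <- seq_len(120 * 10) / 120
  r <- eeg_record(sin(2 * pi * 5 * t), sin(2 * pi * 5 * t), fs = 120)
  expect_warning(condition(r), "clamped")
})

test_that("burst detection follows the amplitude and interburst-interval rules", {
  flat <- eeg_record(numeric(10 * FS), numeric(10 * FS), FS)
  expect_identical(nrow(detect_bursts(flat)), 0L)

  # sub-threshold gap of 0.3 s merges two bursts into one event
  expect_identical(nrow(detect_bursts(burst_train_record(c(1, 1 + 0.4 + 0.3)))), 1L)
  # gap of 0.6 s keeps them separate
  two <- detect_bursts(burst_train_record(c(1, 1 + 0.4 + 0.6)))
  expect_identical(nrow(two), 2L)
  expect_gte(two$onset[2] - two$offset[1], 0.5)

  # k bursts with >= 0.6 s gaps -> exactly k events, peaks above threshold
  onsets <- cumsum(rep(1.2, 7))
  ev <- detect_bursts(burst_train_record(onsets))
  expect_identical(nrow(ev), 7L)
  expect_true(all(ev$peak_left > 10 & ev$peak_right > 10))
  expect_true(all(diff(ev$onset) > 0))
  expect_true(all(ev$offset > ev$onset))
})

test_that("bursts must exceed threshold on both channels", {
  b <- generate_burst(0.4, 50, FS, seed = 2)
  x <- numeric(5 * FS); x[301:(300 + length(b))] <- b
  one_sided <- eeg_record(x, numeric(5 * FS), FS)
  expect_identical(nrow(detect_bursts(one_sided)), 0L)
  both <- eeg_record(x, x, FS)
  expect_identical(nrow(detect_bursts(both)), 1L)
})

test_that("epoch classification distinguishes the three patterns", {
  set.seed(31)
  n <- 60 * FS
  quiet <- eeg_record(rnorm(n, sd = 2), rnorm(n, sd = 2), FS)
  lab <- classify_epochs(quiet, detect_bursts(quiet))
  expect_identical(as.character(lab$label), "isoelectric")

  bs <- burst_train_record(seq(5, 55, by = 10), total = 60, noise_sd = 2)
  lab <- classify_epochs(bs, detect_bursts(bs))
  expect_identical(as.character(lab$label), "burst_suppression")

  cont <- generate_recording(stage_profile(0.5, 1),
                             continuous_spec(total_rms = 20),
                             fs = FS, duration = 61, seed = 17)
  cont <- eeg_record(cont$left[1:n + 300], cont$right[1:n + 300], FS)
  lab <- classify_epochs(cont, detect_bursts(cont))
  expect_identical(as.character(lab$label), "continuous")
})

test_that("trailing partial epochs are dropped and epoch count is floor(duration/60)", {
  r <- burst_train_record(seq(5, 145, by = 10), total = 150, noise_sd = 2)
  lab <- classify_epochs(r, detect_bursts(r))
  expect_identical(nrow(lab), 2L)  # 150 s -> 2 full epochs
  expect_identical(lab$t_start_s, c(0, 60))
})

test_that("classification is threshold-monotone: amplifying bursts never yields isoelectric", {
  r <- burst_train_record(seq(5, 55, by = 10), total = 60, noise_sd = 2, amp = 15)
  for (gain in c(1, 3, 10)) {
    rg <- eeg_record(r$left * gain, r$right * gain, FS)
    lab <- classify_epochs(rg, detect_bursts(rg))
    expect_false(any(lab$label == "isoelectric"))
  }
})

test_that("burst onset time converts to minutes and is missing without bursts", {
  ev <- detect_bursts(burst_train_record(900, total = 905))
  expect_equal(burst_onset_time(ev), 15.0, tolerance = 1e-3)
  expect_true(is.na(burst_onset_time(ev[0, ])))
})

test_that("recovery time follows the persistence rule", {
  expect_equal(recovery_time(label_frame(c("isoelectric", "burst_suppression",
                                           "burst_suppression", "continuous",
                                           "continuous", "continuous"))), 3.0)
  expect_equal(recovery_time(label_frame(c("burst_suppression", "continuous",
                                           "burst_suppression", "continuous",
                                           "continuous"))), 3.0)
  expect_true(is.na(recovery_time(label_frame(c("isoelectric",
                                                "burst_suppression")))))
  expect_true(is.na(recovery_time(label_frame(character(0)))))
})

test_that("burst frequency counts onsets per bin", {
  ev <- data.frame(onset = 60 * seq(0.5, 9.8, length.out = 30),
                   offset = 60 * seq(0.5, 9.8, length.out = 30) + 0.2)
  bf <- burst_frequency(ev, bin_width = 10, window = c(0, 10))
  expect_equal(bf$rate_per_min, 3.0)
  expect_equal(burst_frequency(ev[0, ], bin_width = 5,
                               window = c(0, 10))$rate_per_min, c(0, 0))
  expect_error(burst_frequency(ev, bin_width = 0), "positive")
})

test_that("a rising burst-rate ramp produces a rising detected frequency profile", {
  rate <- data.frame(t_min = c(0, 20), rate = c(2, 10))
  prof <- stage_profile(0, 20 * 60, burst_rate = rate)
  reps <- lapply(1:3, function(k) {
    rec <- generate_recording(prof, continuous_spec(total_rms = 0),
                              fs = 150, duration = 20 * 60 + 1, seed = 100 + k)
    burst_frequency(detect_bursts(condition(rec)), bin_width = 5,
                    window = c(0, 20))$rate_per_min
  })
  avg <- Reduce(`+`, reps) / length(reps)
  expect_gt(cor(seq_along(avg), avg, method = "spearman"), 0)
  expect_true(all(diff(avg) > -1))  # near-monotone increase
})

test_that("the qeeg pipeline is deterministic and internally consistent", {
  prof <- stage_profile(60, 240, burst_rate = 12)
  rec <- generate_recording(prof, continuous_spec(total_rms = 30),
                            fs = FS, duration = 360, seed = 7)
  f1 <- qeeg(rec)
  f2 <- qeeg(rec)
  expect_identical(f1$bursts, f2$bursts)
  expect_identical(f1$labels, f2$labels)
  expect_equal(f1$entropy, f2$entropy)
  # events never overlap; merged gaps respect the interburst rule
  if (nrow(f1$bursts) > 1)
    expect_true(all(f1$bursts$onset[-1] - f1$bursts$offset[-nrow(f1$bursts)] >=
                      0.5 - 1e-9))
  # metrics ordering invariant
  expect_lte(f1$metrics$burst_onset_min, f1$metrics$recovery_min)
  s <- summary(f1)
  expect_s3_class(s, "summary.qeeg")
  expect_output(print(f1), "bursts detected")
})
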