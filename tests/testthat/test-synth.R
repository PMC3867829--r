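# Synthetic generator: waveform contracts, determinism, ground-truth fidelity.

test_that("generated bursts hit the requested peak and length, and taper to zero", {
  b <- generate_burst(1, 50, FS, seed = 1)
  expect_equal(length(b), FS)
  expect_gte(max(abs(b)), 49.5)
  expect_lte(max(abs(b)), 50.5)
  expect_lt(max(abs(b[1:3])), 1)          # tapered ends
  expect_lt(max(abs(b[(FS - 2):FS])), 1)
  expect_equal(length(generate_burst(0.5, 50, FS)), 150)
  expect_error(generate_burst(0, 50, FS), "positive")
  expect_error(generate_burst(1, -5, FS), "positive")
})

test_that("band-limited noise concentrates power in band at the target level", {
  for (case in list(list(band = c(4, 8), pw = 100), list(band = c(0.5, 4), pw = 25))) {
    x <- generate_bandlimited_noise(case$band, case$pw, FS, 60 * FS, seed = 3)
    expect_equal(mean(x^2), case$pw, tolerance = 1e-6) # exact by construction
    ps <- welch_psd(x, FS)
    df <- ps$freq[2] - ps$freq[1]
    sel <- ps$freq >= case$band[1] & ps$freq <= case$band[2]
    expect_gte(sum(ps$psd[sel]) / sum(ps$psd), 0.90)
  }
  expect_identical(generate_bandlimited_noise(c(4, 8), 0, FS, 100), numeric(100))
  expect_error(generate_bandlimited_noise(c(100, 200), 1, FS, 100), "fs/2")
})

test_that("single-band noise drives the four-band spectral entropy toward zero", {
  x <- generate_bandlimited_noise(c(0.5, 4), 100, FS, 60 * FS, seed = 4)
  p <- band_probabilities(band_powers(welch_psd(x, FS)))
  expect_lt(spectral_entropy(p), 0.3)
})

test_that("recordings are deterministic in the seed and honor stage structure", {
  prof <- stage_profile(30, 120, burst_rate = 15)
  r1 <- generate_recording(prof, fs = FS, duration = 180, seed = 10)
  r2 <- generate_recording(prof, fs = FS, duration = 180, seed = 10)
  expect_identical(r1$left, r2$left)
  expect_identical(attr(r1, "events"), attr(r2, "events"))
  r3 <- generate_recording(prof, fs = FS, duration = 180, seed = 11)
  expect_false(identical(r1$left, r3$left))

  ev <- attr(r1, "events")
  expect_true(all(ev$onset >= 30 & ev$offset <= 120))
  expect_true(all(diff(ev$onset) > 0))
  # isoelectric stage stays sub-threshold
  expect_lt(max(abs(r1$left[1:(30 * FS - 1)])), 10 + 1e-9)
  expect_error(generate_recording(prof, fs = FS, duration = 100),
               "duration")
})

test_that("a no-burst sub-threshold profile yields all-isoelectric epochs", {
  prof <- stage_profile(179, 180, suppression_sigma = 2,
                        burst_rate = 0, burst_amp = 50)
  rec <- generate_recording(prof, continuous_spec(total_rms = 0),
                            fs = FS, duration = 180, seed = 2)
  fit <- qeeg(rec)
  expect_true(all(fit$labels$label == "isoelectric"))
  expect_identical(nrow(fit$bursts), 0L)
})

test_that("profile and spec validators reject inconsistent parameters", {
  expect_error(stage_profile(100, 50), "isoelectric_end")
  expect_error(stage_profile(10, 50, burst_amp = 8), "threshold")
  expect_error(continuous_spec(c(0.5, 0.5, 0.1, 0.1)), "sum to 1")
  expect_error(continuous_spec(c(-0.1, 0.5, 0.3, 0.3)), "nonnegative")
  expect_error(cohort_spec(n_per_group = 1), "n_per_group")
})

test_that("cohort generation is balanced, deterministic and carries the configured effect signs", {
  spec <- cohort_spec(n_per_group = 6, seed = 21)
  co <- generate_cohort(spec, signals = FALSE)
  expect_identical(as.vector(table(co$truth$group)), c(6L, 6L))
  expect_identical(co$truth,
                   generate_cohort(spec, signals = FALSE)$truth)
  # treated arm configured with earlier burst onset and earlier recovery
  g1 <- co$truth$group == spec$groups[1]
  expect_lt(mean(co$truth$isoelectric_end[g1]),
            mean(co$truth$isoelectric_end[!g1]))
  expect_lt(mean(co$truth$bs_end[g1]), mean(co$truth$bs_end[!g1]))
  expect_lt(mean(co$outcomes$nds_day4[g1]), mean(co$outcomes$nds_day4[!g1]))
})

test_that("zero per-day death probability means every animal survives 96 h", {
  co <- generate_cohort(cohort_spec(n_per_group = 5, death_scale = 0, seed = 5),
                        signals = FALSE)
  expect_true(all(co$outcomes$survival_hr == 96))
  expect_true(all(co$outcomes$event == 0))
  km <- km_logrank(co$outcomes$survival_hr, co$outcomes$event,
                   co$outcomes$group)
  expect_equal(km$surv_at(96, "hypothermia"), 1)
  expect_true(is.na(km$chisq))  # no events: log-rank undefined
})

test_that("NDS values produced by the cohort generator are valid scale values", {
  co <- generate_cohort(cohort_spec(n_per_group = 4, seed = 8), signals = FALSE)
  cats <- names(nds_categories())
  for (r in seq_len(nrow(co$nds_detail))) {
    expect_silent(nds_total(unlist(co$nds_detail[r, cats])))
  }
  expect_true(all(co$outcomes$nds_day4 >= 0 & co$outcomes$nds_day4 <= 500))
})

test_that("with zero group effects, the onset t-test p value is calibrated", {
  # type-I calibration: both arms share every generating distribution
  set.seed(71)
  rej <- mean(replicate(1000, {
    spec <- cohort_spec(n_per_group = 10,
                        iso_end_mean = c(110, 110), iso_end_sd = c(15, 15),
                        bs_end_mean = c(300, 300), bs_end_sd = c(30, 30),
                        rate_start = c(6, 6), rate_end = c(15, 15),
                        band_fractions = list(c(0.65, 0.15, 0.1, 0.1),
                                              c(0.65, 0.15, 0.1, 0.1)),
                        nds_intercept = c(0, 0), nds_day_coef = c(0, 0),
                        seed = sample.int(2^30, 1))
    co <- generate_cohort(spec, signals = FALSE)
    g1 <- co$truth$group == "hypothermia"
    welch_t_raw(co$truth$isoelectric_end[g1],
                co$truth$isoelectric_end[!g1])$p.value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})
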