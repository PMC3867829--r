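# Shared fixture builders (all signals generated in code).

FS <- 300

# Record with identical sinusoid on both channels.
sine_record <- function(freq, amp = 50, dur = 60, fs = FS, t0 = 0) {
  t <- seq_len(dur * fs) / fs
  x <- amp * sin(2 * pi * freq * t)
  eeg_record(x, x, fs = fs, t0 = t0)
}

# Record containing a train of identical bursts at given onset times (s),
# over a quiet (zero or low-noise) background, same waveform on both channels.
burst_train_record <- function(onsets, dur = 0.4, amp = 50, total = NULL,
                               fs = FS, noise_sd = 0, seed = 42) {
  total <- total %||% (max(onsets) + dur + 2)
  n <- round(total * fs)
  b <- generate_burst(dur, amp, fs, seed = seed)
  x <- if (noise_sd > 0) withr::with_seed(seed, rnorm(n, sd = noise_sd))
       else numeric(n)
  for (on in onsets) {
    i0 <- round(on * fs) + 1
    idx <- i0:min(i0 + length(b) - 1, n)
    x[idx] <- x[idx] + b[seq_along(idx)]
  }
  eeg_record(x, x, fs = fs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built epoch-label frame for metric tests.
label_frame <- function(labels, epoch_s = 60, t0 = 0) {
  data.frame(epoch = seq_along(labels),
             t_start_s = t0 + (seq_along(labels) - 1) * epoch_s,
             label = factor(labels, levels = c("isoelectric",
                                               "burst_suppression",
                                               "continuous")))
}

# Independent Fisher oracle: exhaustive hypergeometric enumeration with the
# sum-of-smaller-probabilities two-sided rule.
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
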