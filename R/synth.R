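# Synthetic EEG generator: three-stage post-resuscitation recovery
# (isoelectric -> burst suppression -> continuous background) with every
# generating parameter recorded so downstream analysis can be validated by
# parameter recovery.

#' Stage profile for a synthetic recording
#'
#' Describes the three-stage recovery structure of one synthetic EEG record:
#' an isoelectric stage, a burst-suppression stage with a time-varying burst
#' rate, and a continuous-background stage.
#'
#' @param isoelectric_end End of the isoelectric stage, seconds from ROSC.
#' @param bs_end End of the burst-suppression stage (start of the continuous
#'   stage), seconds from ROSC. Must exceed `isoelectric_end`.
#' @param suppression_sigma Standard deviation (microvolts RMS) of the
#'   Gaussian sub-threshold background present during the isoelectric and
#'   burst-suppression stages. The default 2 keeps the peak amplitude of a
#'   60 s epoch below the 10 microvolt visibility threshold with probability
#'   above 0.99 (Gaussian extreme-value bound at 5 sigma).
#' @param burst_rate Either a single rate in bursts/minute or a two-column
#'   `data.frame`/matrix (`t_min`, `rate`) giving a piecewise-linear rate as a
#'   function of time *within* the burst-suppression stage (minutes from the
#'   stage start). Values are interpolated linearly and held constant beyond
#'   the last knot.
#' @param burst_amp Peak burst amplitude in microvolts; must exceed the
#'   10 microvolt detection threshold.
#' @param burst_dur_range Length-2 numeric: min and max burst duration (s).
#' @param min_separation Minimum gap enforced between the offset of one burst
#'   and the onset of the next, seconds. Kept above the 0.5 s interburst rule
#'   so generated bursts are individually resolvable.
#'
#' @return An object of class `stage_profile`.
#' @export
stage_profile <- function(isoelectric_end, bs_end, suppression_sigma = 2,
                          burst_rate = 10, burst_amp = 75,
                          burst_dur_range = c(0.15, 0.5),
                          min_separation = 0.6) {
  stopifnot_scalar(isoelectric_end, "isoelectric_end")
  stopifnot_scalar(bs_end, "bs_end")
  if (isoelectric_end < 0 || bs_end <= isoelectric_end)
    stop("need 0 <= isoelectric_end < bs_end", call. = FALSE)
  if (burst_amp <= 10)
    stop("'burst_amp' must exceed the 10 microvolt detection threshold",
         call. = FALSE)
  if (suppression_sigma < 0) stop("'suppression_sigma' must be >= 0", call. = FALSE)
  if (length(burst_dur_range) != 2L || any(burst_dur_range <= 0) ||
      burst_dur_range[1] > burst_dur_range[2])
    stop("'burst_dur_range' must be positive (min, max)", call. = FALSE)
  if (is.numeric(burst_rate) && length(burst_rate) == 1L)
    burst_rate <- data.frame(t_min = 0, rate = burst_rate)
  burst_rate <- as.data.frame(burst_rate)
  names(burst_rate) <- c("t_min", "rate")
  if (any(burst_rate$rate < 0)) stop("burst rates must be >= 0", call. = FALSE)
  structure(
    list(isoelectric_end = isoelectric_end, bs_end = bs_end,
         suppression_sigma = suppression_sigma, burst_rate = burst_rate,
         burst_amp = burst_amp, burst_dur_range = burst_dur_range,
         min_separation = min_separation),
    class = "stage_profile")
}

#' Spectral composition of the continuous-background stage
#'
#' @param band_fractions Four nonnegative fractions summing to 1: the share of
#'   total power in the delta (0.5-4 Hz), theta (4-8 Hz), alpha (8-13 Hz) and
#'   beta (13-30 Hz) bands. The default is the flat-spectrum profile
#'   proportional to the band widths, `c(3.5, 4, 5, 17)/29.5`, whose
#'   four-band spectral entropy is 0.824.
#' @param total_rms Total RMS amplitude of the continuous background in
#'   microvolts.
#' @return An object of class `continuous_spec`.
#' @export
continuous_spec <- function(band_fractions = c(3.5, 4, 5, 17) / 29.5,
                            total_rms = 20) {
  band_fractions <- as.numeric(band_fractions)
  if (length(band_fractions) != 4L || any(band_fractions < 0))
    stop("'band_fractions' must be 4 nonnegative numbers", call. = FALSE)
  if (abs(sum(band_fractions) - 1) > 1e-9)
    stop("'band_fractions' must sum to 1 (within 1e-9)", call. = FALSE)
  if (total_rms < 0) stop("'total_rms' must be >= 0", call. = FALSE)
  structure(list(band_fractions = band_fractions, total_rms = total_rms),
            class = "continuous_spec")
}

#' Band-limited Gaussian noise with exact total power
#'
#' Generates Gaussian noise whose spectral support is restricted to a
#' frequency band by Fourier masking, rescaled so the empirical mean square
#' equals `target_power`.
#'
#' @param band Length-2 numeric `(low, high)` in Hz, `0 < low < high < fs/2`.
#' @param target_power Target mean-square power in microvolts squared.
#' @param fs Sample rate (Hz).
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
generate_bandlimited_noise <- function(band, target_power, fs, n, seed = NULL) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2)
    stop("'band' must satisfy 0 < low < high < fs/2", call. = FALSE)
  if (target_power < 0) stop("'target_power' must be >= 0", call. = FALSE)
  n <- as.integer(n)
  if (target_power == 0) return(numeric(n))
  # generate at a 2/3/5-smooth length (fast mixed-radix FFT), then truncate
  n2 <- stats::nextn(n, c(2L, 3L, 5L))
  with_seed(seed, {
    w <- stats::rnorm(n2)
    f <- (seq_len(n2) - 1L) * fs / n2
    # symmetric mask on the two-sided frequency grid
    fm <- pmin(f, fs - f)
    mask <- fm >= band[1] & fm <= band[2]
    spec <- stats::fft(w) * mask
    x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)] / n2
    p <- mean(x^2)
    if (p <= 0) return(numeric(n))
    x * sqrt(target_power / p)
  })
}

#' Single synthetic EEG burst waveform
#'
#' A band-limited noise burst shaped by a Tukey (tapered cosine) envelope and
#' normalized so its absolute peak equals `peak_amp`. The taper drives both
#' ends to zero so bursts can be added into a record without discontinuities.
#'
#' @param duration Burst duration in seconds (> 0).
#' @param peak_amp Absolute peak amplitude in microvolts (> 0).
#' @param fs Sample rate (Hz).
#' @param seed Optional integer seed.
#' @param band Spectral support of the burst core, Hz.
#' @return Numeric vector of `round(fs * duration)` samples.
#' @export
generate_burst <- function(duration, peak_amp, fs, seed = NULL, band = c(1, 16)) {
  stopifnot_scalar(duration, "duration")
  if (duration <= 0) stop("'duration' must be positive", call. = FALSE)
  if (peak_amp <= 0) stop("'peak_amp' must be positive", call. = FALSE)
  n <- max(8L, as.integer(round(duration * fs)))
  core <- generate_bandlimited_noise(band, 1, fs, n, seed = seed)
  env <- tukey_window(n, alpha = 0.5)
  x <- core * env
  m <- max(abs(x))
  if (m == 0) x else x * (peak_amp / m)
}

# Tukey (tapered cosine) window; alpha = taper fraction of the length.
tukey_window <- function(n, alpha = 0.5) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  a2 <- alpha / 2
  lo <- t < a2
  hi <- t > 1 - a2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

# Inhomogeneous Poisson burst onsets on [0, T) seconds: the event count is
# Poisson(integral of the rate), event times are iid with density
# proportional to the rate (inverse-CDF sampling), and minimum-separation
# conflicts are resolved by shifting an onset forward to the first admissible
# time (never by deletion), so the realized count stays faithful to the
# declared rate; events pushed past the stage end are dropped. Rates in
# bursts/min.
sample_burst_times <- function(rate_knots, stage_len_s, dur_range, min_sep) {
  if (max(rate_knots$rate) <= 0 || stage_len_s <= 0)
    return(data.frame(onset = numeric(0), duration = numeric(0)))
  rate_fn <- if (nrow(rate_knots) < 2L) {
    r0 <- rate_knots$rate[1]
    function(t) rep(r0, length(t))
  } else {
    stats::approxfun(rate_knots$t_min * 60, rate_knots$rate,
                     rule = 2, ties = "ordered")
  }
  grid <- seq(0, stage_len_s, length.out = 4096L)
  lam <- rate_fn(grid) / 60                     # per second
  cum <- c(0, cumsum((lam[-1L] + lam[-length(lam)]) / 2 * diff(grid)))
  total <- cum[length(cum)]
  n <- stats::rpois(1L, total)
  if (n == 0L)
    return(data.frame(onset = numeric(0), duration = numeric(0)))
  tt <- sort(stats::approx(cum, grid, xout = stats::runif(n, 0, total),
                           ties = "ordered")$y)
  durs <- stats::runif(n, dur_range[1], dur_range[2])
  keep <- logical(n)
  last_end <- -Inf
  for (k in seq_len(n)) {
    tt[k] <- max(tt[k], last_end + min_sep)
    if (tt[k] + durs[k] <= stage_len_s) {
      keep[k] <- TRUE
      last_end <- tt[k] + durs[k]
    }
  }
  data.frame(onset = tt[keep], duration = durs[keep])
}

#' Generate a synthetic two-channel EEG recording
#'
#' Builds a two-channel record with the three-stage recovery structure: a
#' sub-threshold isoelectric stage, a burst-suppression stage in which bursts
#' arrive as an inhomogeneous Poisson process with a piecewise-linear rate,
#' and a continuous stage of band-mixture background activity. Bursts share
#' their waveform across the two channels (so they co-occur, as the detection
#' rule requires) while the additive background noise is independent per
#' channel. The generating ground truth is attached to the returned record:
#' `attr(, "stages")` holds the stage boundaries and `attr(, "events")` the
#' burst event log.
#'
#' @param profile A [stage_profile()].
#' @param continuous A [continuous_spec()].
#' @param fs Sample rate in Hz (>= 100).
#' @param duration Total record duration in seconds (>= `profile$bs_end`).
#' @param seed Optional integer seed; fixed seed gives a bit-identical record.
#' @param t0 Time of the first sample, seconds from ROSC.
#' @return An [eeg_record()] with ground-truth attributes.
#' @export
generate_recording <- function(profile, continuous = continuous_spec(),
                               fs = 300, duration = NULL, seed = NULL, t0 = 0) {
  stopifnot(inherits(profile, "stage_profile"),
            inherits(continuous, "continuous_spec"))
  if (fs < 100) stop("'fs' must be >= 100 Hz", call. = FALSE)
  duration <- duration %||% (profile$bs_end + 120)
  if (duration < profile$bs_end)
    stop("invalid profile: 'duration' is shorter than 'bs_end'", call. = FALSE)
  n <- as.integer(round(duration * fs))
  with_seed(seed, {
    left <- stats::rnorm(n, sd = profile$suppression_sigma)
    right <- stats::rnorm(n, sd = profile$suppression_sigma)

    # burst-suppression stage
    stage_len <- profile$bs_end - profile$isoelectric_end
    ev <- sample_burst_times(profile$burst_rate, stage_len,
                             profile$burst_dur_range, profile$min_separation)
    if (nrow(ev)) {
      ev$onset <- ev$onset + profile$isoelectric_end
      for (k in seq_len(nrow(ev))) {
        b <- generate_burst(ev$duration[k], profile$burst_amp, fs)
        i0 <- as.integer(round(ev$onset[k] * fs)) + 1L
        idx <- i0:(i0 + length(b) - 1L)
        idx <- idx[idx <= n]
        left[idx] <- left[idx] + b[seq_along(idx)]
        right[idx] <- right[idx] + b[seq_along(idx)]
      }
    }

    # continuous stage: independent band-mixture realizations per channel
    i_cont <- as.integer(round(profile$bs_end * fs)) + 1L
    if (i_cont <= n && continuous$total_rms > 0) {
      m <- n - i_cont + 1L
      edges <- c(0.5, 4, 8, 13, 30)
      total_pow <- continuous$total_rms^2
      for (ch in c("left", "right")) {
        x <- numeric(m)
        for (b in 1:4) {
          pw <- total_pow * continuous$band_fractions[b]
          if (pw > 0)
            x <- x + generate_bandlimited_noise(c(edges[b], edges[b + 1]),
                                                pw, fs, m)
        }
        if (ch == "left") left[i_cont:n] <- left[i_cont:n] + x
        else right[i_cont:n] <- right[i_cont:n] + x
      }
    }

    rec <- eeg_record(left, right, fs = fs, t0 = t0)
    # realized iso -> burst-suppression boundary: the first burst actually
    # placed (the nominal isoelectric_end is a rate parameter; the stage
    # transition only manifests at the first event)
    attr(rec, "stages") <- list(
      isoelectric_end = profile$isoelectric_end,
      isoelectric_end_realized = if (nrow(ev)) t0 + min(ev$onset) else NA_real_,
      bs_end = profile$bs_end)
    if (nrow(ev)) {
      attr(rec, "events") <- data.frame(onset = t0 + ev$onset,
                                        offset = t0 + ev$onset + ev$duration)
    } else {
      attr(rec, "events") <- data.frame(onset = numeric(0), offset = numeric(0))
    }
    attr(rec, "profile") <- profile
    attr(rec, "continuous") <- continuous
    rec
  })
}
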