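# Spectral entropy of the four-band EEG power distribution.
#
# For each 60 s epoch a Welch averaged periodogram is computed (linear
# detrend + Hanning window per segment), the power spectral density is
# partitioned into the delta/theta/alpha/beta bands, band powers are
# normalized to a probability mass function p_i = X_i / sum(X), and the
# normalized Shannon entropy SE = -sum(p_i log2 p_i) / log2 N is reported
# per channel together with the left/right mean.

#' Frequency-band scheme
#'
#' @param edges Strictly increasing band edges in Hz. The default partitions
#'   0.5-30 Hz into delta (0.5-4), theta (4-8), alpha (8-13) and beta (13-30).
#' @param names Band names, one fewer than `edges`.
#' @return An object of class `band_scheme`.
#' @export
band_scheme <- function(edges = c(0.5, 4, 8, 13, 30),
                        names = c("delta", "theta", "alpha", "beta")) {
  edges <- as.numeric(edges)
  if (any(diff(edges) <= 0)) stop("'edges' must be strictly increasing", call. = FALSE)
  if (length(names) != length(edges) - 1L)
    stop("need one name per band", call. = FALSE)
  structure(list(edges = edges, names = names, n_bands = length(names)),
            class = "band_scheme")
}

#' Welch averaged periodogram
#'
#' Splits the signal into overlapping segments, linearly detrends and Hanning-
#' windows each, and averages the one-sided modified periodograms. The PSD is
#' scaled so that `sum(psd) * df` equals the mean power of the detrended,
#' windowed signal (Parseval-consistent density).
#'
#' @param x Numeric signal (one epoch, microvolts).
#' @param fs Sample rate (Hz).
#' @param segment_s Segment length in seconds (default 10 for 0.1 Hz
#'   resolution, resolving the 0.5 Hz band edge).
#' @param overlap Fractional overlap between consecutive segments (default 0.5).
#' @param detrend Linearly detrend each segment (default TRUE).
#' @return A list with `freq` (Hz) and `psd` (power per Hz), class
#'   `welch_psd`.
#' @export
welch_psd <- function(x, fs, segment_s = 10, overlap = 0.5, detrend = TRUE) {
  nseg <- as.integer(round(segment_s * fs))
  n <- length(x)
  if (n < nseg)
    stop("signal shorter than one Welch segment", call. = FALSE)
  hop <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, n - nseg + 1L, by = hop)
  w <- as.numeric(signal::hanning(nseg))
  u <- sum(w^2)                      # window power normalization
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  tt <- seq_len(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    if (detrend) {
      fit <- stats::lm.fit(cbind(1, tt), seg)
      seg <- fit$residuals
    }
    sp <- stats::fft(seg * w)[seq_len(nfreq)]
    p <- (Mod(sp)^2) / (fs * u)
    # one-sided: double everything except DC (and Nyquist for even nseg)
    p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
    if (nseg %% 2L != 0L) p[nfreq] <- 2 * p[nfreq]
    acc <- acc + p
  }
  structure(list(freq = (seq_len(nfreq) - 1L) * fs / nseg,
                 psd = acc / length(starts),
                 fs = fs, segment_s = segment_s, n_segments = length(starts)),
            class = "welch_psd")
}

#' Band powers from a spectral estimate
#'
#' Integrates the PSD over each band using half-open bins `[low, high)`, so
#' the shared 4 Hz and 8 Hz edges are counted exactly once (in the upper
#' band).
#'
#' @param psd A [welch_psd()] estimate.
#' @param scheme A [band_scheme()].
#' @return Named numeric vector of band powers (microvolts squared).
#' @export
band_powers <- function(psd, scheme = band_scheme()) {
  stopifnot(inherits(psd, "welch_psd"), inherits(scheme, "band_scheme"))
  if (max(psd$freq) < max(scheme$edges))
    stop("frequency grid does not cover the band scheme", call. = FALSE)
  df <- psd$freq[2] - psd$freq[1]
  x <- vapply(seq_len(scheme$n_bands), function(b) {
    sel <- psd$freq >= scheme$edges[b] & psd$freq < scheme$edges[b + 1L]
    sum(psd$psd[sel]) * df
  }, numeric(1))
  names(x) <- scheme$names
  x
}

#' Band probability mass function
#'
#' `p_i = X_i / sum(X)`. When the total power is zero the probabilities (and
#' hence the spectral entropy) are undefined and returned as `NA`.
#'
#' @param x Nonnegative band powers.
#' @return Numeric vector of probabilities summing to 1, or all-`NA`.
#' @export
band_probabilities <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("band powers must be >= 0", call. = FALSE)
  s <- sum(x)
  if (!is.finite(s) || s <= 0) return(rep(NA_real_, length(x)))
  x / s
}

#' Normalized spectral entropy
#'
#' Shannon entropy of the band probability distribution in bits, normalized
#' by `log2(N)` so the result lies in `[0, 1]`: 1 for a uniform distribution,
#' 0 when a single band carries all power. `0 * log2(0)` is treated as 0.
#'
#' @param p Probability vector (nonnegative, summing to 1).
#' @return Spectral entropy in `[0, 1]`, or `NA` if `p` is undefined.
#' @export
spectral_entropy <- function(p) {
  if (anyNA(p)) return(NA_real_)
  if (any(p < 0)) stop("probabilities must be >= 0", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6)
    stop("probabilities must sum to 1", call. = FALSE)
  nz <- p > 0
  h <- -sum(p[nz] * log2(p[nz]))
  se <- h / log2(length(p))
  min(max(se, 0), 1)
}

#' Spectral-entropy time course of a record
#'
#' Computes, for every full nonoverlapping epoch (aligned to the same grid as
#' the epoch classifier), the Welch PSD per channel, band powers, band
#' probabilities and spectral entropy, plus the left/right channel mean.
#'
#' @param record A conditioned [eeg_record()].
#' @param scheme A [band_scheme()].
#' @param epoch_s Epoch length in seconds.
#' @param segment_s,overlap Welch segmentation inside the epoch. Setting
#'   `segment_s = epoch_s` yields a single (non-averaged) periodogram per
#'   epoch.
#' @param labels Optional epoch labels from [classify_epochs()]; when given,
#'   a `label` column is attached (spectral entropy is conventionally
#'   aggregated over continuous epochs only).
#' @return A `data.frame` with one row per epoch: `epoch`, `t_start_s`, band
#'   powers `X_*` (channel mean), probabilities `p_*`, `se_left`, `se_right`,
#'   `se_mean` and optionally `label`.
#' @export
entropy_timecourse <- function(record, scheme = band_scheme(), epoch_s = 60,
                               segment_s = 10, overlap = 0.5, labels = NULL) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  ep_n <- as.integer(round(epoch_s * fs))
  n_ep <- length(record$left) %/% ep_n
  bn <- scheme$names
  out <- vector("list", n_ep)
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1L) * ep_n + 1L):(e * ep_n)
    xs <- list(record$left[idx], record$right[idx])
    Xs <- lapply(xs, function(x)
      band_powers(welch_psd(x, fs, segment_s, overlap), scheme))
    ses <- vapply(Xs, function(X) spectral_entropy(band_probabilities(X)),
                  numeric(1))
    Xm <- (Xs[[1]] + Xs[[2]]) / 2
    pm <- band_probabilities(Xm)
    row <- c(list(epoch = e, t_start_s = record$t0 + (e - 1L) * epoch_s),
             as.list(stats::setNames(Xm, paste0("X_", bn))),
             as.list(stats::setNames(pm, paste0("p_", bn))),
             list(se_left = ses[1], se_right = ses[2],
                  se_mean = mean(ses)))
    out[[e]] <- as.data.frame(row)
  }
  res <- if (n_ep > 0) do.call(rbind, out) else
    as.data.frame(stats::setNames(
      rep(list(numeric(0)), 5L + 2L * length(bn)),
      c("epoch", "t_start_s", paste0("X_", bn), paste0("p_", bn),
        "se_left", "se_right", "se_mean")))
  if (!is.null(labels) && nrow(res))
    res$label <- as.character(labels$label[match(res$epoch, labels$epoch)])
  res
}
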