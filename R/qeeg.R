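# Burst detection, three-class epoch classification and recovery metrics.
#
# Definitions follow the standard quantitative description of early
# post-resuscitation EEG: bursts are episodes of rectified amplitude above
# 10 microvolts on both channels, separated by interburst intervals of at
# least 0.5 s of sub-threshold activity; 60 s epochs are classified as
# isoelectric, burst suppression or continuous background activity.

#' Band-pass condition an EEG record
#'
#' Applies the acquisition passband (0.3-70 Hz by default) digitally as a
#' zero-phase Butterworth filter (forward-backward), so burst onsets are not
#' delayed by group delay. The record is reflection-padded before filtering to
#' suppress edge transients of the low high-pass corner.
#'
#' @param record An [eeg_record()].
#' @param low,high Corner frequencies in Hz.
#' @param order Butterworth order per pass (effective order doubles under
#'   forward-backward filtering).
#' @return The conditioned [eeg_record()]; ground-truth attributes are kept.
#' @export
condition <- function(record, low = 0.3, high = 70, order = 4) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  nyq <- fs / 2
  if (high >= nyq) {
    warning(sprintf("low-pass corner %g Hz unreachable at fs = %g Hz; clamped",
                    high, fs))
    high <- 0.45 * fs
  }
  hp <- signal::butter(2, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  pad <- min(length(record$left) - 1L, as.integer(10 * fs))
  filt1 <- function(x) {
    # reflection padding keeps the 0.3 Hz high-pass transient off the record
    xp <- c(rev(x[seq_len(pad)]), x, rev(x[length(x) - seq_len(pad) + 1L]))
    y <- signal::filtfilt(hp, xp)
    y <- signal::filtfilt(lp, y)
    y[(pad + 1L):(pad + length(x))]
  }
  out <- eeg_record(filt1(record$left), filt1(record$right),
                    fs = fs, t0 = record$t0, labels = record$labels)
  for (a in c("stages", "events", "profile", "continuous"))
    attr(out, a) <- attr(record, a)
  out
}

# Per-channel supra-threshold activity mask: rectified amplitude above
# `threshold`, sub-threshold dips up to `debounce_s` absorbed, activity
# episodes shorter than `debounce_s` discarded as not visible.
activity_mask <- function(x, fs, threshold, debounce_s = 0.01) {
  supra <- abs(x) > threshold
  k <- max(1L, as.integer(round(debounce_s * fs)))
  supra <- close_gaps(supra, k)
  drop_short_runs(supra, k)
}

#' Detect bursts in a two-channel EEG record
#'
#' A burst is an episode whose rectified amplitude exceeds the threshold on
#' *both* channels with overlapping supra-threshold intervals; the event
#' extent is the union of the two overlapping intervals. Events separated by
#' less than `min_gap` seconds of sub-threshold signal are merged, and events
#' shorter than `min_dur` are discarded.
#'
#' @param record A conditioned [eeg_record()].
#' @param threshold Amplitude threshold in microvolts (default 10).
#' @param min_gap Minimum interburst interval in seconds (default 0.5).
#' @param min_dur Minimum burst duration in seconds (default 0.05).
#' @param debounce_s Sub-threshold dips up to this length are absorbed into a
#'   burst; supra-threshold blips shorter than this are ignored.
#' @return A `data.frame` with columns `onset`, `offset` (seconds from ROSC),
#'   `peak_left`, `peak_right` (microvolts), sorted by onset. Zero rows when
#'   no burst is present.
#' @export
detect_bursts <- function(record, threshold = 10, min_gap = 0.5,
                          min_dur = 0.05, debounce_s = 0.01) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  n <- length(record$left)
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      peak_left = numeric(0), peak_right = numeric(0))
  if (n == 0L) return(empty)
  mL <- activity_mask(record$left, fs, threshold, debounce_s)
  mR <- activity_mask(record$right, fs, threshold, debounce_s)
  both <- mL & mR
  if (!any(both)) return(empty)
  runsL <- logical_runs(mL)
  runsR <- logical_runs(mR)
  ov <- logical_runs(both)
  # extend each both-channel overlap to the union of its containing runs
  events <- t(apply(ov, 1L, function(rn) {
    iL <- which(runsL[, 1] <= rn[1] & runsL[, 2] >= rn[2])[1]
    iR <- which(runsR[, 1] <= rn[1] & runsR[, 2] >= rn[2])[1]
    c(min(runsL[iL, 1], runsR[iR, 1]), max(runsL[iL, 2], runsR[iR, 2]))
  }))
  events <- events[order(events[, 1]), , drop = FALSE]
  # coalesce duplicates and merge events separated by < min_gap
  gap_n <- as.integer(round(min_gap * fs))
  merged <- events[1, , drop = FALSE]
  if (nrow(events) > 1L) for (k in 2:nrow(events)) {
    last <- nrow(merged)
    if (events[k, 1] - merged[last, 2] - 1L < gap_n) {
      merged[last, 2] <- max(merged[last, 2], events[k, 2])
    } else {
      merged <- rbind(merged, events[k, , drop = FALSE])
    }
  }
  dur_n <- as.integer(round(min_dur * fs))
  keep <- (merged[, 2] - merged[, 1] + 1L) >= dur_n
  merged <- merged[keep, , drop = FALSE]
  if (!nrow(merged)) return(empty)
  data.frame(
    onset = record$t0 + (merged[, 1] - 1L) / fs,
    offset = record$t0 + merged[, 2] / fs,
    peak_left = vapply(seq_len(nrow(merged)), function(k)
      max(abs(record$left[merged[k, 1]:merged[k, 2]])), numeric(1)),
    peak_right = vapply(seq_len(nrow(merged)), function(k)
      max(abs(record$right[merged[k, 1]:merged[k, 2]])), numeric(1)))
}

#' Classify 60-second epochs as isoelectric, burst suppression or continuous
#'
#' Nonoverlapping epochs anchored at the record start are labeled:
#' `isoelectric` when neither channel shows any visible activity (no
#' supra-threshold episode lasting at least the debounce time);
#' `burst_suppression` when at least one detected burst overlaps the epoch
#' and the epoch contains a suppression segment (both channels sub-threshold)
#' of at least `min_gap` seconds; `continuous` otherwise. A trailing partial
#' epoch is excluded.
#'
#' @inheritParams detect_bursts
#' @param bursts Burst events from [detect_bursts()] on the same record.
#' @param epoch_s Epoch length in seconds (default 60).
#' @return A `data.frame` with `epoch` (1-based index), `t_start_s` (seconds
#'   from ROSC) and `label` (factor with the three levels above).
#' @export
classify_epochs <- function(record, bursts, epoch_s = 60, threshold = 10,
                            min_gap = 0.5, debounce_s = 0.01) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  ep_n <- as.integer(round(epoch_s * fs))
  n_ep <- length(record$left) %/% ep_n
  lev <- c("isoelectric", "burst_suppression", "continuous")
  if (n_ep == 0L)
    return(data.frame(epoch = integer(0), t_start_s = numeric(0),
                      label = factor(character(0), levels = lev)))
  mL <- activity_mask(record$left, fs, threshold, debounce_s)
  mR <- activity_mask(record$right, fs, threshold, debounce_s)
  quiet <- !(mL | mR)
  gap_n <- as.integer(round(min_gap * fs))
  labels <- character(n_ep)
  t_start <- record$t0 + (seq_len(n_ep) - 1L) * epoch_s
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1L) * ep_n + 1L):(e * ep_n)
    act <- mL[idx] | mR[idx]
    if (!any(act)) {
      labels[e] <- "isoelectric"
      next
    }
    has_burst <- nrow(bursts) > 0 &&
      any(bursts$onset < t_start[e] + epoch_s & bursts$offset > t_start[e])
    r <- rle(quiet[idx])
    has_supp <- any(r$values & r$lengths >= gap_n)
    labels[e] <- if (has_burst && has_supp) "burst_suppression" else "continuous"
  }
  data.frame(epoch = seq_len(n_ep), t_start_s = t_start,
             label = factor(labels, levels = lev))
}

#' Burst onset time
#'
#' Onset of the first detected burst, in minutes from ROSC. `NA` when the
#' record contains no burst.
#'
#' @param bursts Burst events from [detect_bursts()].
#' @return Minutes from ROSC, or `NA_real_`.
#' @export
burst_onset_time <- function(bursts) {
  if (is.null(bursts) || nrow(bursts) == 0L) return(NA_real_)
  min(bursts$onset) / 60
}

#' Time of recovery of continuous background activity
#'
#' Start time of the first epoch from which every subsequent labeled epoch is
#' `continuous` (persistence rule: momentary relapses postpone recovery).
#' `NA` when the record never settles into continuous activity.
#'
#' @param labels Epoch labels from [classify_epochs()].
#' @return Minutes from ROSC, or `NA_real_`.
#' @export
recovery_time <- function(labels) {
  lab <- as.character(labels$label)
  n <- length(lab)
  if (n == 0L || lab[n] != "continuous") return(NA_real_)
  nc <- lab != "continuous"
  last_nc <- if (any(nc)) max(which(nc)) else 0L
  if (last_nc == n) return(NA_real_)
  labels$t_start_s[last_nc + 1L] / 60
}

#' Burst-frequency time course
#'
#' Counts burst onsets in consecutive bins and converts to bursts per minute.
#'
#' @param bursts Burst events from [detect_bursts()].
#' @param bin_width Bin width in minutes (default 10).
#' @param window Length-2 numeric: analysis window in minutes from ROSC
#'   (default the first 2 hours). Restrict to the burst-suppression period to
#'   reproduce the standard burst-frequency curve.
#' @return A `data.frame` with `t_start_min`, `t_end_min`, `n_bursts`,
#'   `rate_per_min`.
#' @export
burst_frequency <- function(bursts, bin_width = 10, window = c(0, 120)) {
  if (bin_width <= 0) stop("'bin_width' must be positive", call. = FALSE)
  edges <- seq(window[1], window[2], by = bin_width)
  if (length(edges) < 2L) stop("window shorter than one bin", call. = FALSE)
  onset_min <- if (is.null(bursts) || nrow(bursts) == 0L) numeric(0)
               else bursts$onset / 60
  counts <- vapply(seq_len(length(edges) - 1L), function(k)
    sum(onset_min >= edges[k] & onset_min < edges[k + 1L]), numeric(1))
  data.frame(t_start_min = edges[-length(edges)], t_end_min = edges[-1L],
             n_bursts = counts, rate_per_min = counts / bin_width)
}

#' Quantitative EEG analysis of a two-channel record
#'
#' The central analysis entry point: conditions the record, detects bursts,
#' classifies 60 s epochs, derives the recovery metrics (burst onset time,
#' recovery time of continuous background activity, burst-frequency time
#' course) and computes the spectral-entropy time course.
#'
#' @param record An [eeg_record()].
#' @param epoch_s Epoch length in seconds.
#' @param threshold Burst/visibility amplitude threshold in microvolts.
#' @param min_gap Minimum interburst (suppression) interval, seconds.
#' @param bin_width Burst-frequency bin width, minutes.
#' @param freq_window Burst-frequency analysis window, minutes from ROSC;
#'   `NULL` uses the record's burst-suppression extent rounded to whole bins.
#' @param scheme Band scheme for spectral entropy, see [band_scheme()].
#' @param segment_s,overlap Welch segmentation inside each epoch.
#' @param condition_first Apply [condition()] before analysis (default TRUE).
#' @return An object of class `qeeg`: a list with `bursts`, `labels`,
#'   `entropy`, `metrics` (burst_onset_min, recovery_min, burst_freq), the
#'   analysis parameters and the call.
#' @examples
#' prof <- stage_profile(isoelectric_end = 60, bs_end = 240, burst_rate = 12)
#' rec <- generate_recording(prof, continuous_spec(total_rms = 30),
#'                           fs = 300, duration = 360, seed = 7)
#' fit <- qeeg(rec)
#' summary(fit)
#' @export
qeeg <- function(record, epoch_s = 60, threshold = 10, min_gap = 0.5,
                 bin_width = 10, freq_window = NULL,
                 scheme = band_scheme(), segment_s = 10, overlap = 0.5,
                 condition_first = TRUE) {
  stopifnot(inherits(record, "eeg_record"))
  cond <- if (condition_first) condition(record) else record
  bursts <- detect_bursts(cond, threshold = threshold, min_gap = min_gap)
  labels <- classify_epochs(cond, bursts, epoch_s = epoch_s,
                            threshold = threshold, min_gap = min_gap)
  rec_min <- recovery_time(labels)
  onset_min <- burst_onset_time(bursts)
  if (is.null(freq_window)) {
    end_min <- if (!is.na(rec_min)) rec_min
               else record$t0 / 60 + record_duration(record) / 60
    end_min <- max(bin_width, ceiling(end_min / bin_width) * bin_width)
    freq_window <- c(floor((record$t0 / 60) / bin_width) * bin_width, end_min)
  }
  bf <- burst_frequency(bursts, bin_width = bin_width, window = freq_window)
  ent <- entropy_timecourse(cond, scheme = scheme, epoch_s = epoch_s,
                            segment_s = segment_s, overlap = overlap,
                            labels = labels)
  structure(
    list(bursts = bursts, labels = labels, entropy = ent,
         metrics = list(burst_onset_min = onset_min, recovery_min = rec_min,
                        burst_freq = bf),
         params = list(epoch_s = epoch_s, threshold = threshold,
                       min_gap = min_gap, bin_width = bin_width,
                       segment_s = segment_s, overlap = overlap),
         fs = record$fs, t0 = record$t0, call = match.call()),
    class = "qeeg")
}

#' @export
print.qeeg <- function(x, ...) {
  cat("Quantitative EEG analysis\n")
  tab <- table(x$labels$label)
  cat(sprintf("  epochs: %d (%s)\n", nrow(x$labels),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  bursts detected: %d\n", nrow(x$bursts)))
  cat(sprintf("  burst onset: %s min; recovery of continuous activity: %s min\n",
              format(round(x$metrics$burst_onset_min, 2)),
              format(round(x$metrics$recovery_min, 2))))
  invisible(x)
}

#' @export
summary.qeeg <- function(object, ...) {
  cont <- object$entropy$label == "continuous"
  se_cont <- object$entropy$se_mean[cont]
  out <- list(
    n_epochs = nrow(object$labels),
    label_counts = table(object$labels$label),
    n_bursts = nrow(object$bursts),
    burst_onset_min = object$metrics$burst_onset_min,
    recovery_min = object$metrics$recovery_min,
    mean_se_continuous = if (any(cont)) mean(se_cont, na.rm = TRUE) else NA_real_,
    burst_freq = object$metrics$burst_freq)
  class(out) <- "summary.qeeg"
  out
}

#' @export
print.summary.qeeg <- function(x, ...) {
  cat("Quantitative EEG summary\n")
  cat(sprintf("  epochs: %d  |  bursts: %d\n", x$n_epochs, x$n_bursts))
  print(x$label_counts)
  cat(sprintf("  burst onset:        %s min\n", format(round(x$burst_onset_min, 2))))
  cat(sprintf("  recovery time:      %s min\n", format(round(x$recovery_min, 2))))
  cat(sprintf("  mean SE (continuous epochs): %s\n",
              format(round(x$mean_se_continuous, 3))))
  invisible(x)
}

#' @export
plot.qeeg <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  lab_num <- as.integer(x$labels$label)
  t_min <- x$labels$t_start_s / 60
  plot(t_min, lab_num, type = "s", yaxt = "n", ylim = c(1, 3),
       xlab = "time from ROSC (min)", ylab = "", main = "Epoch classification")
  graphics::axis(2, at = 1:3, labels = c("iso", "BS", "cont"), las = 1)
  plot(x$entropy$t_start_s / 60, x$entropy$se_mean, type = "b", pch = 16,
       ylim = c(0, 1), xlab = "time from ROSC (min)",
       ylab = "spectral entropy", main = "Spectral entropy (channel mean)")
  invisible(x)
}
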