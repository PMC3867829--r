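#' Two-channel EEG record
#'
#' Container for a bipolar two-channel EEG recording in microvolts with a
#' fixed sample rate and a time origin expressed in seconds relative to the
#' return of spontaneous circulation (ROSC).
#'
#' @param left,right Numeric vectors of equal length: samples in microvolts.
#' @param fs Sample rate in Hz (nominally 300).
#' @param t0 Time of the first sample, in seconds from ROSC.
#' @param labels Character vector of length 2 with channel labels.
#'
#' @return An object of class `eeg_record`: a list with elements `left`,
#'   `right`, `fs`, `t0` and `labels`. Attributes may carry generator ground
#'   truth (`stages`, `events`) when the record is synthetic.
#' @seealso [qeeg()], [generate_recording()], [read_eeg()]
#' @export
eeg_record <- function(left, right, fs, t0 = 0, labels = c("EEG-L", "EEG-R")) {
  left <- as.numeric(left)
  right <- as.numeric(right)
  if (length(left) != length(right))
    stop("channels must have equal length", call. = FALSE)
  stopifnot_scalar(fs, "fs")
  if (fs <= 0) stop("'fs' must be positive", call. = FALSE)
  stopifnot_scalar(t0, "t0")
  structure(
    list(left = left, right = right, fs = fs, t0 = t0,
         labels = as.character(labels)),
    class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  dur <- length(x$left) / x$fs
  cat(sprintf("Two-channel EEG record: %d samples/channel, fs = %g Hz (%.1f s)\n",
              length(x$left), x$fs, dur))
  cat(sprintf("  t0 = %g s from ROSC; channels: %s, %s\n",
              x$t0, x$labels[1], x$labels[2]))
  st <- attr(x, "stages")
  if (!is.null(st))
    cat(sprintf("  synthetic ground truth: isoelectric to %g s, burst suppression to %g s\n",
                st$isoelectric_end, st$bs_end))
  invisible(x)
}

#' @export
plot.eeg_record <- function(x, from = NULL, to = NULL, ...) {
  t <- x$t0 + seq_along(x$left) / x$fs
  keep <- rep(TRUE, length(t))
  if (!is.null(from)) keep <- keep & t >= from
  if (!is.null(to)) keep <- keep & t <= to
  old <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(old))
  plot(t[keep], x$left[keep], type = "l", xlab = "", ylab = x$labels[1], ...)
  plot(t[keep], x$right[keep], type = "l", xlab = "time from ROSC (s)",
       ylab = x$labels[2], ...)
  invisible(x)
}

#' Duration of an EEG record in seconds
#' @param record An [eeg_record()].
#' @return Length of the record in seconds.
#' @export
record_duration <- function(record) length(record$left) / record$fs
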