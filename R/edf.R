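# Minimal EDF (European Data Format) writer/reader for two-channel EEG.
# 16-bit integer samples, one-second data records, physical dimension uV.
# Only the subset of the format needed for this package is supported.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write an EEG record to an EDF file
#'
#' Writes the two channels as 16-bit EDF signals (labels `EEG-L`/`EEG-R`,
#' physical dimension uV, one-second data records at the record's sample
#' rate). The physical range is set symmetrically from the data, so the
#' quantization step is `2 * max(abs(x)) / 65535`. The time origin `t0` is
#' stored in the recording-identification field as `t0_s=<seconds>`. A
#' trailing partial second is zero-padded.
#'
#' @param record An [eeg_record()] with an integer sample rate.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  if (fs != round(fs)) stop("EDF export requires an integer sample rate", call. = FALSE)
  n <- length(record$left)
  n_rec <- as.integer(ceiling(n / fs))
  pad <- n_rec * fs - n
  chans <- list(c(record$left, numeric(pad)), c(record$right, numeric(pad)))
  pmax_ <- vapply(chans, function(x) max(abs(x), 1e-6), numeric(1))
  pmax_ <- ceiling(pmax_ * 100) / 100

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  # fixed header (256 bytes)
  wr("0", 8)
  wr("X X X X", 80)
  wr(sprintf("Startdate X t0_s=%.6g", record$t0), 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256 + 2 * 256, 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr("2", 4)
  # signal headers (256 bytes per signal, field-major)
  labs <- c(record$labels[1], record$labels[2])
  for (l in labs) wr(l, 16)
  for (k in 1:2) wr("", 80)          # transducer
  for (k in 1:2) wr("uV", 8)         # physical dimension
  for (k in 1:2) wr(sprintf("%.8g", -pmax_[k]), 8)
  for (k in 1:2) wr(sprintf("%.8g", pmax_[k]), 8)
  for (k in 1:2) wr("-32768", 8)
  for (k in 1:2) wr("32767", 8)
  for (k in 1:2) wr("", 80)          # prefiltering
  for (k in 1:2) wr(fs, 8)           # samples per data record
  for (k in 1:2) wr("", 32)
  # data records
  dig <- lapply(1:2, function(k) {
    # same affine digital<->physical map as on read: [-32768,32767] <-> [-pmax,pmax]
    v <- as.integer(round((chans[[k]] + pmax_[k]) / (2 * pmax_[k]) * 65535 - 32768))
    pmin(pmax(v, -32768L), 32767L)
  })
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (k in 1:2)
      writeBin(dig[[k]][idx], con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a two-channel EEG record from an EDF file
#'
#' Expects at least two signals with physical dimension uV and equal sample
#' rates; the first two such signals become the left and right channels.
#'
#' @param path EDF file path.
#' @return An [eeg_record()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                       # version
  rd(80)                      # patient
  recording <- rd(80)
  rd(8); rd(8)                # date, time
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("not a valid EDF file", call. = FALSE)
  fld <- function(w) vapply(seq_len(ns), function(k) rd(w), character(1))
  labels <- fld(16)
  fld(80)
  dims <- fld(8)
  pmin_ <- as.numeric(fld(8))
  pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8))
  dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  uv <- which(dims %in% c("uV", "µV"))
  if (length(uv) < 2)
    stop("EDF file must contain at least two EEG signals with physical dimension uV",
         call. = FALSE)
  uv <- uv[1:2]
  if (spr[uv[1]] != spr[uv[2]])
    stop("the two EEG signals have different sample rates", call. = FALSE)
  data <- lapply(uv, function(k) numeric(n_rec * spr[k]))
  for (r in seq_len(n_rec)) {
    for (k in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[k], size = 2L, signed = TRUE,
                   endian = "little")
      j <- match(k, uv)
      if (!is.na(j)) {
        scale <- (pmax_[k] - pmin_[k]) / (dmax[k] - dmin[k])
        idx <- ((r - 1L) * spr[k] + 1L):(r * spr[k])
        data[[j]][idx] <- pmin_[k] + (v - dmin[k]) * scale
      }
    }
  }
  t0 <- 0
  m <- regmatches(recording, regexpr("t0_s=[-0-9.eE+]+", recording))
  if (length(m)) t0 <- as.numeric(sub("t0_s=", "", m))
  eeg_record(data[[1]], data[[2]], fs = spr[uv[1]] / rec_dur, t0 = t0,
             labels = labels[uv])
}
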