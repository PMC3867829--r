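# Signal and table input/output: the CSV signal dialect
# (time_s, ch_left_uV, ch_right_uV) and format dispatch.

#' Write an EEG record to a CSV signal file
#'
#' Columns: `time_s` (seconds from ROSC), `ch_left_uV`, `ch_right_uV`.
#'
#' @param record An [eeg_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  t <- record$t0 + (seq_along(record$left) - 1L) / record$fs
  utils::write.csv(
    data.frame(time_s = t, ch_left_uV = record$left, ch_right_uV = record$right),
    path, row.names = FALSE)
  invisible(path)
}

#' Read an EEG record from a CSV signal file
#'
#' Expects columns `time_s`, `ch_left_uV`, `ch_right_uV`. The sample rate is
#' inferred from the median time step; `t0` is the first time stamp.
#'
#' @param path CSV file path.
#' @return An [eeg_record()].
#' @export
read_eeg_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "ch_left_uV", "ch_right_uV")
  if (!all(need %in% names(d)))
    stop("signal CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  dt <- stats::median(diff(d$time_s))
  eeg_record(d$ch_left_uV, d$ch_right_uV, fs = 1 / dt, t0 = d$time_s[1])
}

#' Read an EEG record, dispatching on format
#'
#' @param path File path.
#' @param format `"edf"`, `"csv"` or `"auto"` (by file extension).
#' @return An [eeg_record()].
#' @export
read_eeg <- function(path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  switch(format, edf = read_edf(path), csv = read_eeg_csv(path))
}

#' Write an EEG record, dispatching on format
#'
#' @inheritParams read_eeg
#' @param record An [eeg_record()].
#' @return `path`, invisibly.
#' @export
write_eeg <- function(record, path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  switch(format, edf = write_edf(record, path),
         csv = write_eeg_csv(record, path))
}

#' Write a cohort to CSV files
#'
#' Writes `cohort.csv` (generating parameters joined to outcomes) and, when
#' recordings are present, one signal file per animal.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param signal_format `"csv"` or `"edf"` for the per-animal signal files,
#'   or `NULL` to skip them.
#' @return The cohort table path, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir, signal_format = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- merge(cohort$truth, cohort$outcomes, by = c("animal_id", "group"))
  tab <- tab[order(tab$animal_id), ]
  path <- file.path(dir, "cohort.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  utils::write.csv(cohort$nds_detail, file.path(dir, "nds_detail.csv"),
                   row.names = FALSE)
  if (!is.null(signal_format) && !is.null(cohort$recordings)) {
    for (id in names(cohort$recordings))
      write_eeg(cohort$recordings[[id]],
                file.path(dir, sprintf("%s.%s", id, signal_format)),
                format = signal_format)
  }
  invisible(path)
}
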