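#' mstatebci: EEG microstates and MI-BCI performance prediction
#'
#' Resting-state EEG microstate segmentation (GFP peaks, modified k-means,
#' backfitting), microstate feature parameters, cluster-number selection
#' criteria, CSP-based motor-imagery accuracy scoring, correlation screening,
#' and a two-feature LDA predictor of high/low BCI performers, together with
#' seeded synthetic-data generators for end-to-end testing.
#'
#' @keywords internal
"_PACKAGE"

#' Standard 30-electrode montage used throughout the package
#'
#' The 10-10 subset covering fronto-central, central and centro-parietal
#' scalp, i.e. the sensorimotor region most informative for motor imagery.
#'
#' @return Character vector of 30 electrode labels.
#' @export
standard_channels_30 <- function() {
  c("F3", "Fz", "F4", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4",
    "FC6", "FT8", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "CP3",
    "CP1", "CP2", "CP4", "P5", "P3", "Pz", "P4", "P6", "PO7", "PO8")
}

#' Construct a multichannel EEG recording
#'
#' A recording is a channels-by-samples voltage matrix (microvolts) with
#' ordered electrode labels and a sampling rate.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param channel_names Character vector, one label per row of `data`.
#' @param fs Sampling rate in Hz (positive scalar).
#' @return An object of class `eeg_recording` with fields `data`,
#'   `channel_names` and `fs`.
#' @export
new_recording <- function(data, channel_names, fs) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive finite scalar", call. = FALSE)
  if (nrow(data) != length(channel_names))
    stop("channel count (", nrow(data), ") does not match number of channel ",
         "names (", length(channel_names), ")", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)))
    stop("recording contains non-finite samples", call. = FALSE)
  rownames(data) <- channel_names
  structure(list(data = data,
                 channel_names = as.character(channel_names),
                 fs = as.numeric(fs)),
            class = "eeg_recording")
}

# internal constructor skipping the finiteness scan, for hot paths whose
# inputs are already validated recordings
recording_fast <- function(data, channel_names, fs) {
  rownames(data) <- channel_names
  structure(list(data = data, channel_names = channel_names, fs = fs),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Construct a set of equally sized EEG epochs
#'
#' @param epochs 3-D numeric array, channels x samples x epochs, or a list of
#'   equally sized channels-by-samples matrices.
#' @param fs Sampling rate in Hz.
#' @param condition One of `"rest_pretrial"`, `"mi_left"`, `"mi_right"`.
#' @param subject_id,session_id Optional identifiers carried along.
#' @param channel_names Optional electrode labels.
#' @return An object of class `epoch_set`.
#' @export
new_epoch_set <- function(epochs, fs,
                          condition = c("rest_pretrial", "mi_left", "mi_right"),
                          subject_id = NA, session_id = NA,
                          channel_names = NULL) {
  condition <- match.arg(condition)
  if (is.list(epochs)) {
    if (length(epochs)) {
      d <- vapply(epochs, dim, integer(2))
      if (any(d[1, ] != d[1, 1]) || any(d[2, ] != d[2, 1]))
        stop("all epochs must share channel and sample counts", call. = FALSE)
      epochs <- array(unlist(epochs, use.names = FALSE),
                      dim = c(d[1, 1], d[2, 1], length(epochs)))
    } else {
      epochs <- array(numeric(0), dim = c(0, 0, 0))
    }
  }
  stopifnot(length(dim(epochs)) == 3L)
  structure(list(epochs = epochs, fs = as.numeric(fs), condition = condition,
                 subject_id = subject_id, session_id = session_id,
                 channel_names = channel_names),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs of %d channels x %d samples @ %g Hz [%s]\n",
              d[3], d[1], d[2], x$fs, x$condition))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param x An `epoch_set`.
#' @return Integer count.
#' @export
n_epochs <- function(x) dim(x$epochs)[3]

#' Load an EEG recording from disk
#'
#' Two dialects are supported: European Data Format (EDF, 16-bit) and a
#' plain whitespace/tab-delimited numeric matrix (channels in rows, samples
#' in columns) accompanied by a sidecar text file whose first line is
#' `fs=<Hz>` and whose remaining lines are the channel names in order.
#'
#' @param path Path to the data file.
#' @param format `"edf"`, `"matrix"`, or `"auto"` (by file extension).
#' @param sidecar Path to the channel-name sidecar for the matrix dialect;
#'   defaults to `<path>.channels`.
#' @return An [new_recording()] object.
#' @export
load_recording <- function(path, format = c("auto", "edf", "matrix"),
                           sidecar = paste0(path, ".channels")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read recording: file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  if (format == "edf") return(read_edf(path))
  dat <- as.matrix(utils::read.table(path, header = FALSE))
  if (!file.exists(sidecar))
    stop("matrix recording requires a sidecar file: ", sidecar, call. = FALSE)
  side <- readLines(sidecar)
  fs_line <- side[1]
  if (!grepl("^fs\\s*=", fs_line))
    stop("sidecar must start with a 'fs=<Hz>' line", call. = FALSE)
  fs <- as.numeric(sub("^fs\\s*=\\s*", "", fs_line))
  ch <- trimws(side[-1])
  ch <- ch[nzchar(ch)]
  if (length(ch) != nrow(dat))
    stop("sidecar lists ", length(ch), " channel names but matrix has ",
         nrow(dat), " rows", call. = FALSE)
  new_recording(dat, ch, fs)
}

#' Write an EEG recording to disk
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @param format `"edf"` or `"matrix"` (matrix writes `<path>.channels` too).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("matrix", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(write_edf(rec, path))
  utils::write.table(rec$data, path, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  writeLines(c(paste0("fs=", format(rec$fs, digits = 15)), rec$channel_names),
             paste0(path, ".channels"))
  invisible(path)
}

#' Restrict a recording to named channels, in the requested order
#'
#' @param rec An `eeg_recording`.
#' @param names Ordered character vector of electrode labels to keep.
#' @return A new `eeg_recording` with exactly those channels.
#' @export
select_channels <- function(rec, names) {
  idx <- match(names, rec$channel_names)
  if (anyNA(idx))
    stop("channel(s) not present in recording: ",
         paste(names[is.na(idx)], collapse = ", "), call. = FALSE)
  new_recording(rec$data[idx, , drop = FALSE], rec$channel_names[idx], rec$fs)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass, 4th order per pass.
#' Zero-phase filtering preserves the timing of topographic events, which
#' matters for microstate durations.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth prototype order per pass (default 4).
#' @param method `"filtfilt"` (time-domain forward-backward, default) or
#'   `"fft"`: the same squared-magnitude Butterworth response applied in
#'   the frequency domain. Both are zero-phase; the FFT path assumes
#'   circular boundaries and is much faster on long recordings.
#' @return Filtered `eeg_recording` of identical shape.
#' @export
bandpass <- function(rec, low, high, order = 4L,
                     method = c("filtfilt", "fft")) {
  method <- match.arg(method)
  fs <- rec$fs
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2 (fs = ", fs, ")",
         call. = FALSE)
  ba <- butter_bandpass(order, low, high, fs)
  if (method == "filtfilt") {
    out <- t(filtfilt_mat(t(rec$data), ba$b, ba$a))
  } else {
    n <- ncol(rec$data)
    w <- 2 * pi * (seq_len(n) - 1) / n
    ez <- exp(-1i * outer(w, seq_along(ba$b) - 1))
    H2 <- as.numeric(Mod(ez %*% ba$b)^2 /
                       Mod(ez[, seq_along(ba$a)] %*% ba$a)^2)
    Xf <- stats::mvfft(t(rec$data))           # samples x channels
    out <- t(Re(stats::mvfft(Xf * H2, inverse = TRUE)) / n)
  }
  recording_fast(out, rec$channel_names, fs)
}

#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous cross-channel mean from every sample, so that
#' every column of the result has mean zero. GFP and GMD are only
#' reference-consistent under the average reference, so this is applied
#' before all microstate computation.
#'
#' @param rec An `eeg_recording` with at least two channels.
#' @return Average-referenced `eeg_recording`.
#' @export
average_reference <- function(rec) {
  if (nrow(rec$data) < 2L)
    stop("average reference requires at least 2 channels", call. = FALSE)
  out <- sweep(rec$data, 2L, colMeans(rec$data))
  recording_fast(out, rec$channel_names, rec$fs)
}

#' Extract fixed-length pre-trial epochs
#'
#' Cuts the window `[onset - duration_s*fs, onset)` (half-open, 0-based
#' sample indexing) before each event onset: the resting segment immediately
#' preceding each motor-imagery trial. Onsets too early to admit a full
#' window are skipped with a warning.
#'
#' @param rec An `eeg_recording`.
#' @param event_onsets Integer vector of 0-based onset sample indices.
#' @param duration_s Epoch length in seconds (default 1).
#' @param condition Condition tag for the resulting epoch set.
#' @param subject_id,session_id Optional identifiers.
#' @return An [new_epoch_set()]; attribute `n_skipped` counts skipped onsets.
#' @export
extract_pretrial_epochs <- function(rec, event_onsets, duration_s = 1,
                                    condition = "rest_pretrial",
                                    subject_id = NA, session_id = NA) {
  n <- round(duration_s * rec$fs)
  onsets <- as.integer(event_onsets)
  ok <- onsets >= n & onsets <= ncol(rec$data)
  if (any(!ok))
    warning(sum(!ok), " onset(s) skipped: full ", duration_s,
            " s window not available", call. = FALSE)
  keep <- onsets[ok]
  eps <- lapply(keep, function(o) rec$data[, (o - n + 1L):o, drop = FALSE])
  es <- new_epoch_set(eps, rec$fs, condition, subject_id, session_id,
                      channel_names = rec$channel_names)
  attr(es, "n_skipped") <- sum(!ok)
  es
}

#' Artifact-removal hook
#'
#' Placeholder for blind-source-separation style artifact clean-up. The
#' package ships no artifact removal; a user-supplied function taking and
#' returning an `eeg_recording` can be plugged in here. The default is the
#' identity.
#'
#' @param rec An `eeg_recording`.
#' @param fun A function `eeg_recording -> eeg_recording`, or `NULL`.
#' @return The (possibly cleaned) recording.
#' @export
remove_artifacts <- function(rec, fun = NULL) {
  if (is.null(fun)) return(rec)
  out <- fun(rec)
  stopifnot(inherits(out, "eeg_recording"))
  out
}

#' Read a two-column event file
#'
#' Delimited file with columns `sample_index` (0-based) and `condition`
#' (`left` or `right`).
#'
#' @param path Path to the event file.
#' @return data.frame with columns `onset` (integer) and `condition`.
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = FALSE,
                          col.names = c("onset", "condition"))
  if (!all(ev$condition %in% c("left", "right")))
    stop("event conditions must be 'left' or 'right'", call. = FALSE)
  ev$onset <- as.integer(ev$onset)
  ev
}
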