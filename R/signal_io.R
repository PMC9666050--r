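# Recordings, windows, delimited-text I/O and segmentation.

#' Movement class labels
#'
#' The six hand movements in canonical order: cylindrical (CY), tip (TI),
#' hook (HO), palmar (PA), spherical (SP), lateral (LA).
#' @return Character vector of length 6.
#' @export
movement_classes <- function() c("CY", "TI", "HO", "PA", "SP", "LA")

#' Construct a labelled multi-channel sEMG recording
#'
#' @param samples Numeric matrix, `n_samples x n_channels` (a vector is treated
#'   as one channel). All values must be finite.
#' @param rate Sampling frequency in Hz (positive).
#' @param label Movement class identifier.
#' @param subject Subject identifier.
#' @param trial Trial index within subject and class.
#' @return An object of class `"emg_recording"`.
#' @export
recording <- function(samples, rate = 500, label = NA_character_,
                      subject = 1L, trial = 1L) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 1L || ncol(samples) < 1L) stop("empty recording")
  if (!all(is.finite(samples)))
    stop("recording contains non-finite sample values (subject ", subject,
         ", trial ", trial, ")")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive number")
  if (is.null(colnames(samples)))
    colnames(samples) <- paste0("ch", seq_len(ncol(samples)))
  structure(list(samples = samples, rate = rate,
                 label = as.character(label), subject = subject,
                 trial = as.integer(trial)),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("sEMG recording: %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              nrow(x$samples) / x$rate))
  cat(sprintf("  label %s, subject %s, trial %d\n",
              x$label, as.character(x$subject), x$trial))
  invisible(x)
}

#' Read a delimited-text recording
#'
#' Reads one recording from a comma- or tab-separated text file with one row
#' per sample and one column per channel (the separator is sniffed from the
#' first line; a lone column is also accepted).
#'
#' @param path File path.
#' @param rate Sampling rate in Hz.
#' @param label,subject,trial Metadata attached to the recording.
#' @return An `"emg_recording"`.
#' @export
read_recording_csv <- function(path, rate = 500, label = NA_character_,
                               subject = 1L, trial = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty input file: ", path)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  ncol <- length(parts[[1L]])
  vals <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) != ncol)
      stop("line ", i, ": expected ", ncol, " columns, found ", length(p))
    v <- suppressWarnings(as.numeric(p))
    if (anyNA(v)) stop("line ", i, ": non-numeric value")
    v
  })
  samples <- do.call(rbind, vals)
  recording(samples, rate = rate, label = label, subject = subject,
            trial = trial)
}

#' Write a recording as delimited text
#'
#' One row per sample, one column per channel, comma separated, no header —
#' the format read back by [read_recording_csv()].
#'
#' @param rec An `"emg_recording"`.
#' @param path Output file path.
#' @param digits Significant digits kept (default 15, round-trip safe within
#'   1e-12 for data of magnitude around 1).
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path, digits = 15L) {
  stopifnot(inherits(rec, "emg_recording"))
  m <- apply(rec$samples, 2L, function(col) sprintf("%.*g", digits, col))
  writeLines(apply(m, 1L, paste, collapse = ","), path)
  invisible(path)
}

#' Segment a recording into fixed-length analysis windows
#'
#' Cuts the recording into windows of exactly `window_length` samples starting
#' every `stride = round(window_length * (1 - overlap))` samples; trailing
#' samples that cannot fill a whole window are discarded. Every window inherits
#' the recording's label, subject and trial (the group key used by the
#' evaluation code to keep windows of one trial in a single fold).
#'
#' @param rec An `"emg_recording"`.
#' @param window_length Window size in samples.
#' @param overlap Fractional overlap between consecutive windows, in `[0, 1)`.
#' @return List of `"emg_window"` objects, each with elements `samples`
#'   (matrix `window_length x n_channels`), `rate`, `label`, `subject`,
#'   `trial`, and `start_index` (0-based offset into the source recording).
#' @examples
#' rec <- recording(matrix(rnorm(6000), ncol = 2), rate = 500, label = "CY")
#' length(segment_windows(rec, 400))  # 7
#' @export
segment_windows <- function(rec, window_length, overlap = 0) {
  stopifnot(inherits(rec, "emg_recording"))
  window_length <- as.integer(window_length)
  n <- nrow(rec$samples)
  if (window_length < 1L) stop("window_length must be positive")
  if (window_length > n)
    stop("window_length (", window_length, ") exceeds recording length (", n, ")")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  stride <- as.integer(round(window_length * (1 - overlap)))
  if (stride < 1L) stop("overlap too large: stride is zero")
  starts <- seq(0L, n - window_length, by = stride)
  lapply(starts, function(s) {
    structure(list(samples = rec$samples[(s + 1L):(s + window_length), ,
                                         drop = FALSE],
                   rate = rec$rate, label = rec$label, subject = rec$subject,
                   trial = rec$trial, start_index = s),
              class = "emg_window")
  })
}

#' @export
print.emg_window <- function(x, ...) {
  cat(sprintf("sEMG window: %d samples x %d channels @ %g Hz, label %s, subject %s trial %d, start %d\n",
              nrow(x$samples), ncol(x$samples), x$rate, x$label,
              as.character(x$subject), x$trial, x$start_index))
  invisible(x)
}

# Segment a list of recordings; returns a flat list of windows.
#' Write a set of recordings as a delimited-text directory
#'
#' Writes one CSV per recording plus a `manifest.csv` with columns `file`,
#' `label`, `subject`, `trial`, `rate` — the layout read back by
#' [read_recordings_dir()].
#'
#' @param recordings List of `"emg_recording"` objects.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_recordings_dir <- function(recordings, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    fn <- sprintf("recording_%04d.csv", i)
    write_recording_csv(rec, file.path(dir, fn))
    data.frame(file = fn, label = rec$label,
               subject = as.character(rec$subject), trial = rec$trial,
               rate = rec$rate)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a recordings directory
#'
#' Reads the recordings listed in `<dir>/manifest.csv` (see
#' [write_recordings_dir()]).
#'
#' @param dir Directory containing `manifest.csv` and the recording files.
#' @return List of `"emg_recording"` objects.
#' @export
read_recordings_dir <- function(dir) {
  manifest <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest)) stop("no manifest.csv in ", dir)
  df <- utils::read.csv(manifest)
  lapply(seq_len(nrow(df)), function(i)
    read_recording_csv(file.path(dir, df$file[i]), rate = df$rate[i],
                       label = df$label[i], subject = df$subject[i],
                       trial = df$trial[i]))
}

#' Segment many recordings
#'
#' Applies [segment_windows()] to each recording and concatenates the results.
#'
#' @param recordings List of `"emg_recording"` objects.
#' @inheritParams segment_windows
#' @return Flat list of `"emg_window"` objects.
#' @export
segment_recordings <- function(recordings, window_length, overlap = 0) {
  unlist(lapply(recordings, segment_windows, window_length = window_length,
                overlap = overlap),
         recursive = FALSE)
}
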