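# Minimal EDF (European Data Format) writer/reader for continuous
# recordings, with the trial events carried in a TSV sidecar table
# (<file>.events.tsv). Signals are stored as 16-bit integers with
# per-channel physical scaling, 1-s data records.

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to EDF
#'
#' Stores the continuous signals as standard EDF (16-bit samples, 1-s
#' data records, per-channel physical min/max scaling) and the event
#' table as a TSV sidecar next to it. The record is zero-padded to a
#' whole number of seconds.
#'
#' @param raw A [raw_recording()].
#' @param path Output `.edf` path.
#' @param events_path Sidecar TSV path (default `<path>.events.tsv`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(raw, path, events_path = paste0(path, ".events.tsv")) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- raw$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  ns <- nrow(raw$samples)
  n <- ncol(raw$samples)
  n_rec <- ceiling(n / fs)
  x <- raw$samples
  if (n < n_rec * fs) x <- cbind(x, matrix(0, ns, n_rec * fs - n))

  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768
  dmax <- 32767
  dig <- round((x - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(.edf_pad("0", 8))                         # version
  wr(.edf_pad("synthetic subject", 80))        # patient id
  wr(.edf_pad("attnmi recording", 80))         # recording id
  wr(.edf_pad("01.01.26", 8))                  # start date
  wr(.edf_pad("00.00.00", 8))                  # start time
  wr(.edf_pad(256 + ns * 256, 8))              # header bytes
  wr(.edf_pad("", 44))                         # reserved
  wr(.edf_pad(n_rec, 8))                       # number of data records
  wr(.edf_pad(1, 8))                           # record duration, s
  wr(.edf_pad(ns, 4))                          # number of signals
  for (lab in raw$channel_labels) wr(.edf_pad(paste("EEG", lab), 16))
  for (i in seq_len(ns)) wr(.edf_pad("AgAgCl electrode", 80))
  for (i in seq_len(ns)) wr(.edf_pad("uV", 8))
  for (i in seq_len(ns)) wr(.edf_pad(format(pmin_[i], digits = 7), 8))
  for (i in seq_len(ns)) wr(.edf_pad(format(pmax_[i], digits = 7), 8))
  for (i in seq_len(ns)) wr(.edf_pad(dmin, 8))
  for (i in seq_len(ns)) wr(.edf_pad(dmax, 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))  # prefiltering
  for (i in seq_len(ns)) wr(.edf_pad(fs, 8))   # samples per record
  for (i in seq_len(ns)) wr(.edf_pad("", 32))  # reserved
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
             size = 2, endian = "little")
  }
  utils::write.table(raw$events, events_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads a 16-bit EDF file written by [write_edf()] (or any EDF whose
#' signals share one sampling rate), restoring microvolt values from the
#' per-channel scaling, and loads the event sidecar. A missing or empty
#' event table is an error: downstream analysis is trial-based.
#'
#' @param path `.edf` file path.
#' @param events_path Sidecar TSV path (default `<path>.events.tsv`).
#' @return A [raw_recording()].
#' @export
read_edf <- function(path, events_path = paste0(path, ".events.tsv")) {
  if (!file.exists(path)) stop("no such EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("malformed EDF header (bad version field)")
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header (signal count)")
  labels <- vapply(seq_len(ns), \(i) rd(16), character(1))
  labels <- sub("^EEG ", "", labels)
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), \(i) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), \(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), \(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), \(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), \(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), \(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / rec_dur
  seek(con, header_bytes)
  raw16 <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                   endian = "little")
  dat <- array(raw16, dim = c(spr[1], ns, n_rec))
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  samples <- matrix(0, ns, n_rec * spr[1])
  for (i in seq_len(ns))
    samples[i, ] <- as.vector(dat[, i, ]) * scale[i] + pmin_[i] - dmin[i] * scale[i]
  if (!file.exists(events_path))
    stop("no events: expected sidecar table at ", events_path)
  events <- utils::read.table(events_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  if (nrow(events) == 0) stop("no events: sidecar table is empty")
  raw_recording(samples, fs, labels, tibble::as_tibble(events))
}
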