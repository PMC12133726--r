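# Raw-recording and trial-epoch containers plus the preprocessing chain:
# resample -> band-pass -> epoch -> label -> baseline-correct -> balance.

#' Continuous multichannel recording
#'
#' Light container for a continuous EEG record: a channels x samples
#' matrix in microvolts, its sampling rate, 10/20 channel labels, and an
#' event table with one row per trial marker.
#'
#' @param samples Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate, Hz.
#' @param channel_labels Character vector, one unique label per row.
#' @param events Tibble with columns `sample` (1-based index of the
#'   Select cue), `arrow`, `response`, `correct`.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, fs, channel_labels, events) {
  stopifnot(is.matrix(samples), fs > 0)
  if (nrow(samples) != length(channel_labels))
    stop("channel_labels length must match the number of rows in samples")
  if (anyDuplicated(channel_labels)) stop("duplicate channel labels")
  events <- tibble::as_tibble(events)
  need <- c("sample", "arrow", "response", "correct")
  if (!all(need %in% names(events)))
    stop("events must have columns: ", paste(need, collapse = ", "))
  if (nrow(events) > 0 &&
      (min(events$sample) < 1 || max(events$sample) > ncol(samples)))
    stop("event sample indices outside the record")
  structure(
    list(samples = samples, fs = fs, channel_labels = channel_labels,
         events = events),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$events)))
  invisible(x)
}

#' Resample a recording
#'
#' Anti-alias low-pass filters (zero-phase, cutoff 80% of the target
#' Nyquist) and interpolates onto the new sampling grid. Event indices are
#' remapped proportionally. Only downsampling (or the identity) is
#' supported; `fs_target = fs` returns the input unchanged.
#'
#' @param raw A [raw_recording()].
#' @param fs_target Target rate, Hz; must satisfy
#'   `60 < fs_target <= raw$fs`.
#' @return A [raw_recording()] at `fs_target`.
#' @export
resample_recording <- function(raw, fs_target) {
  stopifnot(inherits(raw, "raw_recording"))
  if (fs_target > raw$fs) stop("upsampling is not supported")
  if (fs_target <= 60)
    stop("fs_target must exceed 60 Hz (twice the 30 Hz band edge)")
  if (fs_target == raw$fs) return(raw)
  ratio <- fs_target / raw$fs
  n_new <- floor(ncol(raw$samples) * ratio)
  bf <- signal::butter(8, 0.8 * fs_target / raw$fs, type = "low")
  t_old <- (seq_len(ncol(raw$samples)) - 1) / raw$fs
  t_new <- (seq_len(n_new) - 1) / fs_target
  out <- matrix(0, nrow(raw$samples), n_new)
  for (ch in seq_len(nrow(raw$samples))) {
    filtered <- signal::filtfilt(bf, raw$samples[ch, ])
    out[ch, ] <- stats::approx(t_old, filtered, xout = t_new)$y
  }
  events <- raw$events
  events$sample <- pmax(1L, as.integer(round((events$sample - 1) * ratio)) + 1L)
  raw_recording(out, fs_target, raw$channel_labels, events)
}

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) Butterworth band-pass, the 1-30 Hz
#' default removing drift and power-line interference without group delay
#' that would shift ERD latencies.
#'
#' @param raw A [raw_recording()].
#' @param lo,hi Band edges in Hz, `0 < lo < hi < fs/2`.
#' @param order Butterworth order per pass (default 4; the
#'   forward-backward pass doubles the effective order).
#' @return The filtered [raw_recording()].
#' @export
bandpass_recording <- function(raw, lo = 1, hi = 30, order = 4) {
  stopifnot(inherits(raw, "raw_recording"))
  if (!(lo > 0 && lo < hi && hi < raw$fs / 2))
    stop("invalid band edges: need 0 < lo < hi < fs/2")
  bf <- signal::butter(order, c(lo, hi) / (raw$fs / 2), type = "pass")
  out <- raw$samples
  for (ch in seq_len(nrow(out))) out[ch, ] <- signal::filtfilt(bf, out[ch, ])
  raw_recording(out, raw$fs, raw$channel_labels, raw$events)
}

#' Attention labels from key-press correctness
#'
#' A trial whose response matches the arrow is labelled `"Attention"`, a
#' mismatching response `"Inattention"`. A missing response does not
#' default to Inattention: the trial is flagged invalid instead.
#'
#' @param events Event tibble with `arrow` and `response` columns.
#' @return The events with added `label` (character, `NA` when invalid)
#'   and `valid` (logical) columns.
#' @export
label_attention <- function(events) {
  events <- tibble::as_tibble(events)
  if (!all(c("arrow", "response") %in% names(events)))
    stop("events must have arrow and response columns")
  valid <- !is.na(events$response) & !is.na(events$arrow)
  label <- ifelse(events$response == events$arrow, "Attention", "Inattention")
  label[!valid] <- NA_character_
  dplyr::mutate(events, label = label, valid = valid)
}

#' Cut a recording into trial epochs
#'
#' Extracts one epoch per event, time-locked to the Select cue (t = 0),
#' and attaches attention labels via [label_attention()]. Events whose
#' window would fall outside the record, and trials with an invalid
#' response, are dropped with a warning reporting the counts.
#'
#' @param raw A [raw_recording()].
#' @param window Epoch span in seconds relative to the cue
#'   (default `c(-2, 7)`, the full paradigm timeline).
#' @param baseline_window Baseline span in seconds (default `c(-1, 0)`,
#'   the pre-cue rest second); must lie inside `window`.
#' @return A `trial_epochs` object: `data` (trials x channels x time
#'   array), `fs`, `time` (seconds), `channel_labels`, `labels`
#'   (per-trial condition), `baseline_window`.
#' @export
epoch_trials <- function(raw, window = c(-2, 7), baseline_window = c(-1, 0)) {
  stopifnot(inherits(raw, "raw_recording"), length(window) == 2)
  if (window[1] >= window[2]) stop("window must be increasing")
  if (baseline_window[1] < window[1] || baseline_window[2] > window[2])
    stop("baseline window must lie inside the epoch window")
  fs <- raw$fs
  ev <- label_attention(raw$events)
  n_inv <- sum(!ev$valid)
  ev <- ev[ev$valid, ]
  offs <- round(window * fs)
  idx0 <- as.integer(round(ev$sample + offs[1]))
  idx1 <- as.integer(round(ev$sample + offs[2])) - 1L
  inside <- idx0 >= 1 & idx1 <= ncol(raw$samples)
  n_oob <- sum(!inside)
  if (n_inv + n_oob > 0)
    warning(sprintf("dropped %d trial(s): %d invalid response, %d outside record",
                    n_inv + n_oob, n_inv, n_oob))
  ev <- ev[inside, ]
  idx0 <- idx0[inside]
  if (nrow(ev) == 0) stop("no usable trials after epoching")
  len <- as.integer(offs[2] - offs[1])
  nchan <- nrow(raw$samples)
  data <- array(0, dim = c(nrow(ev), nchan, len))
  for (k in seq_len(nrow(ev)))
    data[k, , ] <- raw$samples[, idx0[k]:(idx0[k] + len - 1L)]
  structure(
    list(data = data, fs = fs,
         time = window[1] + (seq_len(len) - 1) / fs,
         channel_labels = raw$channel_labels,
         labels = ev$label,
         baseline_window = baseline_window),
    class = "trial_epochs"
  )
}

#' @export
print.trial_epochs <- function(x, ...) {
  cat(sprintf("<trial_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs))
  print(table(x$labels))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean of the baseline segment
#' (default the -1 to 0 s rest second). Idempotent: the baseline mean is
#' exactly zero afterwards.
#'
#' @param epochs A [epoch_trials()] result.
#' @return The corrected `trial_epochs`.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "trial_epochs"))
  bw <- epochs$baseline_window
  sel <- epochs$time >= bw[1] & epochs$time < bw[2]
  if (!any(sel)) stop("degenerate baseline window: no samples inside")
  means <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(means)   # recycles over time axis
  epochs
}

#' Balance trial counts across conditions
#'
#' Randomly subsamples the majority class, without replacement, down to
#' the minority count; the minority class and every retained trial's data
#' are untouched. Deterministic under `seed`.
#'
#' @param epochs A `trial_epochs` with both conditions present.
#' @param seed Integer seed for the subsample.
#' @return The balanced `trial_epochs`.
#' @export
balance_trials <- function(epochs, seed) {
  stopifnot(inherits(epochs, "trial_epochs"))
  tab <- table(epochs$labels)
  if (length(tab) < 2 || any(tab == 0))
    stop("both conditions must be present to balance trials")
  if (tab[1] == tab[2]) return(epochs)
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  keep_min <- which(epochs$labels == minority)
  maj <- which(epochs$labels == majority)
  keep_maj <- .local_seed(seed, sort(sample(maj, min(tab))))
  keep <- sort(c(keep_min, keep_maj))
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$labels <- epochs$labels[keep]
  epochs
}

#' Persist epochs as plain text
#'
#' Writes a `trial_epochs` object to a directory as one TSV matrix per
#' trial-channel block plus a JSON metadata file (sampling rate, time
#' axis, channel labels, condition labels). The layout is documented in
#' `meta.json`; [read_epochs()] restores the object.
#'
#' @param epochs A `trial_epochs`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "trial_epochs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[3] * d[2], ncol = d[1])
  utils::write.table(flat, file.path(dir, "data.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(
    layout = "data.tsv: one column per trial; rows are time-major within channel",
    dim = d, fs = epochs$fs, time = epochs$time,
    channel_labels = epochs$channel_labels, labels = epochs$labels,
    baseline_window = epochs$baseline_window
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file.path(dir, "data.tsv"), sep = "\t"))
  d <- as.integer(meta$dim)
  data <- aperm(array(flat, dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  structure(
    list(data = data, fs = meta$fs, time = meta$time,
         channel_labels = meta$channel_labels, labels = meta$labels,
         baseline_window = meta$baseline_window),
    class = "trial_epochs"
  )
}
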