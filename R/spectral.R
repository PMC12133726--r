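# Time-frequency analysis: wavelet-packet spectrograms, event-related
# spectral perturbation (ERSP) maps in dB relative to the pre-cue
# baseline, ERD window means, and the collapsed energy curves.

.hann <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# windowed wavelet-packet power for the columns of X (time x signals).
# centers_idx: sample index of each window centre. Returns
# [freq x window x signal] power array plus the node frequency axis.
.tf_power <- function(X, fs, centers_idx, win_n, freq_range, wavelet,
                      maxlevel, taper = TRUE) {
  m <- ncol(X)
  nwin <- length(centers_idx)
  half <- floor(win_n / 2)
  idx <- outer(seq_len(win_n) - 1L - half, centers_idx, "+")
  if (min(idx) < 1 || max(idx) > nrow(X))
    stop("analysis window falls outside the signal")
  mat <- X[as.vector(idx), , drop = FALSE]
  if (taper) mat <- mat * rep(.hann(win_n), times = nwin)
  W <- matrix(array(mat, dim = c(win_n, nwin, m)), win_n, nwin * m)
  sp <- wpt_node_power(W, fs, wavelet = wavelet, maxlevel = maxlevel)
  rows <- sp$freq >= freq_range[1] & sp$freq <= freq_range[2]
  power <- array(sp$power[rows, , drop = FALSE],
                 dim = c(sum(rows), nwin, m))
  list(freq = sp$freq[rows], power = power)
}

#' Wavelet-packet spectrogram of a single signal
#'
#' Slides a tapered analysis window along the signal and computes
#' frequency-ordered wavelet-packet node energies per window (window
#' zero-padded to a dyadic length; effective depth
#' `min(maxlevel, log2(padded length))`).
#'
#' @param x Numeric vector, one channel of one trial.
#' @param fs Sampling rate, Hz.
#' @param freq_range Frequency rows to keep, Hz (default 1-30).
#' @param win,step Window length and hop in seconds (defaults 0.5 and
#'   0.25; see the vignette for the time-resolution trade-off).
#' @param t Optional time axis for `x` (seconds); defaults to starting
#'   at 0.
#' @param wavelet,maxlevel Wavelet-packet parameters (defaults `"db4"`,
#'   8).
#' @param taper Apply a Hann taper per window (default `TRUE`).
#' @return A `tf_power` list: `power` (freq x time matrix of band
#'   energies), `freq` (Hz), `time` (window centres, s).
#' @export
trial_spectrogram <- function(x, fs, freq_range = c(1, 30), win = 0.5,
                              step = 0.25, t = NULL, wavelet = "db4",
                              maxlevel = 8, taper = TRUE) {
  stopifnot(is.numeric(x), fs > 0)
  win_n <- round(win * fs)
  if (length(x) < win_n)
    stop("signal shorter than one analysis window")
  if (is.null(t)) t <- (seq_along(x) - 1) / fs
  lo <- t[1] + win / 2
  hi <- t[length(t)] - win / 2
  centers <- seq(lo, hi, by = step)
  centers_idx <- vapply(centers, \(cc) which.min(abs(t - cc)), integer(1))
  res <- .tf_power(matrix(x, ncol = 1), fs, centers_idx, win_n, freq_range,
                   wavelet, maxlevel, taper)
  list(power = res$power[, , 1, drop = TRUE], freq = res$freq, time = centers)
}

#' Event-related spectral perturbation map
#'
#' Averages per-trial wavelet-packet power over the trials of one
#' condition at one channel, then converts to dB relative to the mean
#' baseline power of the same frequency row (baseline = windows fully
#' inside the epochs' baseline window, by default the -1 to 0 s rest
#' second).
#'
#' @param epochs A [epoch_trials()] result.
#' @param channel Channel label, e.g. `"Cz"`.
#' @param condition `"Attention"`, `"Inattention"`, or `NULL` for all
#'   trials.
#' @param freq_range,tf_range Frequency (Hz) and time (s) extent of the
#'   map; defaults 1-30 Hz and -1 to 5 s.
#' @inheritParams trial_spectrogram
#' @return An `ersp_map`: `values` (freq x time, dB), `freq`, `time`,
#'   `channel`, `condition`, `n_trials`.
#' @export
ersp <- function(epochs, channel, condition = NULL, freq_range = c(1, 30),
                 tf_range = c(-1, 5), win = 0.5, step = 0.25,
                 wavelet = "db4", maxlevel = 8, taper = TRUE) {
  stopifnot(inherits(epochs, "trial_epochs"))
  ch <- match(channel, epochs$channel_labels)
  if (is.na(ch)) stop("channel not in epochs: ", channel)
  keep <- if (is.null(condition)) seq_along(epochs$labels) else
    which(epochs$labels == condition)
  if (length(keep) == 0) stop("no trials of condition ", condition)
  fs <- epochs$fs
  X <- t(epochs$data[keep, ch, , drop = FALSE][, 1, ])   # time x trials
  if (length(keep) == 1) X <- matrix(epochs$data[keep, ch, ], ncol = 1)
  win_n <- round(win * fs)
  centers <- seq(tf_range[1], tf_range[2], by = step)
  centers_idx <- vapply(centers, \(cc) which.min(abs(epochs$time - cc)),
                        integer(1))
  res <- .tf_power(X, fs, centers_idx, win_n, freq_range, wavelet,
                   maxlevel, taper)
  P <- apply(res$power, c(1, 2), mean)                   # Eq.-style trial mean
  bw <- epochs$baseline_window
  base_cols <- centers - win / 2 >= bw[1] & centers + win / 2 <= bw[2]
  if (!any(base_cols))
    stop("no analysis window fits inside the baseline window")
  base <- rowMeans(P[, base_cols, drop = FALSE])
  values <- 10 * log10(sweep(P, 1, base, "/"))
  structure(
    list(values = values, freq = res$freq, time = centers,
         channel = channel,
         condition = if (is.null(condition)) "all" else condition,
         n_trials = length(keep), win = win, step = step,
         wavelet = wavelet),
    class = "ersp_map"
  )
}

#' @export
print.ersp_map <- function(x, ...) {
  cat(sprintf(
    "<ersp_map> %s / %s: %d freq x %d time bins (dB), N = %d trials\n",
    x$channel, x$condition, length(x$freq), length(x$time), x$n_trials))
  invisible(x)
}

#' ERD window mean
#'
#' Arithmetic mean of the ERSP values over all frequency-time bins in the
#' requested band and time window (the divisor is the bin count). A time
#' bin belongs to the window when its whole analysis window lies inside
#' it, the same support rule used for the baseline bins, so bins
#' straddling the window edges do not dilute the mean. More negative
#' values indicate stronger desynchronization.
#'
#' @param map An [ersp()] map.
#' @param band Frequency band `c(f1, f2)` in Hz (default alpha, 8-13).
#' @param window Time window `c(t1, t2)` in seconds (default the imagery
#'   phase, 1-5).
#' @return ERD in dB (scalar).
#' @export
erd <- function(map, band = c(8, 13), window = c(1, 5)) {
  stopifnot(inherits(map, "ersp_map"))
  half <- (map$win %||% 0) / 2
  rows <- map$freq >= band[1] & map$freq <= band[2]
  cols <- map$time - half >= window[1] & map$time + half <= window[2]
  if (!any(rows) || !any(cols))
    stop("empty ERD window: no bins inside band/window")
  mean(map$values[rows, cols])
}

#' Collapsed energy curves
#'
#' Collapses ERSP maps to one-dimensional energy curves and averages
#' across maps (subjects): `"over_time"` averages the time bins inside
#' `window` per frequency (energy vs frequency); `"over_frequency"`
#' averages the frequency bins inside `band` per time point (energy vs
#' time).
#'
#' @param maps A single `ersp_map` or a list of maps sharing axes.
#' @param mode `"over_time"` or `"over_frequency"`.
#' @param band,window Collapse ranges, as in [erd()].
#' @return A tibble with columns `axis` (Hz or s), `energy` (dB), `mode`,
#'   and `n_maps`, classed `energy_curve`.
#' @export
energy_curve <- function(maps, mode = c("over_time", "over_frequency"),
                         band = c(8, 13), window = c(1, 5)) {
  mode <- match.arg(mode)
  if (inherits(maps, "ersp_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1)
  f0 <- maps[[1]]$freq
  t0 <- maps[[1]]$time
  for (m in maps) {
    if (!isTRUE(all.equal(m$freq, f0)) || !isTRUE(all.equal(m$time, t0)))
      stop("maps must share frequency and time axes")
  }
  curves <- purrr::map(maps, function(m) {
    if (mode == "over_time") {
      cols <- t0 >= window[1] & t0 <= window[2]
      rowMeans(m$values[, cols, drop = FALSE])
    } else {
      rows <- f0 >= band[1] & f0 <= band[2]
      colMeans(m$values[rows, , drop = FALSE])
    }
  })
  avg <- Reduce(`+`, curves) / length(curves)
  out <- tibble::tibble(
    axis = if (mode == "over_time") f0 else t0,
    energy = avg, mode = mode, n_maps = length(maps)
  )
  class(out) <- c("energy_curve", class(out))
  out
}

#' FFT band power of a signal segment
#'
#' One-sided periodogram power summed over the bins inside `band`,
#' computed with the plain FFT (this is the estimator behind the alpha
#' modulation index; power is on the mean-square scale, so a unit-
#' amplitude in-band sinusoid gives about 0.5).
#'
#' @param x Numeric signal segment (e.g. the 1-5 s imagery window).
#' @param fs Sampling rate, Hz.
#' @param band `c(lo, hi)` in Hz, inside the Nyquist range.
#' @return Band power (scalar, microvolts squared).
#' @export
alpha_power_fft <- function(x, fs, band = c(8, 13)) {
  stopifnot(is.numeric(x), length(x) > 1, fs > 0)
  if (band[1] >= band[2] || band[2] > fs / 2)
    stop("band outside Nyquist range")
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n^2
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs >= band[1] & freqs < band[2]
  2 * sum(p[sel])
}
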