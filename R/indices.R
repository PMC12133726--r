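# Attention indices: alpha modulation index (AMI) from FFT alpha power at
# F4, and the theta/beta ratio (TBR) from wavelet-packet band energies,
# offline (continuous windows) and simulated-online (1-s buffers).

#' Alpha modulation index
#'
#' Normalized contrast `(alpha_right - alpha_wrong) /
#' (alpha_right + alpha_wrong)` between the mean alpha power of
#' correct-response ("right") and incorrect-response ("wrong") selection
#' trials. Bounded in `[-1, 1]`; negative values mean less alpha power on
#' correct trials.
#'
#' @param alpha_right,alpha_wrong Non-negative alpha-band powers.
#' @return The AMI (scalar).
#' @examples
#' ami(1, 3)   # -0.5
#' @export
ami <- function(alpha_right, alpha_wrong) {
  stopifnot(alpha_right >= 0, alpha_wrong >= 0)
  s <- alpha_right + alpha_wrong
  if (s == 0) stop("AMI undefined: both alpha powers are zero")
  (alpha_right - alpha_wrong) / s
}

#' Subject-level AMI from epochs
#'
#' Balances the trial classes (majority subsampled to the minority count,
#' deterministic under `seed`), computes FFT alpha power over the imagery
#' window at the given electrode for every trial, averages within the
#' correct-response and incorrect-response groups, and applies [ami()].
#' Under the key-press labelling rule the right/wrong partition coincides
#' with the Attention/Inattention labels, so one contrast per subject is
#' reported.
#'
#' @param epochs A `trial_epochs` with both conditions present.
#' @param electrode Channel for the alpha power (default `"F4"`).
#' @param band Alpha band, Hz.
#' @param window Imagery window, s.
#' @param seed Seed for the balancing subsample.
#' @return A one-row tibble: `ami`, `alpha_right`, `alpha_wrong`,
#'   `n_per_class`.
#' @export
subject_ami <- function(epochs, electrode = "F4", band = c(8, 13),
                        window = c(1, 5), seed = 1) {
  stopifnot(inherits(epochs, "trial_epochs"))
  ch <- match(electrode, epochs$channel_labels)
  if (is.na(ch)) stop("electrode not in epochs: ", electrode)
  balanced <- balance_trials(epochs, seed)
  sel <- balanced$time >= window[1] & balanced$time < window[2]
  powers <- vapply(seq_along(balanced$labels), function(k) {
    alpha_power_fft(balanced$data[k, ch, sel], balanced$fs, band)
  }, numeric(1))
  right <- mean(powers[balanced$labels == "Attention"])
  wrong <- mean(powers[balanced$labels == "Inattention"])
  tibble::tibble(
    ami = ami(right, wrong), alpha_right = right, alpha_wrong = wrong,
    n_per_class = sum(balanced$labels == "Attention")
  )
}

#' Theta/beta ratio
#'
#' `E_theta / E_beta`. A decrease marks attention, an increase
#' inattention.
#'
#' @param e_theta,e_beta Band energies; `e_beta` must be positive.
#' @return The TBR (scalar).
#' @examples
#' tbr(5, 2)   # 2.5
#' @export
tbr <- function(e_theta, e_beta) {
  stopifnot(e_theta >= 0)
  if (e_beta <= 0) stop("TBR undefined: beta band energy must be positive")
  e_theta / e_beta
}

# TBR of one 1-s (or `win`-second) buffer: the single code path shared by
# the offline series and the online monitor, so the two agree bit-for-bit
.window_tbr <- function(x, fs, theta = c(4, 8), beta = c(13, 30),
                        wavelet = "db4", maxlevel = 8) {
  e <- wpt_band_energy(x, fs, list(theta = theta, beta = beta),
                       wavelet = wavelet, maxlevel = maxlevel)
  vapply(seq_len(ncol(e)), \(j) tbr(e[1, j], e[2, j]), numeric(1))
}

#' Offline per-window TBR series
#'
#' Tiles the epoch with `win`-second windows (stride `step`, default
#' non-overlapping 1-s windows stamped by their end time), computes
#' wavelet-packet theta and beta energies per trial and window, takes the
#' ratio, and averages over trials within each condition.
#'
#' @param epochs A `trial_epochs`.
#' @param channel Channel for the band energies (default `"Cz"`).
#' @param range Time span to cover, seconds relative to the cue (default
#'   `c(0, 5)`, stamping windows at 1..5 s).
#' @param win,step Window length and stride in seconds (default 1 and 1).
#' @param theta,beta Band definitions, Hz.
#' @param wavelet,maxlevel Wavelet-packet parameters.
#' @return A tibble (`tbr_series`): `time` (window end, s), `condition`,
#'   `tbr` (trial mean), `n_trials`, `mode = "offline_continuous"`.
#' @export
tbr_offline_series <- function(epochs, channel = "Cz", range = c(0, 5),
                               win = 1, step = 1, theta = c(4, 8),
                               beta = c(13, 30), wavelet = "db4",
                               maxlevel = 8) {
  stopifnot(inherits(epochs, "trial_epochs"))
  ch <- match(channel, epochs$channel_labels)
  if (is.na(ch)) stop("channel not in epochs: ", channel)
  starts <- seq(range[1], range[2] - win, by = step)
  if (length(starts) < 1) stop("window does not fit inside the range")
  if (range[1] < epochs$time[1] || range[2] > epochs$time[length(epochs$time)])
    stop("TBR window range outside the epoch")
  fs <- epochs$fs
  win_n <- round(win * fs)
  conds <- unique(epochs$labels)
  out <- purrr::map(starts, function(s0) {
    i0 <- which.min(abs(epochs$time - s0))
    seg <- epochs$data[, ch, i0:(i0 + win_n - 1L), drop = FALSE]
    X <- matrix(seg[, 1, ], nrow = dim(seg)[1])      # trials x time
    vals <- .window_tbr(t(X), fs, theta, beta, wavelet, maxlevel)
    purrr::map(conds, function(cnd) {
      tibble::tibble(
        time = s0 + win, condition = cnd,
        tbr = mean(vals[epochs$labels == cnd]),
        n_trials = sum(epochs$labels == cnd)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  out$mode <- "offline_continuous"
  class(out) <- c("tbr_series", class(out))
  out
}

#' Simulated-online per-second TBR
#'
#' Processes a stream of 1-s buffers in arrival order with no look-ahead,
#' emitting one TBR value per complete buffer through the same
#' band-energy code path as [tbr_offline_series()], so replaying an
#' epoch's non-overlapping windows reproduces the offline values exactly.
#' Short or malformed buffers are skipped with a warning, leaving a gap
#' at that second.
#'
#' @param buffers A list of numeric vectors, one per second, each of
#'   length `fs` (e.g. from [epoch_buffers()]).
#' @param fs Sampling rate, Hz.
#' @param t0 Time stamp of the first buffer's start, seconds.
#' @param theta,beta,wavelet,maxlevel As in [tbr_offline_series()].
#' @return A tibble (`tbr_series`): `time` (buffer end, s), `tbr`,
#'   `mode = "online_buffered"`.
#' @export
tbr_online <- function(buffers, fs, t0 = 0, theta = c(4, 8),
                       beta = c(13, 30), wavelet = "db4", maxlevel = 8) {
  stopifnot(is.list(buffers), fs > 0)
  n_exp <- round(fs)
  rows <- purrr::imap(buffers, function(buf, k) {
    stamp <- t0 + k
    if (!is.numeric(buf) || length(buf) != n_exp || anyNA(buf)) {
      warning(sprintf("buffer ending at %g s skipped (malformed or short)",
                      stamp))
      return(NULL)
    }
    tibble::tibble(time = stamp,
                   tbr = .window_tbr(buf, fs, theta, beta, wavelet, maxlevel))
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  if (nrow(out) == 0)
    out <- tibble::tibble(time = numeric(), tbr = numeric())
  out$mode <- rep("online_buffered", nrow(out))
  class(out) <- c("tbr_series", class(out))
  out
}

#' Split an epoch into 1-s playback buffers
#'
#' Cuts one trial's channel signal into consecutive non-overlapping 1-s
#' buffers, the playback source for [tbr_online()].
#'
#' @param epochs A `trial_epochs`.
#' @param trial Trial index.
#' @param channel Channel label.
#' @param range Time span to replay, seconds (default `c(0, 5)`).
#' @return A list of numeric vectors of length `fs`.
#' @export
epoch_buffers <- function(epochs, trial, channel = "Cz", range = c(0, 5)) {
  stopifnot(inherits(epochs, "trial_epochs"))
  ch <- match(channel, epochs$channel_labels)
  if (is.na(ch)) stop("channel not in epochs: ", channel)
  fs <- epochs$fs
  starts <- seq(range[1], range[2] - 1, by = 1)
  purrr::map(starts, function(s0) {
    i0 <- which.min(abs(epochs$time - s0))
    epochs$data[trial, ch, i0:(i0 + round(fs) - 1L)]
  })
}

#' Per-subject ERD/AMI/TBR index table
#'
#' Runs the full index battery for one subject's epochs: condition-wise
#' alpha ERD at `erd_channel`, the balanced AMI contrast at
#' `ami_electrode`, and the mean 1-5 s TBR at `tbr_channel` per
#' condition.
#'
#' @param epochs A `trial_epochs` (baseline-corrected).
#' @param subject Subject identifier carried into the output.
#' @param erd_channel,ami_electrode,tbr_channel Channels (defaults Cz,
#'   F4, Cz).
#' @param seed Balancing seed for the AMI.
#' @param ... Passed to [ersp()] (window, wavelet, ... parameters).
#' @return A tibble with one row per condition: `subject`, `condition`,
#'   `erd`, `ami`, `tbr`.
#' @export
subject_indices <- function(epochs, subject = 1L, erd_channel = "Cz",
                            ami_electrode = "F4", tbr_channel = "Cz",
                            seed = 1, ...) {
  stopifnot(inherits(epochs, "trial_epochs"))
  conds <- intersect(c("Attention", "Inattention"), unique(epochs$labels))
  a <- if (length(conds) == 2)
    subject_ami(epochs, ami_electrode, seed = seed)$ami else NA_real_
  series <- tbr_offline_series(epochs, tbr_channel, range = c(0, 5))
  purrr::map(conds, function(cnd) {
    map <- ersp(epochs, erd_channel, cnd, ...)
    # windows fully inside the 1-5 s imagery span (stamps mark window ends)
    tb <- dplyr::filter(series, .data$condition == cnd, .data$time >= 2)
    tibble::tibble(subject = subject, condition = cnd,
                   erd = erd(map), ami = a, tbr = mean(tb$tbr))
  }) |> purrr::list_rbind()
}
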