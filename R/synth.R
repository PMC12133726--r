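# Synthetic multichannel motor-imagery EEG with known attention-dependent
# spectral structure: band-limited alpha/theta/beta oscillations (combs of
# random-phase sinusoids) riding on 1/f noise, with alpha suppression at Cz
# during the imagery window and condition-dependent alpha gain at F4.

# run expr under a local RNG seed, restoring the caller's RNG state
.local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.per_condition <- function(x, name) {
  if (length(x) == 1) x <- c(x, x)
  if (length(x) != 2) stop(name, " must have length 1 or 2 (Attention, Inattention)")
  stats::setNames(as.numeric(x), c("Attention", "Inattention"))
}

#' Configuration for the synthetic EEG generator
#'
#' Defines a cohort of subjects performing the arrow-selection / lower-limb
#' motor-imagery paradigm: per trial, Ready (-2 to -1 s), Start (-1 to 0 s),
#' Select cue with key press (0 to 1 s), motor imagery (1 to 5 s), Rest
#' (5 to 7 s), with t = 0 at the Select cue. Trials are labelled
#' Attention/Inattention by simulated key-press correctness.
#'
#' Spectral ground truth injected at generation time:
#' * alpha (8-13 Hz) comb at every channel, multiplied by
#'   `1 - erd_depth` at Cz during the 1-5 s imagery window;
#' * condition-dependent multiplicative alpha gain at F4 (drives the AMI);
#' * theta (4-8 Hz) and beta (13-30 Hz) combs whose per-condition band
#'   amplitudes set the target theta/beta ratio;
#' * per-channel 1/f^`noise_exponent` background noise scaled so the
#'   alpha-band oscillation-to-noise ratio equals `snr_db`.
#'
#' Amplitudes are band RMS values in microvolts. Default effect sizes are
#' calibrated so that the full analysis pipeline reproduces the group
#' statistics of a 14-subject reference cohort (attention ERD about
#' -1.77 dB, AMI about -0.042, TBR about 2.55 vs 2.58); see the package
#' vignette for the calibration.
#'
#' @param n_subjects,n_sets,trials_per_set Cohort layout (defaults 14
#'   subjects, 4 sets of 20 trials).
#' @param fs_raw Acquisition sampling rate in Hz (default 1000).
#' @param channel_labels Channels to generate; must be a subset of
#'   [montage_1020()] labels and include `"Cz"` and `"F4"`.
#' @param p_attention Probability that a trial is answered correctly and
#'   hence labelled Attention (default 0.7, giving the class imbalance the
#'   trial-balancing step needs).
#' @param erd_depth_attention,erd_depth_inattention Fractional alpha
#'   suppression at Cz during imagery, in `[0, 1)`.
#' @param erd_depth_sd Between-subject SD of a common additive offset on
#'   both depths (sign flips allowed; depths clamped to `(-0.6, 0.95)`).
#' @param f4_alpha_gain_attention,f4_alpha_gain_inattention Multiplicative
#'   alpha amplitude factors at F4 per condition.
#' @param ami_sd Between-subject SD of the injected alpha-modulation
#'   contrast at F4.
#' @param alpha_amp Band RMS amplitude of the alpha comb, microvolts.
#' @param theta_amp,beta_amp Band RMS amplitudes of the theta and beta
#'   combs; scalars or length-2 `(Attention, Inattention)` vectors.
#' @param tbr_sd Between-subject SD of a common multiplicative factor on
#'   the theta amplitude (spreads subject TBR levels).
#' @param noise_exponent Spectral slope of the 1/f background (default 1).
#' @param snr_db Alpha-band oscillation-to-noise ratio in dB (default 20).
#' @param seed Integer RNG seed; mandatory. The same seed yields
#'   bit-identical recordings.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_subjects = 14,
                         n_sets = 4,
                         trials_per_set = 20,
                         fs_raw = 1000,
                         channel_labels = montage_1020()$channel,
                         p_attention = 0.7,
                         erd_depth_attention = 0.254,
                         erd_depth_inattention = 0.0013,
                         erd_depth_sd = 0.21,
                         f4_alpha_gain_attention = 0.9636,
                         f4_alpha_gain_inattention = 1,
                         ami_sd = 0.045,
                         alpha_amp = 10,
                         theta_amp = c(15.70, 16.70),
                         beta_amp = 9.5,
                         tbr_sd = 0.06,
                         noise_exponent = 1,
                         snr_db = 20,
                         seed) {
  if (missing(seed)) stop("`seed` is mandatory in synth_config()")
  stopifnot(
    n_subjects >= 1, n_sets >= 1, trials_per_set >= 1,
    fs_raw > 60,
    p_attention >= 0, p_attention <= 1,
    erd_depth_attention >= 0, erd_depth_attention < 1,
    erd_depth_inattention >= 0, erd_depth_inattention < 1,
    erd_depth_sd >= 0, ami_sd >= 0, tbr_sd >= 0,
    f4_alpha_gain_attention > 0, f4_alpha_gain_inattention > 0,
    alpha_amp >= 0, noise_exponent >= 0,
    is.numeric(seed), length(seed) == 1
  )
  if (fs_raw <= 2 * 30) stop("fs_raw must exceed twice the 30 Hz band edge")
  unknown <- setdiff(channel_labels, montage_1020()$channel)
  if (length(unknown) > 0)
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(channel_labels)) stop("duplicate channel labels")
  if (!all(c("Cz", "F4") %in% channel_labels))
    stop("channel_labels must include Cz and F4")
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_sets = as.integer(n_sets),
    trials_per_set = as.integer(trials_per_set), fs_raw = fs_raw,
    channel_labels = channel_labels, p_attention = p_attention,
    erd_depth_attention = erd_depth_attention,
    erd_depth_inattention = erd_depth_inattention,
    erd_depth_sd = erd_depth_sd,
    f4_alpha_gain_attention = f4_alpha_gain_attention,
    f4_alpha_gain_inattention = f4_alpha_gain_inattention,
    ami_sd = ami_sd, alpha_amp = alpha_amp,
    theta_amp = .per_condition(theta_amp, "theta_amp"),
    beta_amp = .per_condition(beta_amp, "beta_amp"),
    tbr_sd = tbr_sd, noise_exponent = noise_exponent, snr_db = snr_db,
    seed = as.integer(seed)
  )
  structure(cfg, class = "synth_config")
}

# comb frequencies per band: dense enough that every ERSP row in the band
# carries oscillatory energy
.band_freqs <- list(
  alpha = seq(8, 13, by = 0.25),
  theta = seq(4.25, 7.75, by = 0.25),
  beta = seq(13.5, 29.5, by = 0.5)
)

# comb of random-phase sinusoids, with fresh phases and an amplitude
# renormalisation per 1-s segment so the realised band RMS equals `amp`
# in every second. A narrow band observed through 1-s windows has only a
# handful of spectral degrees of freedom: with trial-constant phases the
# per-window band energy fluctuates by tens of percent and consecutive
# windows are strongly correlated, which would swamp the small condition
# effects the cohort statistics are calibrated to. Per-segment phases
# mimic the burst-like phase drift of real rhythms while keeping
# segments statistically independent.
.comb_wave <- function(tt, freqs, amp, seg = NULL) {
  if (amp == 0) return(numeric(length(tt)))
  w <- numeric(length(tt))
  if (is.null(seg)) seg <- length(w)
  # 50-ms raised-cosine ramps at segment edges avoid phase-jump clicks,
  # whose broadband splatter would otherwise contaminate other bands
  ramp <- max(1L, round(0.05 * seg))
  for (s0 in seq(1, length(w), by = seg)) {
    ix <- s0:min(s0 + seg - 1, length(w))
    ph <- stats::runif(length(freqs), 0, 2 * pi)
    wseg <- colSums(sin(outer(2 * pi * freqs, tt[ix]) + ph))
    if (length(ix) > 2 * ramp) {
      env <- rep(1, length(ix))
      rr <- 0.5 - 0.5 * cos(pi * (seq_len(ramp) - 0.5) / ramp)
      env[seq_len(ramp)] <- rr
      env[length(ix) + 1 - seq_len(ramp)] <- rr
      wseg <- wseg * env
    }
    w[ix] <- wseg * amp / sqrt(mean(wseg^2))
  }
  w
}

# 1/f^beta noise with expected alpha-band power scaled to `band_power`;
# scaling uses the realised periodogram so the SNR is exact per channel
.pink_noise <- function(n, fs, exponent, band = c(8, 13), band_power) {
  freqs <- seq(0, fs / 2, by = fs / n)
  nf <- length(freqs)
  shape <- c(0, pmax(freqs[-1], 0.25)^(-exponent / 2))
  z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * shape
  # hermitian spectrum -> real signal
  if (n %% 2 == 0) {
    spec <- c(z[1:nf], Conj(z[(nf - 1):2]))
    spec[nf] <- complex(real = Re(z[nf]), imaginary = 0)
  } else {
    spec <- c(z[1:nf], Conj(z[nf:2]))
  }
  spec[1] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE)) / sqrt(n)
  if (band_power > 0) {
    px <- Mod(stats::fft(x))^2 / n^2
    sel <- which(freqs >= band[1] & freqs < band[2])
    realised <- 2 * sum(px[sel])
    x <- x * sqrt(band_power / realised)
  } else {
    x <- x * 0
  }
  x
}

# subject-level random effects around the configured means
.subject_effects <- function(cfg) {
  d_off <- stats::rnorm(1, 0, cfg$erd_depth_sd)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  base_ami <- {
    ga2 <- cfg$f4_alpha_gain_attention^2
    gi2 <- cfg$f4_alpha_gain_inattention^2
    (ga2 - gi2) / (ga2 + gi2)
  }
  ami <- clamp(base_ami + stats::rnorm(1, 0, cfg$ami_sd), -0.9, 0.9)
  gain_att <- cfg$f4_alpha_gain_inattention * sqrt((1 + ami) / (1 - ami))
  theta_mult <- clamp(1 + stats::rnorm(1, 0, cfg$tbr_sd), 0.5, 1.5)
  list(
    erd_depth = clamp(
      c(Attention = cfg$erd_depth_attention,
        Inattention = cfg$erd_depth_inattention) + d_off, -0.6, 0.95),
    f4_gain = c(Attention = gain_att,
                Inattention = cfg$f4_alpha_gain_inattention),
    theta_amp = cfg$theta_amp * theta_mult,
    beta_amp = cfg$beta_amp
  )
}

#' Generate one synthetic subject
#'
#' Produces a continuous multichannel recording covering
#' `n_sets * trials_per_set` trials of the 9-s paradigm timeline, with an
#' event marker at each Select cue carrying the arrow direction, the
#' simulated key response and its correctness, plus the per-trial ground
#' truth (condition label and injected effect sizes).
#'
#' @param config A [synth_config()].
#' @param subject_index Subject number (1-based); determines the
#'   subject-level RNG stream, so any subject can be regenerated alone.
#' @return A list with elements `recording` (a [raw_recording()]) and
#'   `truth` (a tibble, one row per trial).
#' @examples
#' cfg <- synth_config(n_subjects = 1, n_sets = 1, trials_per_set = 4,
#'                     fs_raw = 200, channel_labels = c("Cz", "F4"),
#'                     seed = 7)
#' subj <- generate_subject(cfg, 1)
#' subj$truth
#' @export
generate_subject <- function(config, subject_index) {
  stopifnot(inherits(config, "synth_config"))
  if (subject_index < 1 || subject_index != round(subject_index))
    stop("subject_index must be a positive integer")
  fs <- config$fs_raw
  trial_sec <- 9L                      # -2..7 s around the Select cue
  n_trials <- config$n_sets * config$trials_per_set
  trial_len <- trial_sec * fs
  n <- n_trials * trial_len
  chans <- config$channel_labels
  nchan <- length(chans)
  i_cz <- match("Cz", chans)
  i_f4 <- match("F4", chans)

  subj_seed <- (config$seed + 10007L * as.integer(subject_index)) %% 2147483629L
  .local_seed(subj_seed, {
    eff <- .subject_effects(config)

    cond <- ifelse(stats::runif(n_trials) < config$p_attention,
                   "Attention", "Inattention")
    arrow <- sample(c("up", "down"), n_trials, replace = TRUE)
    response <- ifelse(cond == "Attention", arrow,
                       ifelse(arrow == "up", "down", "up"))

    tt <- (seq_len(trial_len) - 1) / fs   # trial-local time from -2 s
    sel_rel <- tt - 2                     # seconds relative to Select cue
    mi <- sel_rel >= 1 & sel_rel < 5      # imagery window

    sig <- matrix(0, nchan, n)
    for (k in seq_len(n_trials)) {
      cnd <- cond[k]
      # alpha keeps trial-constant phases: its dB ratio is insensitive to
      # slow energy fluctuations, and per-second resegmentation would put
      # crossfade dips inside the imagery windows but never the baseline,
      # biasing the ERD. Theta/beta are resegmented per second so the 1-s
      # TBR windows are statistically independent; their dips cancel in
      # the theta/beta ratio.
      w_alpha <- .comb_wave(tt, .band_freqs$alpha, config$alpha_amp)
      w_theta <- .comb_wave(tt, .band_freqs$theta, eff$theta_amp[[cnd]], fs)
      w_beta <- .comb_wave(tt, .band_freqs$beta, eff$beta_amp[[cnd]], fs)
      env <- rep(1, trial_len)
      env[mi] <- 1 - eff$erd_depth[[cnd]]
      gains <- rep(1, nchan)
      gains[i_f4] <- eff$f4_gain[[cnd]]
      chunk <- outer(gains, w_alpha)
      chunk[i_cz, ] <- w_alpha * env
      chunk <- chunk + rep(w_theta + w_beta, each = nchan)
      sig[, ((k - 1) * trial_len + 1):(k * trial_len)] <- chunk
    }

    noise_band_power <- config$alpha_amp^2 / 10^(config$snr_db / 10)
    for (ch in seq_len(nchan)) {
      sig[ch, ] <- sig[ch, ] +
        .pink_noise(n, fs, config$noise_exponent, band_power = noise_band_power)
    }

    onset <- (seq_len(n_trials) - 1) * trial_len + 2 * fs + 1
    events <- tibble::tibble(
      sample = as.integer(onset), arrow = arrow, response = response,
      correct = response == arrow
    )
    truth <- tibble::tibble(
      subject = as.integer(subject_index),
      set = rep(seq_len(config$n_sets), each = config$trials_per_set),
      trial = seq_len(n_trials),
      sample = as.integer(onset),
      condition = cond, arrow = arrow, response = response,
      correct = response == arrow,
      erd_depth = unname(eff$erd_depth[cond]),
      f4_alpha_gain = unname(eff$f4_gain[cond]),
      theta_amp = unname(eff$theta_amp[cond]),
      beta_amp = unname(eff$beta_amp[cond])
    )
    list(
      recording = raw_recording(sig, fs, chans, events),
      truth = truth
    )
  })
}

#' Generate a synthetic cohort
#'
#' Runs [generate_subject()] for `config$n_subjects` subjects (each with
#' its own deterministic RNG stream derived from `config$seed`) and binds
#' the ground-truth tables.
#'
#' @param config A [synth_config()].
#' @return A list with `recordings` (list of [raw_recording()]) and
#'   `truth` (tibble with one row per generated trial across subjects).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  subjects <- purrr::map(seq_len(config$n_subjects),
                         \(i) generate_subject(config, i))
  list(
    recordings = purrr::map(subjects, "recording"),
    truth = purrr::list_rbind(purrr::map(subjects, "truth"))
  )
}
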