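# Shared small fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# small two-channel synthetic subject, preprocessed; memoised
tiny_epochs <- function() {
  if (is.null(.fixture_env$epochs)) {
    cfg <- tiny_config()
    subj <- generate_subject(cfg, 1)
    rc <- run_config(synth = list(seed = 1))
    .fixture_env$raw <- subj$recording
    .fixture_env$truth <- subj$truth
    .fixture_env$epochs <- preprocess_cohort(list(subj$recording), rc)[[1]]
  }
  .fixture_env$epochs
}

tiny_raw <- function() {
  tiny_epochs()
  .fixture_env$raw
}

tiny_truth <- function() {
  tiny_epochs()
  .fixture_env$truth
}

tiny_config <- function(...) {
  args <- list(n_subjects = 1, n_sets = 2, trials_per_set = 10, fs_raw = 200,
               channel_labels = c("Cz", "F4"), p_attention = 0.7, seed = 7)
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(synth_config, args)
}

# hand-built recording: given per-trial channel waveforms (list of
# channels x time matrices, 9 s each) concatenated with Select markers
manual_recording <- function(trials, fs, channel_labels,
                             arrow = NULL, response = NULL) {
  n_tr <- length(trials)
  len <- ncol(trials[[1]])
  sig <- do.call(cbind, trials)
  if (is.null(arrow)) arrow <- rep("up", n_tr)
  if (is.null(response)) response <- arrow
  events <- tibble::tibble(
    sample = as.integer((seq_len(n_tr) - 1) * len + 2 * fs + 1),
    arrow = arrow, response = response,
    correct = !is.na(response) & response == arrow
  )
  raw_recording(sig, fs, channel_labels, events)
}

# one 9-s trial whose named channels carry the given waveform functions
# of cue-relative time (others zero)
manual_trial <- function(fs, channel_labels, waves) {
  tt <- (seq_len(9 * fs) - 1) / fs - 2
  sig <- matrix(0, length(channel_labels), length(tt))
  for (ch in names(waves))
    sig[match(ch, channel_labels), ] <- waves[[ch]](tt)
  sig
}
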