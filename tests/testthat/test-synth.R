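# Synthetic generator: determinism, labelling, timeline, injected
# spectral structure.

test_that("same seed gives bit-identical recordings", {
  cfg <- tiny_config()
  a <- generate_subject(cfg, 1)
  b <- generate_subject(cfg, 1)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth, b$truth)
})

test_that("trial counts, markers and label rules follow the paradigm", {
  cfg <- tiny_config()
  subj <- generate_subject(cfg, 1)
  tr <- subj$truth
  expect_equal(nrow(tr), cfg$n_sets * cfg$trials_per_set)
  # Select cue 2 s after each 9-s trial starts
  expect_equal(tr$sample, (seq_len(nrow(tr)) - 1) * 9 * cfg$fs_raw +
                 2 * cfg$fs_raw + 1)
  expect_identical(tr$condition == "Attention", tr$correct)
  expect_identical(tr$correct, tr$response == tr$arrow)
  # degenerate label distribution
  all_att <- generate_subject(tiny_config(p_attention = 1), 1)$truth
  expect_true(all(all_att$condition == "Attention"))
})

test_that("label proportions converge to p_attention", {
  cfg <- tiny_config(n_sets = 4, trials_per_set = 50, p_attention = 0.7)
  tr <- generate_subject(cfg, 1)$truth
  p_hat <- mean(tr$condition == "Attention")
  expect_lt(abs(p_hat - 0.7), 3 * sqrt(0.7 * 0.3 / nrow(tr)))
})

test_that("cohort assembles one truth row per trial and per-subject streams", {
  cfg <- tiny_config(n_subjects = 3, n_sets = 1, trials_per_set = 5)
  co <- generate_cohort(cfg)
  expect_length(co$recordings, 3)
  expect_equal(nrow(co$truth), 15)
  # subject 2 regenerated alone matches its slot in the cohort
  solo <- generate_subject(cfg, 2)
  expect_identical(solo$recording$samples, co$recordings[[2]]$samples)
  single <- generate_cohort(tiny_config(n_subjects = 1, n_sets = 1,
                                        trials_per_set = 5))
  expect_length(single$recordings, 1)
  expect_equal(nrow(single$truth), 5)
})

test_that("injected alpha suppression matches (1 - depth)^2 in band power", {
  cfg <- tiny_config(n_sets = 4, trials_per_set = 50, p_attention = 1,
                     erd_depth_attention = 0.4, erd_depth_sd = 0,
                     theta_amp = 0, beta_amp = 0, snr_db = 40)
  subj <- generate_subject(cfg, 1)
  raw <- subj$recording
  icz <- match("Cz", raw$channel_labels)
  pow <- sapply(seq_len(nrow(subj$truth)), function(k) {
    s0 <- subj$truth$sample[k]
    base <- raw$samples[icz, (s0 - raw$fs):(s0 - 1)]
    # same 1-s length as the baseline so spectral leakage cancels in the ratio
    mi <- raw$samples[icz, (s0 + 2 * raw$fs):(s0 + 3 * raw$fs - 1)]
    c(alpha_power_fft(mi, raw$fs), alpha_power_fft(base, raw$fs))
  })
  # ratio of mean band powers, not mean of noisy per-trial ratios
  expect_equal(mean(pow[1, ]) / mean(pow[2, ]), 0.36, tolerance = 0.05)
})

test_that("zero injected effect gives a near-zero condition ERD difference", {
  # quiet theta/beta keep the per-window alpha-row noise small enough for
  # a small cohort to resolve the absence of an effect
  cfg <- tiny_config(n_subjects = 3, n_sets = 2, trials_per_set = 12,
                     erd_depth_attention = 0, erd_depth_inattention = 0,
                     erd_depth_sd = 0, p_attention = 0.5,
                     theta_amp = 5, beta_amp = 4)
  co <- generate_cohort(cfg)
  rc <- run_config(synth = list(seed = 1))
  eps <- preprocess_cohort(co$recordings, rc)
  diffs <- sapply(eps, function(ep) {
    erd(ersp(ep, "Cz", "Attention")) - erd(ersp(ep, "Cz", "Inattention"))
  })
  expect_lt(abs(mean(diffs)), 0.4)
})

test_that("config validation guards counts, labels and probabilities", {
  expect_error(tiny_config(n_subjects = 0))
  expect_error(tiny_config(channel_labels = c("Cz", "F4", "XX")), "unknown")
  expect_error(tiny_config(channel_labels = c("F4", "F3")), "Cz")
  expect_error(tiny_config(p_attention = 1.5))
  expect_error(tiny_config(erd_depth_attention = 1))
  expect_error(synth_config(n_subjects = 1), "seed")
  expect_error(tiny_config(fs_raw = 50))
})
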