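# Spectral analysis: spectrogram band separation, ERSP dB referencing,
# ERD arithmetic, energy curves, FFT band power.

test_that("spectrogram separates tones into their bands", {
  fs <- 200
  t <- (0:(6 * fs - 1)) / fs
  tone10 <- trial_spectrogram(sin(2 * pi * 10 * t), fs)
  band <- function(sp, lo, hi) sum(sp$power[sp$freq >= lo & sp$freq < hi, ])
  expect_gt(band(tone10, 8, 13) / band(tone10, 1, 30), 0.7)
  z <- trial_spectrogram(rep(0, length(t)), fs)
  expect_equal(max(abs(z$power)), 0)
  two <- trial_spectrogram(sin(2 * pi * 6 * t) + sin(2 * pi * 20 * t), fs)
  expect_gt(band(two, 4, 8), 10 * band(two, 9, 12))
  expect_gt(band(two, 18, 22), 10 * band(two, 9, 12))
  expect_error(trial_spectrogram(rnorm(20), fs), "shorter than")
})

test_that("constant-power signal gives a 0 dB map; trial averaging is exact", {
  fs <- 200
  # stationary tone: power identical in baseline and task windows
  trial <- manual_trial(fs, "Cz",
                        list(Cz = function(t) sin(2 * pi * 10 * t)))
  raw <- manual_recording(list(trial, trial, trial), fs, "Cz")
  ep <- epoch_trials(raw)
  m3 <- ersp(ep, "Cz", "Attention")
  rows <- m3$freq >= 9 & m3$freq <= 11
  expect_lt(max(abs(m3$values[rows, ])), 0.05)
  # N identical trials equal a single trial
  raw1 <- manual_recording(list(trial), fs, "Cz")
  m1 <- ersp(epoch_trials(raw1), "Cz", "Attention")
  expect_equal(m1$values, m3$values, tolerance = 1e-10)
  expect_equal(m3$n_trials, 3)
  expect_error(ersp(ep, "Cz", "Inattention"), "no trials")
  expect_error(ersp(ep, "F7", "Attention"), "not in epochs")
})

test_that("alpha power at 0.36 x baseline reads about -4.44 dB", {
  fs <- 200
  wave <- function(t) {
    env <- ifelse(t >= 1 & t < 5, 0.6, 1)
    env * sin(2 * pi * 10 * t)
  }
  raw <- manual_recording(list(manual_trial(fs, "Cz", list(Cz = wave))),
                          fs, "Cz")
  m <- ersp(epoch_trials(raw), "Cz", "Attention")
  rows <- m$freq >= 9.5 & m$freq <= 10.5
  cols <- m$time - m$win / 2 >= 1 & m$time + m$win / 2 <= 5
  expect_equal(mean(m$values[rows, cols]), 10 * log10(0.36),
               tolerance = 0.25)
})

test_that("ERSP is invariant under trial reordering", {
  ep <- tiny_epochs()
  perm <- rev(seq_along(ep$labels))
  ep2 <- ep
  ep2$data <- ep$data[perm, , ]
  ep2$labels <- ep$labels[perm]
  expect_equal(ersp(ep, "Cz", "Attention")$values,
               ersp(ep2, "Cz", "Attention")$values)
})

test_that("grand-average ERSP of white noise is flat", {
  fs <- 200
  set.seed(8)
  trials <- replicate(100, matrix(rnorm(9 * fs), 1), simplify = FALSE)
  raw <- manual_recording(trials, fs, "Cz")
  m <- ersp(epoch_trials(raw), "Cz", "Attention")
  expect_lt(abs(mean(m$values)), 0.5)
})

test_that("ERD is the window mean and is linear in the map", {
  ep <- tiny_epochs()
  m <- ersp(ep, "Cz", "Attention")
  const <- m
  const$values[] <- -2
  expect_equal(erd(const), -2)
  half <- m
  nf <- length(m$freq)
  half$values[] <- rep(c(-4, 0), length.out = nf)   # alternate by row
  rows <- half$freq >= 8 & half$freq <= 13
  expect_equal(erd(half), mean(rep(c(-4, 0), length.out = nf)[rows]))
  # linearity
  twice <- m
  twice$values <- 2 * m$values
  expect_equal(erd(twice), 2 * erd(m))
  expect_error(erd(m, band = c(40, 50)), "empty ERD window")
})

test_that("energy curves collapse maps and order conditions by injected depth", {
  ep <- tiny_epochs()
  ma <- ersp(ep, "Cz", "Attention")
  const <- ma
  const$values[] <- -1.5
  flat <- energy_curve(const, "over_time")
  expect_true(all(abs(flat$energy + 1.5) < 1e-12))
  expect_equal(nrow(flat), length(ma$freq))
  one <- energy_curve(list(ma), "over_frequency")
  expect_equal(one$energy, colMeans(ma$values[ma$freq >= 8 & ma$freq <= 13, ]))
  # attention (deeper suppression) lies below inattention in the alpha band
  mi <- ersp(ep, "Cz", "Inattention")
  ca <- energy_curve(ma, "over_time")
  ci <- energy_curve(mi, "over_time")
  alpha <- ca$axis >= 8 & ca$axis <= 13
  expect_lt(mean(ca$energy[alpha]), mean(ci$energy[alpha]))
  bad <- mi
  bad$freq <- bad$freq + 1
  expect_error(energy_curve(list(ma, bad)), "share")
})

test_that("FFT band power satisfies Parseval-style checks", {
  fs <- 200
  t <- (0:(4 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  expect_equal(alpha_power_fft(x, fs), mean(x^2), tolerance = 0.05)
  y <- sin(2 * pi * 20 * t)
  expect_lt(alpha_power_fft(y, fs, c(8, 13)), 0.01 * mean(y^2))
  expect_equal(alpha_power_fft(rep(0, 100), fs), 0)
  expect_error(alpha_power_fft(x, fs, c(90, 120)), "Nyquist")
})
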