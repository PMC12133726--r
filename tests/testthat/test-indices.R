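# Attention indices: AMI identities, subject-level AMI, TBR identities,
# offline series, online buffering.

test_that("AMI identities hold", {
  expect_equal(ami(2, 2), 0)
  expect_equal(ami(1, 3), -0.5)
  expect_equal(ami(0, 2), -1)
  expect_equal(ami(2, 0), 1)
  for (p in list(c(0.3, 1.2), c(5, 5), c(0, 7), c(2.5, 0.1))) {
    expect_equal(ami(p[1], p[2]), -ami(p[2], p[1]))
    expect_lte(abs(ami(p[1], p[2])), 1)
  }
  expect_error(ami(0, 0), "both alpha powers are zero")
  expect_error(ami(-1, 2))
})

test_that("subject AMI recovers constructed alpha-power contrasts", {
  fs <- 200
  mk_trial <- function(amp) manual_trial(fs, c("Cz", "F4"), list(
    F4 = function(t) amp * sin(2 * pi * 10 * t)))
  # correct trials amp 1 (power 0.5), wrong trials amp sqrt(2) (power 1)
  trials <- c(replicate(6, mk_trial(1), simplify = FALSE),
              replicate(4, mk_trial(sqrt(2)), simplify = FALSE))
  arrow <- rep("up", 10)
  response <- c(rep("up", 6), rep("down", 4))
  raw <- manual_recording(trials, fs, c("Cz", "F4"), arrow, response)
  ep <- epoch_trials(raw)
  res <- subject_ami(ep, "F4", seed = 3)
  expect_equal(res$ami, (0.5 - 1) / (0.5 + 1), tolerance = 0.02)
  expect_equal(res$n_per_class, 4)
  # equal powers give AMI ~ 0
  eq <- manual_recording(c(replicate(5, mk_trial(1), simplify = FALSE),
                           replicate(5, mk_trial(1), simplify = FALSE)),
                         fs, c("Cz", "F4"), arrow,
                         c(rep("up", 5), rep("down", 5)))
  expect_lt(abs(subject_ami(epoch_trials(eq), "F4", seed = 1)$ami), 1e-6)
  # balancing determinism
  r1 <- subject_ami(ep, "F4", seed = 11)
  r2 <- subject_ami(ep, "F4", seed = 11)
  expect_identical(r1, r2)
  expect_error(subject_ami(ep, "Oz"), "not in epochs")
})

test_that("TBR identities hold", {
  expect_equal(tbr(1, 1), 1)
  expect_equal(tbr(5, 2), 2.5)
  expect_equal(tbr(0, 2), 0)
  expect_error(tbr(1, 0), "beta band energy")
  expect_error(tbr(-1, 2))
})

test_that("TBR is invariant under signal scaling", {
  ep <- tiny_epochs()
  s1 <- tbr_offline_series(ep, "Cz")
  scaled <- ep
  scaled$data <- ep$data * 3.7
  s2 <- tbr_offline_series(scaled, "Cz")
  expect_equal(s1$tbr, s2$tbr, tolerance = 1e-12)
})

test_that("stationary two-tone signal gives a flat series at the energy ratio", {
  fs <- 200
  wave <- function(t) 2 * sin(2 * pi * 6 * t) + sin(2 * pi * 20 * t)
  raw <- manual_recording(list(manual_trial(fs, "Cz", list(Cz = wave))),
                          fs, "Cz")
  ep <- epoch_trials(raw)
  s <- tbr_offline_series(ep, "Cz")
  expect_equal(s$time, 1:5)
  expect_lt(diff(range(s$tbr)) / mean(s$tbr), 0.25)
  # closed form: energies scale with squared amplitudes, ratio ~ 4
  e <- wpt_band_energy(wave((0:(fs - 1)) / fs), fs,
                       list(th = c(4, 8), be = c(13, 30)))
  expect_equal(mean(s$tbr), e[1] / e[2], tolerance = 0.3)
})

test_that("synthetic attention TBR lies below inattention over the series", {
  cfg <- tiny_config(n_subjects = 2, n_sets = 4, seed = 31)
  co <- generate_cohort(cfg)
  rc <- run_config(synth = list(seed = 1))
  eps <- preprocess_cohort(co$recordings, rc)
  ser <- cohort_tbr_series(eps, rc)
  means <- ser |>
    dplyr::filter(.data$time >= 2) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(tbr = mean(.data$tbr))
  expect_lt(means$tbr[means$condition == "Attention"],
            means$tbr[means$condition == "Inattention"])
})

test_that("online TBR equals the offline non-overlapping series bit-for-bit", {
  ep <- tiny_epochs()
  k <- 2
  single <- ep
  single$data <- ep$data[k, , , drop = FALSE]
  single$labels <- ep$labels[k]
  off <- tbr_offline_series(single, "Cz", range = c(0, 5))
  on <- tbr_online(epoch_buffers(ep, k, "Cz", c(0, 5)), ep$fs, t0 = 0)
  expect_identical(on$tbr, off$tbr)
  expect_identical(on$time, off$time)
})

test_that("online stream handles empty and malformed buffers", {
  empty <- tbr_online(list(), 200)
  expect_equal(nrow(empty), 0)
  ep <- tiny_epochs()
  bufs <- epoch_buffers(ep, 1, "Cz", c(0, 5))
  bufs[[3]] <- bufs[[3]][1:50]   # short buffer
  expect_warning(s <- tbr_online(bufs, ep$fs, t0 = 0), "skipped")
  expect_equal(s$time, c(1, 2, 4, 5))
  full <- tbr_online(epoch_buffers(ep, 1, "Cz", c(0, 5)), ep$fs, t0 = 0)
  expect_identical(s$tbr, full$tbr[full$time %in% s$time])
})

test_that("per-subject index battery reports both conditions", {
  si <- subject_indices(tiny_epochs(), subject = 4L)
  expect_equal(sort(si$condition), c("Attention", "Inattention"))
  expect_equal(si$subject, c(4L, 4L))
  expect_equal(si$ami[1], si$ami[2])   # one balanced contrast per subject
  expect_true(all(si$tbr > 0))
})
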