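test_that("R-wave detection finds every beat of a clean ECG", {
  ecg <- simulate_ecg(60, duration_s = 30, sampling_rate = 500)
  b <- detect_beats(ecg, "r_wave")
  expect_equal(nrow(b), 30)
  gaps <- diff(b$onset_time_s)
  expect_true(all(abs(gaps - 1.0) <= 0.01))
})

test_that("featureless signals raise an insufficient-beats error", {
  flat <- sampled_signal(rep(3, 1000), 100)
  expect_error(detect_beats(flat, "r_wave"), "insufficient beats")
  expect_error(detect_beats(flat, "foot"), "insufficient beats")
})

test_that("a beat implying a sub-physiologic period is excluded", {
  ecg <- simulate_ecg(60, duration_s = 10, sampling_rate = 500)
  v <- ecg$value
  # inject a spurious extra R spike 150 ms after the 5th beat
  spike_at <- round((0.2 + 4 * 1.0 + 0.15) * 500)
  i <- spike_at + (-5:5)
  v[i] <- v[i] + 0.95 * exp(-((i - spike_at)^2) / (2 * 5^2))
  with_spike <- sampled_signal(v, 500)
  expect_equal(nrow(detect_beats(with_spike, "r_wave")),
               nrow(detect_beats(ecg, "r_wave")))
})

test_that("beat detection is shift-equivariant", {
  ecg <- simulate_ecg(60, duration_s = 12, sampling_rate = 500)
  b0 <- detect_beats(ecg, "r_wave")
  k <- 250
  shifted <- sampled_signal(c(rep(0, k), ecg$value), 500)
  b1 <- detect_beats(shifted, "r_wave")
  common <- intersect(b0$onset_idx + k, b1$onset_idx)
  expect_gte(length(common), nrow(b0) - 1)
})

test_that("averaging identical beats reproduces a single beat", {
  beat <- wk_beat(fs = 500)
  v <- rep(beat$value, 20)
  sig <- sampled_signal(v, 500, "mmHg")
  beats <- beat_set(seq(1, length(v), by = nrow(beat)), 500, "foot")
  avg <- ensemble_average(sig, beats, epoch_s = NULL)
  expect_equal(avg$value, beat$value, tolerance = 1e-9)
  expect_equal(attr(avg, "n_beats_averaged"), 19)
})

test_that("ensemble averaging is idempotent on its own output", {
  beat <- wk_beat(fs = 500)
  sig <- sampled_signal(rep(beat$value, 10), 500, "mmHg")
  beats <- beat_set(seq(1, nrow(sig), by = nrow(beat)), 500, "foot")
  avg1 <- ensemble_average(sig, beats, epoch_s = NULL)
  tiled <- sampled_signal(rep(avg1$value, 8), 500, "mmHg")
  beats2 <- beat_set(seq(1, nrow(tiled), by = length(avg1$value)), 500, "foot")
  avg2 <- ensemble_average(tiled, beats2, epoch_s = NULL)
  expect_equal(avg2$value, avg1$value, tolerance = 1e-12)
})

test_that("ensemble averaging shrinks noise like one over root n", {
  beat <- wk_beat(fs = 500)
  n_beats <- 25
  withr::with_seed(21, {
    sigma <- 2
    v <- rep(beat$value, n_beats) + rnorm(nrow(beat) * n_beats, sd = sigma)
  })
  sig <- sampled_signal(v, 500, "mmHg")
  beats <- beat_set(seq(1, length(v), by = nrow(beat)), 500, "foot")
  avg <- suppressMessages(ensemble_average(sig, beats, epoch_s = NULL))
  resid_sd <- sd(avg$value[seq_len(nrow(beat))] - beat$value)
  expected <- 2 / sqrt(attr(avg, "n_beats_averaged"))
  expect_gt(resid_sd / expected, 0.7)
  expect_lt(resid_sd / expected, 1.4)
})

test_that("a 20 s epoch at 60 beats/min averages 19-20 beats", {
  wk <- wk_fixture(fs = 500, n_beats = 25)
  beats <- detect_beats(wk$pressure, "foot")
  avg <- ensemble_average(wk$pressure, beats, epoch_s = 20)
  expect_true(attr(avg, "n_beats_averaged") %in% c(19, 20))
})

test_that("epochs longer than the recording raise a window error", {
  wk <- wk_fixture(fs = 500, n_beats = 5)
  beats <- detect_beats(wk$pressure, "foot")
  expect_error(ensemble_average(wk$pressure, beats, epoch_s = 60),
               "window error")
})

test_that("amplitude-artifact beats are rejected from the ensemble", {
  beat <- wk_beat(fs = 500)
  n <- nrow(beat)
  v <- rep(beat$value, 10)
  withr::with_seed(3, v <- v + rnorm(length(v), sd = 0.05))
  v[(4 * n + 1):(5 * n)] <- v[(4 * n + 1):(5 * n)] * 3 # corrupted beat
  sig <- sampled_signal(v, 500, "mmHg")
  beats <- beat_set(seq(1, length(v), by = n), 500, "foot")
  expect_message(avg <- ensemble_average(sig, beats, epoch_s = NULL),
                 "artifact")
  expect_equal(attr(avg, "n_beats_averaged"), 8)
})

test_that("segmentation conserves samples under the half-open convention", {
  wk <- wk_fixture(fs = 500, n_beats = 8)
  beats <- detect_beats(wk$pressure, "foot")
  segs <- hemowave:::segment_beats(beats, nrow(wk$pressure))
  expect_equal(sum(lengths(segs)),
               max(beats$onset_idx) - min(beats$onset_idx))
  expect_false(any(duplicated(unlist(segs))))
})

test_that("derivatives match closed forms", {
  t <- seq(0, 1, by = 1e-3)
  s <- ensemble_beat(sin(2 * pi * t), 1000)
  d <- signal_derivative(s)
  expect_equal(max(d$value), 2 * pi, tolerance = 1e-3)

  const <- ensemble_beat(rep(5, 100), 100)
  expect_true(all(signal_derivative(const)$value == 0))
  expect_equal(signal_mean(const), 5)

  ramp <- ensemble_beat(3.5 * (0:99) / 100, 100)
  expect_equal(signal_derivative(ramp)$value, rep(3.5, 100), tolerance = 1e-9)
})
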