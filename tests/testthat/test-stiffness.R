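test_that("intersecting-tangents foot is exact on flat-then-ramp input", {
  v <- c(rep(2, 50), 2 + 0.04 * (1:50))
  beat <- sampled_signal(v, 100)
  expect_equal(detect_foot(beat), 0.49, tolerance = 1e-9) # ramp onset
})

test_that("foot detection is shift-equivariant", {
  beat <- wk_beat(fs = 1000)
  # pad so the upstroke sits away from the window edge in both copies
  a <- sampled_signal(c(rep(beat$value[1], 100), beat$value), 1000)
  b <- sampled_signal(c(rep(beat$value[1], 180), beat$value), 1000)
  expect_equal(detect_foot(b) - detect_foot(a), 0.08, tolerance = 1e-3)
})

test_that("foot jitter stays below 2 ms at 40 dB SNR", {
  beat <- wk_beat(fs = 1000)
  pulsatile <- beat$value - min(beat$value)
  noise_sd <- sqrt(mean(pulsatile^2)) / 100 # 40 dB below signal RMS
  feet <- withr::with_seed(99, {
    replicate(200, {
      noisy <- sampled_signal(beat$value + rnorm(nrow(beat), sd = noise_sd), 1000)
      detect_foot(noisy)
    })
  })
  expect_lt(sd(feet), 2e-3)
})

test_that("a falling waveform has no detectable upstroke", {
  expect_error(detect_foot(sampled_signal(seq(10, 0, length.out = 50), 100)),
               "no upstroke")
})

test_that("cfPWV recovers the programmed velocity from a delayed pair", {
  tpl <- wk_fixture(n_beats = 8)$pressure
  pair <- simulate_delayed_pair(tpl, 60, 750)
  ecg <- simulate_ecg(60, duration_s = 8, sampling_rate = 1000,
                      first_r_s = 0.85)
  beats <- detect_beats(ecg, "r_wave")
  res <- cfpwv(pair$proximal, pair$distal, beats, 60)
  expect_equal(res$cfpwv, 750, tolerance = 0.02 * 750)
  expect_equal(res$transit_time_s, 0.08, tolerance = 2e-3)
})

test_that("cfPWV is linear in path distance", {
  tpl <- wk_fixture(n_beats = 8)$pressure
  pair <- simulate_delayed_pair(tpl, 60, 750)
  ecg <- simulate_ecg(60, duration_s = 8, sampling_rate = 1000,
                      first_r_s = 0.85)
  beats <- detect_beats(ecg, "r_wave")
  r1 <- cfpwv(pair$proximal, pair$distal, beats, 60)
  r2 <- cfpwv(pair$proximal, pair$distal, beats, 120)
  expect_equal(r2$cfpwv, 2 * r1$cfpwv, tolerance = 1e-12)
})

test_that("identical signals produce an ordering error", {
  tpl <- wk_fixture(n_beats = 8)$pressure
  ecg <- simulate_ecg(60, duration_s = 8, sampling_rate = 1000,
                      first_r_s = 0.85)
  beats <- detect_beats(ecg, "r_wave")
  expect_error(cfpwv(tpl, tpl, beats, 60), "ordering error")
})

test_that("beta stiffness evaluates the printed formula", {
  expect_equal(beta_stiffness(120, 80, 6.05, 5.50), log(1.5) / 0.1,
               tolerance = 1e-12)
  expect_equal(beta_stiffness(100, 100, 6, 5), 0) # ln(1) = 0
  expect_equal(beta_stiffness(240, 160, 6.05, 5.50),
               beta_stiffness(120, 80, 6.05, 5.50), tolerance = 1e-12)
  expect_error(beta_stiffness(120, 80, 5.5, 5.5), "zero-strain")
  expect_error(beta_stiffness(120, -1, 6, 5), "domain")
})

test_that("beta stiffness agrees with an independent algebraic form", {
  withr::with_seed(12, {
    ps <- runif(1000, 90, 200)
    pd <- runif(1000, 50, 89)
    dd <- runif(1000, 4, 8)
    ds <- dd * (1 + runif(1000, 0.02, 0.2))
  })
  ours <- beta_stiffness(ps, pd, ds, dd)
  # same quantity written differently: (log ps - log pd) / (ds/dd - 1)
  other <- (log(ps) - log(pd)) / (ds / dd - 1)
  expect_lt(max(abs(ours - other)), 1e-12)
})

test_that("volumetric flow converts velocity and area correctly", {
  v <- sampled_signal(rep(40, 100), 100, "cm/s")
  fl <- volumetric_flow(v, 6)
  expect_equal(attr(fl, "cross_sectional_area_cm2"), 0.2827, tolerance = 1e-3)
  expect_equal(fl$value[1], 11.31, tolerance = 1e-3)
  expect_equal(sig_units(fl), "mL/s")
  zero <- volumetric_flow(sampled_signal(rep(0, 10), 10, "cm/s"), 6)
  expect_true(all(zero$value == 0))
  doubled <- volumetric_flow(v, 6 * sqrt(2))
  expect_equal(doubled$value, 2 * fl$value, tolerance = 1e-12)
  expect_error(volumetric_flow(v, -2), "domain")
})

test_that("characteristic impedance is exact on proportional waves", {
  wk <- wk_fixture(n_beats = 1)
  q <- wk$flow
  p <- sig_replace(wk$pressure, 0.1 * q$value + 80)
  expect_equal(characteristic_impedance(p, q), 0.1, tolerance = 1e-12)
  # doubling flow at fixed pressure halves the estimate
  q2 <- sig_replace(q, 2 * q$value)
  expect_equal(characteristic_impedance(p, q2), 0.05, tolerance = 1e-12)
})

test_that("degenerate flow raises an error", {
  wk <- wk_fixture(n_beats = 1)
  falling <- sig_replace(wk$flow, seq(10, 0, length.out = nrow(wk$flow)))
  expect_error(characteristic_impedance(wk$pressure, falling),
               "degenerate flow")
})

test_that("wave separation returns a pure forward wave when dP = Zc dQ", {
  wk <- wk_fixture(n_beats = 1)
  q <- wk$flow
  p <- sig_replace(wk$pressure, 0.1 * q$value + 80)
  ws <- wave_separation(p, q, 0.1)
  expect_equal(ws$pb_amplitude, 0, tolerance = 1e-9)
  expect_equal(ws$reflection_index, 0, tolerance = 1e-9)
})

test_that("injected reflections are recovered by the reflection index", {
  wk <- wk_fixture(n_beats = 1)
  fs <- 1000
  pf <- wk$pressure$value - min(wk$pressure$value)
  shift <- round(0.12 * fs)
  pb <- 0.30 * c(rep(0, shift), pf[1:(length(pf) - shift)])
  zc <- 0.1
  p <- sig_replace(wk$pressure, 70 + pf + pb)
  q <- sig_replace(wk$flow, (pf - pb) / zc)
  ws <- wave_separation(p, q, zc)
  expect_equal(ws$reflection_index, 0.30, tolerance = 0.10)
  expect_equal(ws$pf_amplitude, max(pf), tolerance = 0.01 * max(pf))
})

test_that("forward plus backward reconstructs the pulsatile pressure", {
  withr::with_seed(31, {
    for (i in 1:5) {
      wk <- wk_fixture(zc = runif(1, 0.05, 0.2), hr = runif(1, 50, 90),
                       fs = 500, n_beats = 1, noise_sd = runif(1, 0, 2),
                       seed = sample.int(1e6, 1))
      ws <- wave_separation(wk$pressure, wk$flow, runif(1, 0.05, 0.3))
      dp <- wk$pressure$value - min(wk$pressure$value)
      expect_lt(max(abs(ws$waves$pf + ws$waves$pb - dp)), 1e-9)
    }
  })
})

test_that("wave separation validates zc and warns on RIx above 1", {
  wk <- wk_fixture(n_beats = 1)
  expect_error(wave_separation(wk$pressure, wk$flow, -1), "domain")
  # backward wave dominating: flip the flow sign
  flipped <- sig_replace(wk$flow, -wk$flow$value)
  expect_warning(wave_separation(wk$pressure, flipped, 0.2),
                 "exceeds 1")
})
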