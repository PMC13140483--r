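test_that("Windkessel diastolic decay follows the RC time constant", {
  wk <- wk_fixture()
  p <- wk$pressure$value
  q <- wk$flow$value
  # diastole of the first emitted beat, clear of the ejection transition
  dia <- which(q[1:1000] == 0)
  dia <- dia[dia > 400 & dia < 950]
  slope <- coef(lm(log(p[dia]) ~ wk$pressure$time_s[dia]))[[2]]
  expect_equal(-1 / slope, 1.0 * 1.5, tolerance = 1e-3) # tau = R * C
})

test_that("Windkessel output is periodic at steady state", {
  wk <- wk_fixture(n_beats = 2)
  p <- wk$pressure$value
  pp <- diff(range(p[1:1000]))
  expect_lt(max(abs(p[1:1000] - p[1001:2000])), 1e-6 * pp)
})

test_that("Windkessel generators are deterministic and validate parameters", {
  a <- wk_fixture(noise_sd = 1, seed = 11)
  b <- wk_fixture(noise_sd = 1, seed = 11)
  expect_identical(a$pressure$value, b$pressure$value)
  expect_identical(a$flow$value, b$flow$value)
  c <- wk_fixture(noise_sd = 1, seed = 12)
  expect_false(identical(a$pressure$value, c$pressure$value))
  expect_error(simulate_windkessel(-0.1, 1, 1.5, 60, 70), "zc")
  expect_error(simulate_windkessel(0.1, 1, 1.5, 60, 70, sampling_rate = 100),
               "200 Hz")
  expect_error(
    simulate_windkessel(0.1, 1, 1.5, 60, 70, ejection_fraction_of_cycle = 1.2),
    "ejection_fraction"
  )
})

test_that("Windkessel flow integrates to the stroke volume each beat", {
  wk <- wk_fixture(hr = 75, fs = 500)
  q <- wk$flow$value
  per_beat <- round(500 * 60 / 75)
  expect_equal(sum(q[1:per_beat]) / 500, 70, tolerance = 1e-3)
})

test_that("delayed pair embeds the requested transit delay", {
  tpl <- wk_fixture(n_beats = 6)$pressure
  pair <- simulate_delayed_pair(tpl, distance_cm = 60, true_pwv = 750)
  expect_equal(pair$true_delay_s, 0.08)
  # cross-correlation peak sits at the embedded delay
  cc <- sapply(0:200, function(k) {
    n <- nrow(tpl)
    cor(pair$proximal$value[1:(n - k)], pair$distal$value[(k + 1):n])
  })
  expect_equal((which.max(cc) - 1) / 1000, 0.08, tolerance = 2e-3)
})

test_that("delayed pair degenerates to identity as PWV grows", {
  tpl <- wk_fixture(n_beats = 2)$pressure
  pair <- simulate_delayed_pair(tpl, 60, 1e12)
  expect_equal(pair$distal$value, pair$proximal$value, tolerance = 1e-9)
})

test_that("delays longer than one cycle are rejected", {
  tpl <- wk_fixture(n_beats = 2)$pressure
  expect_error(simulate_delayed_pair(tpl, 60, 50), "exceeds one cardiac cycle")
})

test_that("Doppler envelope hits its systolic/diastolic/mean targets", {
  env <- simulate_doppler_envelope(98, 46, 63, duration_s = 10)
  per_beat <- 200 # one beat at 60 beats/min, 200 Hz
  beats <- matrix(env$value[1:(5 * per_beat)], nrow = per_beat)
  expect_equal(apply(beats, 2, max), rep(98, 5), tolerance = 0.005)
  expect_equal(apply(beats, 2, min), rep(46, 5), tolerance = 0.005)
  expect_equal(colMeans(beats), rep(63, 5), tolerance = 0.005)
})

test_that("Doppler envelope construction is linear in its targets", {
  a <- simulate_doppler_envelope(98, 46, 63, duration_s = 4)
  b <- simulate_doppler_envelope(196, 92, 126, duration_s = 4)
  expect_equal(b$value, 2 * a$value, tolerance = 1e-12)
})

test_that("infeasible Doppler triples are rejected with the violated ordering", {
  expect_error(simulate_doppler_envelope(50, 50, 50), "v_dia < v_mean")
  expect_error(simulate_doppler_envelope(50, 40, 55), "v_mean < v_sys")
  # diastolic-dominant mean outside the template family
  expect_error(simulate_doppler_envelope(100, 0, 60), "infeasible")
})

test_that("breath-hold schedule arithmetic matches the protocol", {
  sch <- breath_hold_schedule()
  expect_equal(attr(sch, "n_repeats"), 4)
  b1 <- sch[sch$repeat_idx == 1 & sch$segment == "breath", ]
  expect_equal(nrow(b1), 8)
  expect_equal(max(b1$end_s) - min(b1$start_s), 30) # 8 breaths at 16/min
  h1 <- sch[sch$repeat_idx == 1 & sch$segment == "hold", ]
  expect_equal(h1$end_s - h1$start_s, 20)
  expect_true(all(diff(sch$start_s[order(sch$start_s)]) >= 0))
})

test_that("breath-hold session round-trips its programmed reactivity", {
  sess <- simulate_breath_hold_session(39, 8, 60, 1.5)
  res <- analyze_breath_hold(sess$etco2, sess$mcav, sess$schedule)
  expect_equal(res$cvr_abs, 1.5, tolerance = 0.05)
  expect_equal(res$baseline_mcav, 60, tolerance = 0.01)
})

test_that("zero reactivity gives a flat velocity trace and zero CVR", {
  sess <- simulate_breath_hold_session(39, 8, 60, 0)
  expect_equal(diff(range(sess$mcav$value)), 0)
  res <- analyze_breath_hold(sess$etco2, sess$mcav, sess$schedule)
  expect_equal(res$cvr_abs, 0, tolerance = 1e-9)
})

test_that("cohort generator reproduces cell means exactly at zero SD", {
  cm <- cohort_grid(means = c(1, 2, 3, 4, 5, 6), sds = rep(0, 6))
  tab <- simulate_cohort(cm, n_per_group = 5, seed = 3)
  chk <- tab |>
    dplyr::left_join(cm, by = c("group", "time", "outcome")) |>
    dplyr::mutate(dev = abs(value - mean))
  expect_equal(max(chk$dev), 0)
})

test_that("cohort generator induces the requested within-subject correlation", {
  cm <- cohort_grid(means = rep(10, 6), sds = rep(2, 6))
  tab <- simulate_cohort(cm, n_per_group = 2000,
                         within_subject_correlation = 0.8, seed = 5)
  wide <- tidyr::pivot_wider(tab, names_from = "time", values_from = "value")
  r <- cor(wide$baseline, wide$`30`)
  expect_equal(r, 0.8, tolerance = 0.03)
})

test_that("every generator is bit-identical under a repeated seed", {
  e1 <- simulate_doppler_envelope(98, 46, 63, noise_sd = 2, seed = 9)
  e2 <- simulate_doppler_envelope(98, 46, 63, noise_sd = 2, seed = 9)
  expect_identical(e1$value, e2$value)
  s1 <- simulate_breath_hold_session(39, 8, 60, 1.5, noise_sd = 1, seed = 9)
  s2 <- simulate_breath_hold_session(39, 8, 60, 1.5, noise_sd = 1, seed = 9)
  expect_identical(s1$mcav$value, s2$mcav$value)
  t1 <- simulate_cohort(cohort_grid(rep(1, 6), rep(1, 6)), 5, seed = 9)
  t2 <- simulate_cohort(cohort_grid(rep(1, 6), rep(1, 6)), 5, seed = 9)
  expect_identical(t1$value, t2$value)
  g1 <- simulate_ecg(60, 5, noise_sd = 0.05, seed = 9)
  g2 <- simulate_ecg(60, 5, noise_sd = 0.05, seed = 9)
  expect_identical(g1$value, g2$value)
})

test_that("seeded generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(simulate_doppler_envelope(98, 46, 63, noise_sd = 1, seed = 42))
  after <- rnorm(1)
  expect_identical(before, after)
})
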