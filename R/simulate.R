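#' Simulate pressure and flow from a three-element Windkessel
#'
#' Generates one cardiac-cycle-periodic pressure/flow pair with known
#' characteristic impedance, for use as ground truth when validating
#' time-domain impedance estimation. Flow is a half-sinusoid ejection
#' integrating to `stroke_volume` per beat and zero in diastole; pressure is
#' `p_wk + zc * flow`, where the Windkessel pressure `p_wk` solves
#' `compliance * dp_wk/dt = flow - p_wk / r_peripheral`. The ODE is integrated
#' with the classical fixed-step fourth-order Runge-Kutta scheme at the signal
#' sampling rate; 20 warm-up beats are run and discarded so the emitted beats
#' are at periodic steady state.
#'
#' @param zc Characteristic impedance, mmHg s/mL (> 0).
#' @param r_peripheral Peripheral resistance, mmHg s/mL (> 0).
#' @param compliance Arterial compliance, mL/mmHg (> 0).
#' @param heart_rate Beats per minute (> 0).
#' @param stroke_volume Ejected volume per beat, mL (> 0).
#' @param ejection_fraction_of_cycle Fraction of the cycle spent in ejection,
#'   in (0, 1). Default 0.3, a resting left-ventricular ejection time of about
#'   0.3 s at 60 beats/min.
#' @param sampling_rate Sampling rate, Hz (>= 200).
#' @param n_beats Number of steady-state beats to emit.
#' @param noise_sd SD of additive Gaussian noise, in the output units.
#' @param seed Optional integer seed; the same seed gives bit-identical output.
#'
#' @return A list with elements `pressure` (mmHg) and `flow` (mL/s), both
#'   [sampled_signal()] objects carrying the generating parameters in the
#'   `ground_truth` attribute.
#' @export
#' @examples
#' wk <- simulate_windkessel(zc = 0.1, r_peripheral = 1, compliance = 1.5,
#'                           heart_rate = 60, stroke_volume = 70,
#'                           sampling_rate = 500, n_beats = 3)
#' range(wk$pressure$value)
simulate_windkessel <- function(zc, r_peripheral, compliance, heart_rate,
                                stroke_volume,
                                ejection_fraction_of_cycle = 0.3,
                                sampling_rate = 500, n_beats = 10,
                                noise_sd = 0, seed = NULL) {
  pars <- c(zc = zc, r_peripheral = r_peripheral, compliance = compliance,
            heart_rate = heart_rate, stroke_volume = stroke_volume,
            sampling_rate = sampling_rate)
  bad <- names(pars)[!is.finite(pars) | pars <= 0]
  if (length(bad)) {
    stop("invalid Windkessel parameter(s), must be positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (ejection_fraction_of_cycle <= 0 || ejection_fraction_of_cycle >= 1) {
    stop("`ejection_fraction_of_cycle` must lie in (0, 1)", call. = FALSE)
  }
  if (sampling_rate < 200) {
    stop("`sampling_rate` must be at least 200 Hz", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)

  period <- 60 / heart_rate
  t_ej <- ejection_fraction_of_cycle * period
  q_peak <- pi * stroke_volume / (2 * t_ej) # so the half-sine integrates to SV
  qfun <- function(t) {
    tm <- t %% period
    ifelse(tm < t_ej, q_peak * sin(pi * tm / t_ej), 0)
  }

  n_warm <- 20L
  h <- 1 / sampling_rate
  n_emit <- round(n_beats * period * sampling_rate)
  n_tot <- round(n_warm * period * sampling_rate) + n_emit
  t_grid <- (seq_len(n_tot) - 1) * h

  # RK4 on the linear ODE p' = -a p + b(t), a = 1/(RC), b = q/C. For a linear
  # scalar ODE the classical RK4 step reduces to a one-term linear recurrence
  # p[i+1] = A p[i] + w0 b[i] + wh b[i+1/2] + w1 b[i+1], evaluated exactly with
  # a recursive filter.
  a <- 1 / (r_peripheral * compliance)
  ah <- a * h
  A <- 1 - ah + ah^2 / 2 - ah^3 / 6 + ah^4 / 24
  w0 <- h / 6 * (1 - ah + ah^2 / 2 - ah^3 / 4)
  wh <- h / 6 * (4 - 2 * ah + ah^2 / 2)
  w1 <- h / 6
  b <- qfun(t_grid) / compliance
  bh <- qfun(t_grid + h / 2) / compliance
  p0 <- r_peripheral * stroke_volume / period # mean-pressure initial guess
  n <- n_tot
  rhs <- w0 * b[-n] + wh * bh[-n] + w1 * b[-1]
  p_wk <- c(p0, stats::filter(rhs, A, method = "recursive", init = p0))

  keep <- (n_tot - n_emit + 1):n_tot
  q <- qfun(t_grid[keep] - t_grid[keep][1]) # re-anchor phase at 0
  p <- p_wk[keep] + zc * q

  if (noise_sd > 0) {
    noise <- with_local_seed(seed, list(
      stats::rnorm(n_emit, sd = noise_sd),
      stats::rnorm(n_emit, sd = noise_sd)
    ))
    p <- p + noise[[1]]
    q <- q + noise[[2]]
  }

  gt <- list(zc = zc, r_peripheral = r_peripheral, compliance = compliance,
             heart_rate = heart_rate, stroke_volume = stroke_volume,
             ejection_fraction_of_cycle = ejection_fraction_of_cycle,
             period_s = period, noise_sd = noise_sd, seed = seed)
  pressure <- sampled_signal(p, sampling_rate, "mmHg", "windkessel pressure")
  flow <- sampled_signal(q, sampling_rate, "mL/s", "windkessel flow")
  attr(pressure, "ground_truth") <- gt
  attr(flow, "ground_truth") <- gt
  list(pressure = pressure, flow = flow)
}

#' Simulate a proximal/distal waveform pair with a known transit delay
#'
#' Shifts `template` by `distance_cm / true_pwv` seconds (sub-sample shift by
#' linear interpolation) to produce the distal signal, the oracle for
#' foot-to-foot pulse wave velocity estimation.
#'
#' @param template A [sampled_signal()] containing at least one full beat.
#' @param distance_cm Path distance between sites, cm (> 0).
#' @param true_pwv Ground-truth pulse wave velocity, cm/s (> 0).
#' @param noise_sd SD of additive Gaussian noise.
#' @param seed Optional integer seed.
#' @param period_s Cardiac period of the template; inferred from its
#'   `ground_truth` attribute when available. The embedded delay must not
#'   exceed one period, otherwise foot pairing would be ambiguous.
#'
#' @return List with `proximal`, `distal` ([sampled_signal()]s) and
#'   `true_delay_s`.
#' @export
simulate_delayed_pair <- function(template, distance_cm, true_pwv,
                                  noise_sd = 0, seed = NULL, period_s = NULL) {
  stopifnot(inherits(template, "sampled_signal"))
  if (distance_cm <= 0) stop("`distance_cm` must be > 0", call. = FALSE)
  if (true_pwv <= 0) stop("`true_pwv` must be > 0", call. = FALSE)
  delay <- distance_cm / true_pwv
  period_s <- period_s %||% attr(template, "ground_truth")$period_s %||%
    (nrow(template) / sig_rate(template))
  if (delay > period_s) {
    stop("embedded delay (", signif(delay, 3), " s) exceeds one cardiac cycle (",
         signif(period_s, 3), " s); foot pairing would be ambiguous",
         call. = FALSE)
  }
  t <- template$time_s
  v <- template$value
  shifted <- stats::approx(t, v, xout = t - delay, rule = 2)$y
  if (noise_sd > 0) {
    noise <- with_local_seed(seed, list(
      stats::rnorm(length(v), sd = noise_sd),
      stats::rnorm(length(v), sd = noise_sd)
    ))
    prox_v <- v + noise[[1]]
    dist_v <- shifted + noise[[2]]
  } else {
    prox_v <- v
    dist_v <- shifted
  }
  fs <- sig_rate(template)
  proximal <- sampled_signal(prox_v, fs, sig_units(template), "proximal")
  distal <- sampled_signal(dist_v, fs, sig_units(template), "distal")
  gt <- list(true_delay_s = delay, true_pwv = true_pwv,
             distance_cm = distance_cm, period_s = period_s)
  attr(proximal, "ground_truth") <- gt
  attr(distal, "ground_truth") <- gt
  list(proximal = proximal, distal = distal, true_delay_s = delay)
}

#' Simulate a Doppler velocity envelope with known beat metrics
#'
#' Emits a quasi-periodic velocity envelope whose every beat has maximum
#' `v_sys`, minimum `v_dia` and time-average `v_mean` (at zero noise, to
#' within discretization). Each beat is a raised-cosine upstroke of fixed
#' width (15% of the cycle), a raised-cosine decay whose width is set so the
#' beat mean hits `v_mean`, and a diastolic plateau at `v_dia`. Triples whose
#' mean cannot be reached by this family are rejected, not clipped.
#'
#' @param v_sys,v_dia,v_mean Target systolic/diastolic/mean velocity, cm/s;
#'   must satisfy `v_dia < v_mean < v_sys`.
#' @param heart_rate Beats per minute.
#' @param duration_s Length of the emitted signal, seconds.
#' @param sampling_rate Sampling rate, Hz.
#' @param noise_sd SD of additive Gaussian noise.
#' @param seed Optional integer seed.
#' @return A [sampled_signal()] in cm/s with the targets in `ground_truth`.
#' @export
#' @examples
#' env <- simulate_doppler_envelope(98, 46, 63, duration_s = 5)
#' c(max(env$value), min(env$value))
simulate_doppler_envelope <- function(v_sys, v_dia, v_mean, heart_rate = 60,
                                      duration_s = 10, sampling_rate = 200,
                                      noise_sd = 0, seed = NULL) {
  if (!(v_dia < v_mean)) {
    stop("infeasible velocity triple: requires v_dia < v_mean (got v_dia = ",
         v_dia, ", v_mean = ", v_mean, ")", call. = FALSE)
  }
  if (!(v_mean < v_sys)) {
    stop("infeasible velocity triple: requires v_mean < v_sys (got v_mean = ",
         v_mean, ", v_sys = ", v_sys, ")", call. = FALSE)
  }
  period <- 60 / heart_rate
  w_up <- 0.15 * period
  # each raised-cosine limb has mean 1/2 over its width, so the normalized
  # beat mean is (w_up + w_down) / (2 * period); solve for w_down
  m <- (v_mean - v_dia) / (v_sys - v_dia)
  w_down <- 2 * period * m - w_up
  if (w_down <= 0 || w_up + w_down >= period) {
    stop("infeasible velocity triple: normalized mean ",
         signif(m, 4), " outside the range reachable by the beat template ",
         "(systolic-dominant envelopes require ",
         signif(w_up / (2 * period), 3), " < (v_mean - v_dia)/(v_sys - v_dia) < 0.5)",
         call. = FALSE)
  }
  n <- round(duration_s * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  ph <- t %% period
  s <- numeric(n)
  up <- ph < w_up
  s[up] <- (1 - cos(pi * ph[up] / w_up)) / 2
  dn <- ph >= w_up & ph < (w_up + w_down)
  s[dn] <- (1 + cos(pi * (ph[dn] - w_up) / w_down)) / 2
  v <- v_dia + (v_sys - v_dia) * s
  if (noise_sd > 0) {
    v <- v + with_local_seed(seed, stats::rnorm(n, sd = noise_sd))
  }
  out <- sampled_signal(v, sampling_rate, "cm/s", "doppler envelope")
  attr(out, "ground_truth") <- list(v_sys = v_sys, v_dia = v_dia,
                                    v_mean = v_mean, heart_rate = heart_rate,
                                    period_s = period, noise_sd = noise_sd)
  out
}

#' Breath-hold protocol schedule
#'
#' Segment boundaries for the paced-breathing breath-hold protocol: per
#' repeat, `paced_breaths` breaths at `paced_rate` breaths/min, then a
#' `hold_s` breath-hold, then a recovery window. Defaults follow the adapted
#' protocol of eight paced breaths at 16 breaths/min, a 20 s hold, repeated
#' four times.
#'
#' @param n_repeats Number of repeats.
#' @param paced_breaths Paced breaths per repeat.
#' @param paced_rate Paced breathing rate, breaths/min.
#' @param hold_s Breath-hold duration, seconds.
#' @param recovery_s Recovery window after each hold, seconds.
#' @return A tibble with columns `repeat_idx`, `segment`
#'   (`"breath"`/`"hold"`/`"recovery"`), `breath_idx`, `start_s`, `end_s`,
#'   carrying the protocol parameters as attributes.
#' @export
breath_hold_schedule <- function(n_repeats = 4, paced_breaths = 8,
                                 paced_rate = 16, hold_s = 20,
                                 recovery_s = 20) {
  stopifnot(n_repeats >= 1, paced_breaths >= 2, paced_rate > 0, hold_s > 0,
            recovery_s > 0)
  breath_s <- 60 / paced_rate
  rep_len <- paced_breaths * breath_s + hold_s + recovery_s
  rows <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    t0 <- (r - 1) * rep_len
    breaths <- tibble::tibble(
      repeat_idx = r, segment = "breath", breath_idx = seq_len(paced_breaths),
      start_s = t0 + (seq_len(paced_breaths) - 1) * breath_s,
      end_s = t0 + seq_len(paced_breaths) * breath_s
    )
    hold0 <- t0 + paced_breaths * breath_s
    dplyr::bind_rows(
      breaths,
      tibble::tibble(repeat_idx = r, segment = "hold", breath_idx = NA_integer_,
                     start_s = hold0, end_s = hold0 + hold_s),
      tibble::tibble(repeat_idx = r, segment = "recovery",
                     breath_idx = NA_integer_,
                     start_s = hold0 + hold_s, end_s = t0 + rep_len)
    )
  })
  structure(rows,
            n_repeats = n_repeats, paced_breaths = paced_breaths,
            paced_rate = paced_rate, hold_s = hold_s, recovery_s = recovery_s,
            class = c("breath_hold_schedule", class(rows)))
}

#' Simulate a breath-hold cerebrovascular reactivity session
#'
#' Emits continuous end-tidal CO2 and MCA mean-velocity traces following the
#' paced-breathing breath-hold protocol, with a known end-tidal rise and a
#' known reactivity. The CO2 trace shows one end-tidal plateau per paced
#' breath at `etco2_baseline`, a low apnoeic segment during the hold, a
#' post-hold end-tidal peak at `etco2_baseline + delta_etco2_true`, and
#' recovery breaths decaying back to baseline. The velocity trace rises by
#' `cvr_true * delta_etco2_true` around the end of each hold, with a plateau
#' wide enough to survive 3 s smoothing.
#'
#' @param etco2_baseline Baseline end-tidal CO2, mmHg (> 0).
#' @param delta_etco2_true End-tidal rise produced by the hold, mmHg.
#' @param mcav_baseline Baseline MCA mean velocity, cm/s (> 0).
#' @param cvr_true Ground-truth reactivity, cm/s per mmHg (>= 0).
#' @param sampling_rate Sampling rate of both traces, Hz.
#' @param noise_sd SD of additive Gaussian noise (both traces).
#' @param seed Optional integer seed.
#' @param schedule A [breath_hold_schedule()]; defaults to the standard
#'   4-repeat protocol.
#' @return List with `etco2`, `mcav` ([sampled_signal()]s) and `schedule`.
#' @export
simulate_breath_hold_session <- function(etco2_baseline, delta_etco2_true,
                                         mcav_baseline, cvr_true,
                                         sampling_rate = 50, noise_sd = 0,
                                         seed = NULL,
                                         schedule = breath_hold_schedule()) {
  if (etco2_baseline <= 0 || mcav_baseline <= 0) {
    stop("baselines must be positive", call. = FALSE)
  }
  if (cvr_true < 0) stop("`cvr_true` must be >= 0", call. = FALSE)
  total_s <- max(schedule$end_s)
  n <- round(total_s * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  co2_low <- 3 # inspired / apnoeic capnograph level, mmHg

  etco2 <- rep(co2_low, n)
  # raised-cosine half-transition from `lo` to `hi` over [t0, t0 + w]
  ramp <- function(x, t0, w) (1 - cos(pi * pmin(pmax((x - t0) / w, 0), 1))) / 2

  breaths <- schedule[schedule$segment == "breath", ]
  for (i in seq_len(nrow(breaths))) {
    b0 <- breaths$start_s[i]; b1 <- breaths$end_s[i]
    dur <- b1 - b0
    in_b <- t >= b0 & t < b1
    # inspiration (low), expiration upstroke, end-tidal plateau
    tb <- t[in_b] - b0
    prof <- co2_low +
      (etco2_baseline - co2_low) * ramp(tb, 0.45 * dur, 0.25 * dur)
    prof[tb >= 0.95 * dur] <- co2_low # start of next inspiration
    etco2[in_b] <- prof
  }
  holds <- schedule[schedule$segment == "hold", ]
  recs <- schedule[schedule$segment == "recovery", ]
  for (i in seq_len(nrow(holds))) {
    h1 <- holds$end_s[i]
    r1 <- recs$end_s[i]
    peak <- etco2_baseline + delta_etco2_true
    # post-hold exhalation: fast rise to the peak plateau, then recovery
    # breaths whose end-tidal values decay back to baseline
    in_peak <- t >= h1 & t < h1 + 3
    etco2[in_peak] <- co2_low + (peak - co2_low) * ramp(t[in_peak] - h1, 0, 0.8)
    rec_breath <- 60 / attr(schedule, "paced_rate")
    k <- 1
    b0 <- h1 + 3
    while (b0 + rec_breath <= r1) {
      lvl <- etco2_baseline + delta_etco2_true * exp(-k / 1.5)
      in_b <- t >= b0 & t < b0 + rec_breath
      tb <- t[in_b] - b0
      prof <- co2_low + (lvl - co2_low) * ramp(tb, 0.45 * rec_breath, 0.25 * rec_breath)
      prof[tb >= 0.95 * rec_breath] <- co2_low
      etco2[in_b] <- prof
      b0 <- b0 + rec_breath
      k <- k + 1
    }
  }

  mcav <- rep(mcav_baseline, n)
  amp <- cvr_true * delta_etco2_true
  if (amp > 0) {
    for (i in seq_len(nrow(holds))) {
      h1 <- holds$end_s[i]
      # rise over 6 s ending at the hold end, 6 s plateau, 8 s decay
      mcav <- mcav + amp * (ramp(t, h1 - 6, 6) - ramp(t, h1 + 6, 8))
    }
  }

  if (noise_sd > 0) {
    noise <- with_local_seed(seed, list(stats::rnorm(n, sd = noise_sd),
                                        stats::rnorm(n, sd = noise_sd)))
    etco2 <- etco2 + noise[[1]]
    mcav <- mcav + noise[[2]]
  }
  gt <- list(etco2_baseline = etco2_baseline,
             delta_etco2_true = delta_etco2_true,
             mcav_baseline = mcav_baseline, cvr_true = cvr_true,
             noise_sd = noise_sd)
  etco2 <- sampled_signal(etco2, sampling_rate, "mmHg", "ETCO2")
  mcav <- sampled_signal(mcav, sampling_rate, "cm/s", "MCAv")
  attr(etco2, "ground_truth") <- gt
  attr(mcav, "ground_truth") <- gt
  list(etco2 = etco2, mcav = mcav, schedule = schedule)
}

#' Simulate a two-group by three-time cohort with within-subject correlation
#'
#' Draws a long-format study table from a compound-symmetry model: each
#' subject (per outcome) carries a shared standard-normal deviate weighted by
#' `sqrt(rho) * sd`, plus an independent residual weighted by
#' `sqrt(1 - rho) * sd`, so every cell matches its requested mean and SD in
#' expectation and any two time points within a subject correlate at `rho`.
#'
#' @param cell_means Tibble with columns `group`, `time`, `outcome`, `mean`,
#'   `sd`; `time` must be exactly `baseline`, `30`, `60` for each
#'   group-outcome combination.
#' @param n_per_group Subjects per group; either a single number or a named
#'   vector (names = groups).
#' @param within_subject_correlation Correlation `rho` in [0, 1).
#' @param seed Optional integer seed.
#' @return A long tibble (`subject`, `group`, `time`, `outcome`, `value`)
#'   with `time` an ordered factor `baseline < 30 < 60`.
#' @export
#' @examples
#' cm <- tidyr::crossing(group = c("YA", "MA"), time = c("baseline", "30", "60")) |>
#'   dplyr::mutate(outcome = "pi", mean = 1.8, sd = 0.4)
#' simulate_cohort(cm, n_per_group = 5, within_subject_correlation = 0.5, seed = 1)
simulate_cohort <- function(cell_means, n_per_group,
                            within_subject_correlation = 0.5, seed = NULL) {
  req <- c("group", "time", "outcome", "mean", "sd")
  if (!all(req %in% names(cell_means))) {
    stop("`cell_means` needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(cell_means$sd < 0)) stop("SDs must be >= 0", call. = FALSE)
  rho <- within_subject_correlation
  if (rho < 0 || rho >= 1) {
    stop("`within_subject_correlation` must lie in [0, 1)", call. = FALSE)
  }
  times <- c("baseline", "30", "60")
  chk <- dplyr::count(cell_means, .data$group, .data$outcome)
  if (!setequal(unique(cell_means$time), times) || any(chk$n != 3)) {
    stop("each group x outcome must have exactly the times baseline, 30, 60",
         call. = FALSE)
  }
  groups <- unique(cell_means$group)
  if (length(n_per_group) == 1 && is.null(names(n_per_group))) {
    n_per_group <- stats::setNames(rep(n_per_group, length(groups)), groups)
  }
  subjects <- purrr::map_dfr(groups, function(g) {
    tibble::tibble(group = g,
                   subject = sprintf("%s%02d", g, seq_len(n_per_group[[g]])))
  })
  grid <- tidyr::crossing(subjects, time = times,
                          outcome = unique(cell_means$outcome)) |>
    dplyr::left_join(cell_means, by = c("group", "time", "outcome"))

  draws <- with_local_seed(seed, {
    subj_dev <- tidyr::crossing(subject = subjects$subject,
                                outcome = unique(cell_means$outcome))
    subj_dev$z <- stats::rnorm(nrow(subj_dev))
    e <- stats::rnorm(nrow(grid))
    list(subj_dev = subj_dev, e = e)
  })
  grid |>
    dplyr::left_join(draws$subj_dev, by = c("subject", "outcome")) |>
    dplyr::mutate(
      value = .data$mean + .data$sd * (sqrt(rho) * .data$z +
                                         sqrt(1 - rho) * draws$e),
      time = factor(.data$time, levels = times, ordered = TRUE)
    ) |>
    dplyr::select("subject", "group", "time", "outcome", "value") |>
    dplyr::arrange(.data$outcome, .data$group, .data$subject, .data$time)
}

#' Simulate a surface ECG with known R-wave times
#'
#' A simple P-QRS-T morphology built from Gaussian bumps, for exercising
#' R-wave gating. R waves fall at `0.2 + k * 60/heart_rate` seconds.
#'
#' @param heart_rate Beats per minute.
#' @param duration_s Signal length, seconds.
#' @param sampling_rate Sampling rate, Hz.
#' @param noise_sd SD of additive Gaussian noise.
#' @param seed Optional integer seed.
#' @param first_r_s Time of the first R wave, seconds. When gating pressure
#'   waveforms whose feet fall at multiples of the period, set this so each R
#'   wave leads its beat's foot by a realistic pre-ejection interval.
#' @return A [sampled_signal()] (arbitrary units) with R-wave times in
#'   `ground_truth`.
#' @export
simulate_ecg <- function(heart_rate = 60, duration_s = 30,
                         sampling_rate = 500, noise_sd = 0, seed = NULL,
                         first_r_s = 0.2) {
  period <- 60 / heart_rate
  n <- round(duration_s * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  r_times <- seq(first_r_s, duration_s - 0.1, by = period)
  v <- numeric(n)
  bump <- function(center, amp, width) {
    i <- which(abs(t - center) < 4 * width)
    v[i] <<- v[i] + amp * exp(-((t[i] - center)^2) / (2 * width^2))
  }
  for (r in r_times) {
    bump(r - 0.16, 0.15, 0.025) # P
    bump(r - 0.025, -0.12, 0.01) # Q
    bump(r, 1.0, 0.01) # R
    bump(r + 0.025, -0.2, 0.01) # S
    bump(r + 0.25, 0.3, 0.05) # T
  }
  if (noise_sd > 0) v <- v + with_local_seed(seed, stats::rnorm(n, sd = noise_sd))
  out <- sampled_signal(v, sampling_rate, "mV", "ECG")
  attr(out, "ground_truth") <- list(r_times = r_times, heart_rate = heart_rate,
                                    period_s = period)
  out
}

# evaluate `code` under a temporary RNG state seeded with `seed` (NULL = use
# the current stream), restoring the caller's stream afterwards
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
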