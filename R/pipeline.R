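#' Analysis configuration for a visit
#'
#' Collects every tunable analysis choice in one auditable place.
#'
#' @param map_method MAP derivation: waveform `"integral"` (default) or
#'   `"form_factor"`.
#' @param tonometry_epoch_s Ensemble-averaging epoch for pressure waveforms,
#'   seconds.
#' @param artifact_sd Beat amplitude-outlier threshold (SDs from the epoch
#'   median).
#' @param cfpwv_min_beats Minimum usable beats for the transit-time median.
#' @param post_window_s Post-hold search window for the CVR stage, seconds.
#' @return A named list of class `visit_config`.
#' @export
visit_config <- function(map_method = "integral", tonometry_epoch_s = 20,
                         artifact_sd = 3, cfpwv_min_beats = 5,
                         post_window_s = 15) {
  structure(list(map_method = map_method,
                 tonometry_epoch_s = tonometry_epoch_s,
                 artifact_sd = artifact_sd, cfpwv_min_beats = cfpwv_min_beats,
                 post_window_s = post_window_s),
            class = "visit_config")
}

# group x time true values emulating a two-group meal-challenge study;
# offsets: per-subject deviations applied on top (see simulate_study)
visit_params <- function(group = c("YA", "MA"),
                         time = c("baseline", "30", "60"),
                         offsets = NULL) {
  group <- match.arg(group)
  time <- match.arg(time)
  ti <- match(time, c("baseline", "30", "60"))
  pick <- function(ya, ma) if (group == "YA") ya[ti] else ma[ti]
  p <- list(
    map = pick(c(83, 82, 81), c(93, 89, 89)),
    heart_rate = pick(c(56, 63, 65), c(59, 63, 65)),
    pwv_true = pick(c(527, 516, 515), c(753, 729, 742)),
    beta_true = pick(c(4.10, 3.89, 3.82), c(7.81, 7.12, 6.73)),
    diameter_mm = pick(c(5.3, 5.4, 5.5), c(5.7, 5.6, 5.7)),
    mca_v_sys = pick(c(98, 106, 102), c(89, 94, 91)),
    mca_v_dia = pick(c(46, 45, 44), c(40, 41, 39)),
    mca_v_mean = pick(c(63, 65, 63), c(56, 58, 57)),
    car_v_sys = pick(c(104, 113, 113), c(84, 90, 86)),
    car_v_dia = pick(c(27, 24, 25), c(27, 25, 24)),
    car_v_mean = pick(c(42, 41, 41), c(43, 42, 40)),
    zc_wk = pick(c(0.10, 0.096, 0.093), c(0.14, 0.134, 0.130)),
    compliance = if (group == "YA") 1.5 else 1.0,
    r_peripheral = 1.0,
    stroke_volume = 70,
    etco2_baseline = pick(c(39, 39, 39), c(40, 40, 39)),
    delta_etco2 = 8,
    cvr_true = pick(c(1.5, 1.7, 1.6), c(1.2, 1.1, 1.1)),
    glucose = pick(c(73.8, 100.9, 81.1), c(86.5, 109.9, 100.9)),
    insulin = pick(c(302.6, 1997.6, 1169.6), c(483.5, 1991.3, 1183.0)),
    path_distance_cm = 60
  )
  if (!is.null(offsets)) {
    for (k in names(offsets)) p[[k]] <- p[[k]] + offsets[[k]]
  }
  # keep envelope targets inside the systolic-dominant feasible band
  clamp_mean <- function(vm, vd, vs) {
    min(max(vm, vd + 0.1 * (vs - vd)), vd + 0.48 * (vs - vd))
  }
  p$mca_v_mean <- clamp_mean(p$mca_v_mean, p$mca_v_dia, p$mca_v_sys)
  p$car_v_mean <- clamp_mean(p$car_v_mean, p$car_v_dia, p$car_v_sys)
  p
}

#' Simulate every recording of one experimental visit
#'
#' Builds the complete input set a visit-level analysis consumes, all with
#' known ground truth: a 20 s brachial and carotid tonometry trace with ECG,
#' a carotid/femoral pair with an embedded transit delay, carotid and MCA
#' Doppler envelopes, carotid pressure/flow for impedance and wave
#' separation, a breath-hold session, cuff pressures, diameters and assay
#' values.
#'
#' @param subject_id Subject identifier.
#' @param group `"YA"` or `"MA"`.
#' @param time `"baseline"`, `"30"` or `"60"`.
#' @param seed Integer seed; every embedded noise draw derives from it.
#' @param params True parameter values, see `visit_params`; defaults are the
#'   group-by-time study conditions.
#' @param noise Relative noise level for the waveforms (SD as a fraction of
#'   signal amplitude).
#' @return A named list (`visit` record) consumed by [run_visit()].
#' @export
simulate_visit <- function(subject_id, group, time, seed = 1,
                           params = visit_params(group, time), noise = 0.005) {
  p <- params
  sub_seed <- function(k) (seed * 97 + k) %% .Machine$integer.max
  period <- 60 / p$heart_rate
  cuff <- tibble::tibble(systolic = p$map + 27, diastolic = p$map - 13)
  p_ratio <- (p$map + 22) / (p$map - 13) # approximate carotid sys/dia ratio
  strain <- log(p_ratio) / p$beta_true
  d_sys <- p$diameter_mm * (1 + strain)

  wk <- function(n_beats, seed_k, fs = 500) {
    simulate_windkessel(
      zc = p$zc_wk, r_peripheral = p$r_peripheral, compliance = p$compliance,
      heart_rate = p$heart_rate, stroke_volume = p$stroke_volume,
      sampling_rate = fs, n_beats = n_beats, noise_sd = noise * 40,
      seed = sub_seed(seed_k)
    )
  }
  tono <- wk(ceiling(22 / period), 1) # >= 20 s pressure trace
  brachial_raw <- tono$pressure
  carotid_raw <- sig_replace(tono$pressure,
                             sig_values(tono$pressure) / 50) # uncalibrated a.u.
  ecg <- simulate_ecg(p$heart_rate, duration_s = nrow(brachial_raw) / 500,
                      sampling_rate = 500, noise_sd = noise,
                      seed = sub_seed(2))

  template <- wk(8, 3)$pressure
  pair <- simulate_delayed_pair(template, p$path_distance_cm, p$pwv_true,
                                noise_sd = noise * 40, seed = sub_seed(4))
  # R waves lead each pressure foot (at multiples of the period) by 150 ms
  ecg_pwv <- simulate_ecg(p$heart_rate, duration_s = nrow(template) / 500,
                          sampling_rate = 500, noise_sd = noise,
                          seed = sub_seed(5), first_r_s = period - 0.15)

  beat <- wk(1, 6)
  area_cm2 <- pi * (p$diameter_mm / 20)^2
  flow_velocity <- sampled_signal(sig_values(beat$flow) / area_cm2, 500,
                                  "cm/s", "carotid doppler velocity")
  carotid_velocity <- simulate_doppler_envelope(
    p$car_v_sys, p$car_v_dia, p$car_v_mean, heart_rate = p$heart_rate,
    duration_s = 26, sampling_rate = 200, noise_sd = noise * p$car_v_sys,
    seed = sub_seed(7)
  )
  mca_velocity <- simulate_doppler_envelope(
    p$mca_v_sys, p$mca_v_dia, p$mca_v_mean, heart_rate = p$heart_rate,
    duration_s = 122, sampling_rate = 200, noise_sd = noise * p$mca_v_sys,
    seed = sub_seed(8)
  )
  session <- simulate_breath_hold_session(
    p$etco2_baseline, p$delta_etco2, p$mca_v_mean, p$cvr_true,
    sampling_rate = 50, noise_sd = noise * 10, seed = sub_seed(9)
  )

  list(
    subject_id = subject_id, group = group, time = time,
    cuff = cuff,
    brachial_raw = brachial_raw, carotid_raw = carotid_raw, ecg = ecg,
    pwv_carotid = pair$proximal, pwv_femoral = pair$distal, ecg_pwv = ecg_pwv,
    pressure_beat = beat$pressure, flow_velocity = flow_velocity,
    carotid_velocity = carotid_velocity, mca_velocity = mca_velocity,
    etco2 = session$etco2, mcav = session$mcav, schedule = session$schedule,
    d_sys_mm = d_sys, d_dia_mm = p$diameter_mm,
    path_distance_cm = p$path_distance_cm,
    glucose = p$glucose, insulin = p$insulin,
    ground_truth = p
  )
}

#' Run the full analysis battery on one visit
#'
#' Executes, in order: cuff validation, brachial calibration and MAP, carotid
#' calibration, cfPWV from the carotid/femoral pair, beta stiffness,
#' volumetric flow, characteristic impedance, wave separation, carotid and
#' MCA Doppler metrics, and breath-hold reactivity. Each stage is isolated:
#' a failing stage leaves its metrics `NA` and appends an error code to the
#' `errors` field — never a silent partial value.
#'
#' @param visit A visit record, e.g. from [simulate_visit()].
#' @param config A [visit_config()].
#' @return A one-row tibble of all visit-level outcomes, with an `errors`
#'   column (empty string when every stage succeeded).
#' @export
run_visit <- function(visit, config = visit_config()) {
  errors <- character(0)
  stage <- function(code, expr) {
    tryCatch(
      suppressMessages(suppressWarnings(expr)),
      error = function(e) {
        errors <<- c(errors, paste0(code, ": ", conditionMessage(e)))
        NULL
      }
    )
  }
  na_if_null <- function(x, field = NULL) {
    if (is.null(x)) return(NA_real_)
    if (is.null(field)) as.numeric(x) else as.numeric(x[[field]])
  }

  cuff <- stage("cuff", cuff_reading(visit$cuff))
  bp <- stage("calibration", {
    beats <- detect_beats(visit$brachial_raw, anchor = "foot")
    raw_beat <- ensemble_average(visit$brachial_raw, beats,
                                 epoch_s = config$tonometry_epoch_s,
                                 artifact_sd = config$artifact_sd)
    brachial <- calibrate_brachial(raw_beat, cuff)
    map <- derive_map(brachial, method = config$map_method)
    cbeats <- detect_beats(visit$carotid_raw, anchor = "foot")
    craw <- ensemble_average(visit$carotid_raw, cbeats,
                             epoch_s = config$tonometry_epoch_s,
                             artifact_sd = config$artifact_sd)
    carotid <- calibrate_carotid(craw, min(sig_values(brachial)), map)
    list(brachial = brachial, map = map, carotid = carotid,
         heart_rate = 60 / stats::median(diff(beats$onset_time_s)))
  })
  pwv <- stage("cfpwv", {
    beats <- detect_beats(visit$ecg_pwv, anchor = "r_wave")
    cfpwv(visit$pwv_carotid, visit$pwv_femoral, beats,
          visit$path_distance_cm, min_beats = config$cfpwv_min_beats)
  })
  cs <- if (!is.null(bp)) pressure_summary(bp$carotid) else NULL
  beta <- stage("beta", {
    if (is.null(cs)) stop("carotid pressures unavailable")
    beta_stiffness(cs$systolic, cs$diastolic, visit$d_sys_mm, visit$d_dia_mm)
  })
  wavemech <- stage("wave_mechanics", {
    flow <- volumetric_flow(visit$flow_velocity, visit$d_dia_mm)
    zc <- characteristic_impedance(visit$pressure_beat, flow)
    ws <- wave_separation(visit$pressure_beat, flow, zc)
    list(zc = zc, ws = ws)
  })
  car <- stage("carotid_doppler", {
    doppler_metrics(visit$carotid_velocity, epoch_plan("carotid"),
                    map_mmhg = if (is.null(bp)) NULL else bp$map)
  })
  mca <- stage("mca_doppler", {
    doppler_metrics(visit$mca_velocity, epoch_plan("mca"),
                    map_mmhg = if (is.null(bp)) NULL else bp$map)
  })
  cvr <- stage("cvr", {
    analyze_breath_hold(visit$etco2, visit$mcav, visit$schedule,
                        post_window_s = config$post_window_s)
  })

  ws <- if (is.null(wavemech)) NULL else glance(wavemech$ws)
  car_s <- if (is.null(car)) NULL else car$summary
  mca_s <- if (is.null(mca)) NULL else mca$summary
  tibble::tibble(
    subject = visit$subject_id, group = visit$group, time = visit$time,
    map = na_if_null(bp, "map"),
    heart_rate = na_if_null(bp, "heart_rate"),
    carotid_systolic = na_if_null(cs, "systolic"),
    carotid_diastolic = na_if_null(cs, "diastolic"),
    carotid_pulse_pressure = na_if_null(cs, "pulse_pressure"),
    cfpwv = na_if_null(pwv, "cfpwv"),
    beta = na_if_null(beta),
    zc = na_if_null(wavemech, "zc"),
    pf = na_if_null(ws, "pf_amplitude"),
    pb = na_if_null(ws, "pb_amplitude"),
    rix = na_if_null(ws, "reflection_index"),
    carotid_diameter = as.numeric(visit$d_dia_mm),
    carotid_v_mean = na_if_null(car_s, "v_mean"),
    carotid_v_sys = na_if_null(car_s, "v_sys"),
    carotid_v_dia = na_if_null(car_s, "v_dia"),
    carotid_pi = na_if_null(car_s, "pi"),
    mca_v_mean = na_if_null(mca_s, "v_mean"),
    mca_v_sys = na_if_null(mca_s, "v_sys"),
    mca_v_dia = na_if_null(mca_s, "v_dia"),
    mca_pi = na_if_null(mca_s, "pi"),
    mca_ri = na_if_null(mca_s, "ri"),
    conductance = na_if_null(mca_s, "conductance"),
    cvr_abs = na_if_null(cvr, "cvr_abs"),
    cvr_rel = na_if_null(cvr, "cvr_rel"),
    glucose = as.numeric(visit$glucose %||% NA_real_),
    insulin = as.numeric(visit$insulin %||% NA_real_),
    errors = paste(errors, collapse = "; ")
  )
}

#' Assemble visit rows into a long study table
#'
#' @param rows Tibble of visit rows from [run_visit()] (or any wide table
#'   keyed by `subject`, `group`, `time`).
#' @param outcomes Metric columns to keep; defaults to every numeric column.
#' @return Long tibble (`subject`, `group`, `time`, `outcome`, `value`);
#'   duplicate (subject, time, outcome) keys are an integrity error.
#' @export
build_study_table <- function(rows, outcomes = NULL) {
  if (!nrow(rows)) stop("no visit rows supplied", call. = FALSE)
  id_cols <- c("subject", "group", "time")
  stopifnot(all(id_cols %in% names(rows)))
  if (is.null(outcomes)) {
    outcomes <- setdiff(names(rows)[vapply(rows, is.numeric, TRUE)], id_cols)
  }
  long <- rows |>
    dplyr::select(dplyr::all_of(c(id_cols, outcomes))) |>
    tidyr::pivot_longer(dplyr::all_of(outcomes), names_to = "outcome",
                        values_to = "value")
  dup <- long |>
    dplyr::count(.data$subject, .data$time, .data$outcome) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("integrity error: duplicate (subject, time, outcome) rows, e.g. ",
         dup$subject[1], "/", dup$time[1], "/", dup$outcome[1], call. = FALSE)
  }
  long
}

#' Simulate and analyse a full two-group, three-time study
#'
#' Draws per-subject deviations around the group-by-time study conditions,
#' simulates every visit recording, runs the complete analysis battery on
#' each, and returns both the wide visit rows and the long study table ready
#' for [rm_anova()].
#'
#' @param n_ya,n_ma Subjects per group.
#' @param seed Integer seed controlling every random draw.
#' @param noise Relative waveform noise level passed to [simulate_visit()].
#' @return List: `visits` (wide tibble, one row per subject-time) and
#'   `study_table` (long tibble).
#' @export
simulate_study <- function(n_ya = 21, n_ma = 20, seed = 1, noise = 0.005) {
  subjects <- tibble::tibble(
    subject = c(sprintf("YA%02d", seq_len(n_ya)), sprintf("MA%02d", seq_len(n_ma))),
    group = c(rep("YA", n_ya), rep("MA", n_ma))
  )
  offs <- with_local_seed(seed, {
    lapply(seq_len(nrow(subjects)), function(i) {
      list(map = stats::rnorm(1, 0, 8),
           pwv_true = stats::rnorm(1, 0, 80),
           beta_true = stats::rnorm(1, 0, 0.7),
           mca_v_sys = stats::rnorm(1, 0, 10),
           mca_v_dia = stats::rnorm(1, 0, 5),
           mca_v_mean = stats::rnorm(1, 0, 7),
           car_v_sys = stats::rnorm(1, 0, 8),
           car_v_dia = stats::rnorm(1, 0, 2),
           car_v_mean = stats::rnorm(1, 0, 4),
           zc_wk = stats::rnorm(1, 0, 0.015),
           cvr_true = stats::rnorm(1, 0, 0.25),
           glucose = stats::rnorm(1, 0, 12),
           insulin = stats::rnorm(1, 0, 300))
    })
  })
  visits <- purrr::map_dfr(seq_len(nrow(subjects)), function(i) {
    purrr::map_dfr(c("baseline", "30", "60"), function(tm) {
      pars <- visit_params(subjects$group[i], tm, offsets = offs[[i]])
      v <- simulate_visit(subjects$subject[i], subjects$group[i], tm,
                          seed = (seed + 131 * i +
                                    7 * match(tm, c("baseline", "30", "60"))) %%
                            .Machine$integer.max,
                          params = pars, noise = noise)
      run_visit(v)
    })
  })
  list(visits = visits,
       study_table = build_study_table(dplyr::select(visits, -"errors")))
}
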