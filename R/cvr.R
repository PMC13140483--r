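#' Per-breath end-tidal CO2 values
#'
#' Extracts one end-tidal value per scheduled paced breath as the plateau
#' maximum within each breath window. A breath whose window shows no
#' expiratory plateau (its maximum does not rise meaningfully above the
#' signal floor) counts as missing; any missing scheduled breath raises a
#' protocol-mismatch error.
#'
#' @param etco2 A [sampled_signal()] CO2 trace in mmHg spanning the schedule.
#' @param schedule A [breath_hold_schedule()].
#' @param t0_s Time of the schedule origin within the recording, seconds
#'   (allows leading padding).
#' @return Tibble: `repeat_idx`, `breath_idx`, `end_tidal` (mmHg).
#' @export
extract_end_tidal <- function(etco2, schedule, t0_s = 0) {
  stopifnot(inherits(etco2, "sampled_signal"))
  fs <- sig_rate(etco2)
  v <- sig_values(etco2)
  dur <- length(v) / fs
  if (t0_s + max(schedule$end_s) > dur + 1e-9) {
    stop("window error: recording (", signif(dur, 4),
         " s) does not span the schedule", call. = FALSE)
  }
  rng <- max(v) - min(v)
  floor_v <- min(v)
  breaths <- schedule[schedule$segment == "breath", ]
  out <- purrr::map_dfr(seq_len(nrow(breaths)), function(i) {
    i0 <- floor((t0_s + breaths$start_s[i]) * fs) + 1
    i1 <- min(length(v), floor((t0_s + breaths$end_s[i]) * fs))
    m <- max(v[i0:i1])
    detected <- rng == 0 || (m - floor_v) > 0.5 * rng
    tibble::tibble(repeat_idx = breaths$repeat_idx[i],
                   breath_idx = breaths$breath_idx[i],
                   end_tidal = ifelse(detected, m, NA_real_))
  })
  n_miss <- sum(is.na(out$end_tidal))
  if (n_miss > 0) {
    stop("protocol mismatch: ", nrow(out) - n_miss,
         " end-tidal plateaus detected for ", nrow(out),
         " scheduled paced breaths", call. = FALSE)
  }
  out
}

#' End-tidal CO2 rise produced by a breath-hold
#'
#' The post-hold peak minus the average of the last two paced end-tidal
#' values before the hold.
#'
#' @param end_tidals Numeric vector of paced per-breath end-tidal values for
#'   one repeat, in breath order (at least 2).
#' @param post_hold_peak Peak end-tidal CO2 following the hold, mmHg.
#' @return Delta ETCO2 in mmHg.
#' @export
#' @examples
#' delta_etco2(c(38, 39, 38, 40), 46) # 46 - mean(38, 40) = 7
delta_etco2 <- function(end_tidals, post_hold_peak) {
  if (length(end_tidals) < 2) {
    stop("insufficient data: need at least 2 paced end-tidal values", call. = FALSE)
  }
  post_hold_peak - mean(utils::tail(end_tidals, 2))
}

# centered moving average over `width_s` seconds
moving_average <- function(v, fs, width_s) {
  k <- max(1L, round(width_s * fs))
  out <- stats::filter(v, rep(1 / k, k), sides = 2)
  as.numeric(out)
}

#' MCA velocity response to one breath-hold repeat
#'
#' Mirrors the end-tidal construction: the baseline is the mean velocity over
#' the last two paced-breath windows of the repeat, and the response is the
#' peak of the 3 s moving-averaged velocity within the hold plus a 15 s
#' post-hold window, minus the baseline.
#'
#' @param mcav A [sampled_signal()] MCA mean-velocity trace, cm/s.
#' @param schedule A [breath_hold_schedule()].
#' @param repeat_idx Which repeat to analyse.
#' @param t0_s Schedule origin within the recording, seconds.
#' @param smooth_s Moving-average width, seconds.
#' @param post_window_s Post-hold search window, seconds.
#' @return A one-row tibble: `repeat_idx`, `baseline`, `delta` (cm/s).
#' @export
delta_mcav <- function(mcav, schedule, repeat_idx, t0_s = 0, smooth_s = 3,
                       post_window_s = 15) {
  stopifnot(inherits(mcav, "sampled_signal"))
  fs <- sig_rate(mcav)
  v <- sig_values(mcav)
  rows <- schedule[schedule$repeat_idx == repeat_idx, ]
  if (!nrow(rows)) stop("no such repeat in schedule", call. = FALSE)
  hold <- rows[rows$segment == "hold", ]
  end_t <- t0_s + hold$end_s + post_window_s
  if (end_t > length(v) / fs + 1e-9) {
    stop("window error: recording does not cover the hold + ", post_window_s,
         " s window of repeat ", repeat_idx, call. = FALSE)
  }
  last2 <- utils::tail(rows[rows$segment == "breath", ], 2)
  bi <- floor((t0_s + min(last2$start_s)) * fs) + 1
  bj <- min(length(v), floor((t0_s + max(last2$end_s)) * fs))
  baseline <- mean(v[bi:bj])
  sm <- moving_average(v, fs, smooth_s)
  ri <- floor((t0_s + hold$start_s) * fs) + 1
  rj <- min(length(v), floor(end_t * fs))
  seg <- sm[ri:rj]
  delta <- max(seg, na.rm = TRUE) - baseline
  tibble::tibble(repeat_idx = repeat_idx, baseline = baseline, delta = delta)
}

#' Cerebrovascular reactivity from per-repeat deltas
#'
#' Averages per-repeat ratios (not a ratio of means): the absolute
#' reactivity is `mean(delta_mcav / delta_etco2)` in cm/s/mmHg and the
#' relative reactivity is `mean((100 * delta_mcav / baseline) / delta_etco2)`
#' in %/mmHg. Repeats with a non-positive end-tidal rise (failed holds) are
#' excluded and reported.
#'
#' @param per_repeat Tibble with columns `repeat_idx`, `delta_etco2`,
#'   `delta_mcav`, `baseline_mcav`.
#' @return A list of class `cvr_result`: `per_repeat` (with a `valid`
#'   column), `cvr_abs`, `cvr_rel`, `baseline_mcav`, `n_valid`.
#' @export
cvr_indices <- function(per_repeat) {
  req <- c("repeat_idx", "delta_etco2", "delta_mcav", "baseline_mcav")
  stopifnot(all(req %in% names(per_repeat)))
  per_repeat <- dplyr::mutate(per_repeat, valid = .data$delta_etco2 > 0)
  if (any(!per_repeat$valid)) {
    message("excluding ", sum(!per_repeat$valid),
            " repeat(s) with non-positive delta ETCO2: ",
            paste(per_repeat$repeat_idx[!per_repeat$valid], collapse = ", "))
  }
  ok <- per_repeat[per_repeat$valid, ]
  if (!nrow(ok)) {
    stop("no valid repeats: every breath-hold had a non-positive end-tidal rise",
         call. = FALSE)
  }
  structure(
    list(
      per_repeat = per_repeat,
      cvr_abs = mean(ok$delta_mcav / ok$delta_etco2),
      cvr_rel = mean((100 * ok$delta_mcav / ok$baseline_mcav) / ok$delta_etco2),
      baseline_mcav = mean(ok$baseline_mcav),
      n_valid = nrow(ok)
    ),
    class = "cvr_result"
  )
}

#' Full breath-hold reactivity analysis
#'
#' Runs the complete pipeline on raw traces: end-tidal extraction per paced
#' breath, per-repeat end-tidal rise (post-hold peak minus the mean of the
#' last two paced breaths), per-repeat velocity response, and the averaged
#' absolute/relative reactivity indices.
#'
#' @inheritParams extract_end_tidal
#' @param mcav MCA mean-velocity trace, cm/s.
#' @param post_window_s Post-hold search window for both the CO2 peak and the
#'   velocity response, seconds.
#' @return A `cvr_result`; see [cvr_indices()].
#' @export
#' @examples
#' sess <- simulate_breath_hold_session(39, 8, 60, 1.5)
#' res <- analyze_breath_hold(sess$etco2, sess$mcav, sess$schedule)
#' res$cvr_abs
analyze_breath_hold <- function(etco2, mcav, schedule, t0_s = 0,
                                post_window_s = 15) {
  ets <- extract_end_tidal(etco2, schedule, t0_s = t0_s)
  fs <- sig_rate(etco2)
  v <- sig_values(etco2)
  holds <- schedule[schedule$segment == "hold", ]
  per_repeat <- purrr::map_dfr(unique(schedule$repeat_idx), function(r) {
    h1 <- holds$end_s[holds$repeat_idx == r]
    i0 <- floor((t0_s + h1) * fs) + 1
    i1 <- min(length(v), floor((t0_s + h1 + post_window_s) * fs))
    peak <- max(v[i0:i1])
    de <- delta_etco2(ets$end_tidal[ets$repeat_idx == r], peak)
    dm <- delta_mcav(mcav, schedule, r, t0_s = t0_s,
                     post_window_s = post_window_s)
    tibble::tibble(repeat_idx = r, delta_etco2 = de, delta_mcav = dm$delta,
                   baseline_mcav = dm$baseline)
  })
  cvr_indices(per_repeat)
}

#' @export
print.cvr_result <- function(x, ...) {
  cat(sprintf(
    "<cvr_result> CVR = %.3f cm/s/mmHg (%.3f %%/mmHg), baseline MCAv %.1f cm/s, %d/%d valid repeats\n",
    x$cvr_abs, x$cvr_rel, x$baseline_mcav, x$n_valid, nrow(x$per_repeat)
  ))
  invisible(x)
}
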