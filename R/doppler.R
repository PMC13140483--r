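#' Epoching plan for Doppler velocity metrics
#'
#' Standard site plans: the middle cerebral artery uses eight 7 s epochs
#' across a 2 min window; the common carotid uses two 12 s epochs. Epochs are
#' spaced evenly across the total window.
#'
#' @param site `"mca"` or `"carotid"`, or `"custom"` with the remaining
#'   arguments supplied.
#' @param n_epochs,epoch_s,total_window_s Custom plan parameters; must
#'   satisfy `n_epochs * epoch_s <= total_window_s`.
#' @return A one-row tibble: `site`, `n_epochs`, `epoch_s`, `total_window_s`.
#' @export
epoch_plan <- function(site = c("mca", "carotid", "custom"), n_epochs = NULL,
                       epoch_s = NULL, total_window_s = NULL) {
  site <- match.arg(site)
  plan <- switch(site,
    mca = list(n_epochs = 8L, epoch_s = 7, total_window_s = 120),
    carotid = list(n_epochs = 2L, epoch_s = 12, total_window_s = 24),
    custom = list(n_epochs = as.integer(n_epochs), epoch_s = epoch_s,
                  total_window_s = total_window_s)
  )
  if (is.null(plan$n_epochs) || is.null(plan$epoch_s) ||
      is.null(plan$total_window_s)) {
    stop("custom plans need `n_epochs`, `epoch_s` and `total_window_s`",
         call. = FALSE)
  }
  if (plan$n_epochs * plan$epoch_s > plan$total_window_s + 1e-9) {
    stop("epochs do not fit: n_epochs * epoch_s exceeds total_window_s",
         call. = FALSE)
  }
  tibble::tibble(site = site, n_epochs = plan$n_epochs, epoch_s = plan$epoch_s,
                 total_window_s = plan$total_window_s)
}

#' Per-epoch systolic/diastolic/mean velocity
#'
#' Splits the velocity envelope into the planned epochs (evenly spaced across
#' the window) and computes, per epoch, the systolic velocity as the mean of
#' per-beat maxima, the diastolic velocity as the mean of per-beat minima and
#' the mean velocity as the time-average. When too few beats can be
#' identified inside an epoch (e.g., a near-constant envelope) the epoch
#' extrema are used directly.
#'
#' @param velocity A [sampled_signal()] in cm/s covering the plan's window.
#' @param plan An [epoch_plan()].
#' @return A tibble with one row per epoch: `epoch`, `start_s`, `v_sys`,
#'   `v_dia`, `v_mean`.
#' @export
#' @examples
#' env <- simulate_doppler_envelope(98, 46, 63, duration_s = 124)
#' epoch_metrics(env, epoch_plan("mca"))
epoch_metrics <- function(velocity, plan) {
  stopifnot(inherits(velocity, "sampled_signal"))
  fs <- sig_rate(velocity)
  dur <- nrow(velocity) / fs
  if (dur + 1e-9 < plan$total_window_s) {
    stop("window error: signal (", signif(dur, 4), " s) shorter than the ",
         plan$total_window_s, " s plan window", call. = FALSE)
  }
  starts <- if (plan$n_epochs == 1) 0 else {
    seq(0, plan$total_window_s - plan$epoch_s, length.out = plan$n_epochs)
  }
  purrr::map_dfr(seq_along(starts), function(k) {
    i0 <- floor(starts[k] * fs) + 1
    i1 <- min(nrow(velocity), i0 + round(plan$epoch_s * fs) - 1)
    v <- velocity$value[i0:i1]
    seg <- sampled_signal(v, fs)
    beats <- tryCatch(detect_beats(seg, anchor = "foot"),
                      error = function(e) NULL)
    segs <- if (!is.null(beats)) segment_beats(beats, length(v)) else list()
    if (length(segs) >= 2) {
      v_sys <- mean(purrr::map_dbl(segs, ~ max(v[.x])))
      v_dia <- mean(purrr::map_dbl(segs, ~ min(v[.x])))
    } else {
      v_sys <- max(v)
      v_dia <- min(v)
    }
    tibble::tibble(epoch = k, start_s = starts[k], v_sys = v_sys,
                   v_dia = v_dia, v_mean = mean(v))
  })
}

#' Doppler pulsatility index
#'
#' `PI = (v_sys - v_dia) / v_mean`; dimensionless, scale-invariant.
#'
#' @param v_sys,v_dia,v_mean Systolic, diastolic and mean velocity, cm/s
#'   (`v_mean > 0`). Vectorized.
#' @return PI, a.u.
#' @export
#' @examples
#' pulsatility_index(98, 46, 63)
pulsatility_index <- function(v_sys, v_dia, v_mean) {
  if (any(v_mean <= 0)) stop("domain error: v_mean must be positive", call. = FALSE)
  (v_sys - v_dia) / v_mean
}

#' Doppler resistive index (Pourcelot)
#'
#' `RI = (v_sys - v_dia) / v_sys`; lies in [0, 1] for non-negative
#' velocities. Related to the pulsatility index by
#' `RI = PI * v_mean / v_sys`.
#'
#' @param v_sys,v_dia Systolic and diastolic velocity, cm/s (`v_sys > 0`).
#'   Vectorized.
#' @return RI, a.u.
#' @export
#' @examples
#' resistive_index(106, 45)
resistive_index <- function(v_sys, v_dia) {
  if (any(v_sys <= 0)) stop("domain error: v_sys must be positive", call. = FALSE)
  (v_sys - v_dia) / v_sys
}

#' Cerebrovascular conductance index
#'
#' `mean velocity / mean arterial pressure`, cm/s per mmHg.
#'
#' @param v_mean Mean velocity, cm/s.
#' @param map_mmhg Brachial waveform mean arterial pressure, mmHg (> 0).
#' @return Conductance, cm/s/mmHg.
#' @export
conductance <- function(v_mean, map_mmhg) {
  if (any(map_mmhg <= 0)) stop("domain error: MAP must be positive", call. = FALSE)
  v_mean / map_mmhg
}

#' Aggregate Doppler metrics for a velocity recording
#'
#' Runs [epoch_metrics()] and aggregates across epochs (mean of per-epoch
#' values), deriving the pulsatility index, resistive index and — when a MAP
#' is supplied — the conductance index. Per-subject indices are computed from
#' that subject's velocities (mean of ratios across epochs, not a ratio of
#' group means).
#'
#' @inheritParams epoch_metrics
#' @param map_mmhg Optional mean arterial pressure for the conductance index.
#' @return A list of class `doppler_metrics` with `per_epoch` (tibble) and
#'   `summary` (one-row tibble: `site`, `v_sys`, `v_dia`, `v_mean`, `pi`,
#'   `ri`, `conductance`).
#' @export
doppler_metrics <- function(velocity, plan, map_mmhg = NULL) {
  per_epoch <- epoch_metrics(velocity, plan) |>
    dplyr::mutate(pi = pulsatility_index(.data$v_sys, .data$v_dia, .data$v_mean),
                  ri = resistive_index(.data$v_sys, .data$v_dia))
  summary <- tibble::tibble(
    site = plan$site,
    v_sys = mean(per_epoch$v_sys),
    v_dia = mean(per_epoch$v_dia),
    v_mean = mean(per_epoch$v_mean),
    pi = mean(per_epoch$pi),
    ri = mean(per_epoch$ri),
    conductance = if (is.null(map_mmhg)) NA_real_ else
      conductance(mean(per_epoch$v_mean), map_mmhg)
  )
  structure(list(per_epoch = per_epoch, summary = summary),
            class = "doppler_metrics")
}

#' @export
print.doppler_metrics <- function(x, ...) {
  cat("<doppler_metrics>", x$summary$site, "site,",
      nrow(x$per_epoch), "epochs\n")
  print(x$summary)
  invisible(x)
}
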