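#' Intersecting-tangents foot of a pressure upstroke
#'
#' The waveform foot is located at the intersection of (a) the horizontal
#' line through the pre-upstroke minimum and (b) the tangent to the waveform
#' at its point of maximum upstroke slope — the consensus foot definition for
#' foot-to-foot transit-time methods.
#'
#' @param beat A [sampled_signal()] or [ensemble_beat()] containing one
#'   upstroke.
#' @param smooth_s Width of the centred moving average applied to the
#'   derivative before locating the maximum slope, seconds.
#' @return Foot time in seconds, relative to the start of `beat`.
#' @export
#' @examples
#' v <- c(rep(0, 50), seq(0, 1, length.out = 50))
#' detect_foot(sampled_signal(v, 100)) # foot at 0.49 s, the ramp onset
detect_foot <- function(beat, smooth_s = 0.02) {
  v <- sig_values(beat)
  fs <- sig_rate(beat)
  n <- length(v)
  # centred moving average over ~20 ms (edge-padded): suppresses sample noise
  # while leaving piecewise-linear upstrokes exact away from the corner
  k <- max(1L, round(smooth_s * fs))
  if (k %% 2 == 0) k <- k + 1L
  k2 <- (k - 1L) %/% 2L
  vs <- if (k > 1 && n > k) {
    padded <- c(rep(v[1], k2), v, rep(v[n], k2))
    as.numeric(stats::filter(padded, rep(1 / k, k), sides = 2))[k2 + seq_len(n)]
  } else v
  d <- sig_values(signal_derivative(sampled_signal(vs, fs)))
  # edge samples see the replicated padding; keep the argmax interior
  search <- if (n > 2 * (k2 + 1)) (k2 + 1):(n - k2 - 1) else seq_len(n)
  i_max <- search[which.max(d[search])]
  if (d[i_max] <= 0) {
    stop("no upstroke: maximum slope is not positive", call. = FALSE)
  }
  v_min <- min(vs[seq_len(i_max)])
  t_m <- (i_max - 1) / fs
  t_m - (vs[i_max] - v_min) / d[i_max]
}

#' Carotid-femoral pulse wave velocity
#'
#' Per beat (shared R-wave gating), the transit time is the difference
#' between the femoral and carotid intersecting-tangent foot times; the
#' per-beat transit times are aggregated by the median (robust to isolated
#' mis-detections) and the velocity is `path_distance_cm / transit_time`.
#'
#' @param carotid,femoral [sampled_signal()] pressure waveforms on a common
#'   time base.
#' @param beats A shared [beat_set()] (R-wave anchors) valid for both signals.
#' @param path_distance_cm Carotid-to-femoral path distance, cm.
#' @param min_beats Minimum number of usable beats (default 5).
#' @return One-row tibble: `cfpwv` (cm/s), `transit_time_s`,
#'   `path_distance_cm`, `n_beats`.
#' @export
cfpwv <- function(carotid, femoral, beats, path_distance_cm, min_beats = 5) {
  stopifnot(inherits(carotid, "sampled_signal"),
            inherits(femoral, "sampled_signal"),
            inherits(beats, "beat_set"))
  if (path_distance_cm <= 0) stop("`path_distance_cm` must be > 0", call. = FALSE)
  fs <- sig_rate(carotid)
  n <- min(nrow(carotid), nrow(femoral))
  segs <- segment_beats(beats, n)
  dts <- purrr::map_dbl(segs, function(ix) {
    fc <- tryCatch(detect_foot(sampled_signal(carotid$value[ix], fs)),
                   error = function(e) NA_real_)
    ff <- tryCatch(detect_foot(sampled_signal(femoral$value[ix], fs)),
                   error = function(e) NA_real_)
    ff - fc
  })
  dts <- dts[is.finite(dts)]
  if (length(dts) < min_beats) {
    stop("insufficient beats: ", length(dts), " usable beats, need at least ",
         min_beats, call. = FALSE)
  }
  transit <- stats::median(dts)
  if (transit <= 0) {
    stop("ordering error: median carotid-to-femoral time lag is not positive ",
         "(sites swapped or mis-gated?)", call. = FALSE)
  }
  tibble::tibble(cfpwv = path_distance_cm / transit, transit_time_s = transit,
                 path_distance_cm = path_distance_cm, n_beats = length(dts))
}

#' Beta stiffness index
#'
#' `ln(p_sys / p_dia) / ((d_sys - d_dia) / d_dia)` — the pressure-normalized
#' stiffness of the carotid wall from systolic/diastolic pressure and
#' diameter. Dimensionless (a.u.); vectorized over its arguments.
#'
#' @param p_sys,p_dia Systolic and diastolic pressure, mmHg
#'   (`p_sys >= p_dia > 0`).
#' @param d_sys,d_dia Systolic and diastolic diameter, mm
#'   (`d_sys > d_dia > 0`).
#' @return Beta stiffness, a.u.
#' @export
#' @examples
#' beta_stiffness(120, 80, 6.05, 5.50) # ln(1.5) / 0.1
beta_stiffness <- function(p_sys, p_dia, d_sys, d_dia) {
  if (any(p_dia <= 0) || any(p_sys < p_dia)) {
    stop("domain error: pressures must satisfy p_sys >= p_dia > 0", call. = FALSE)
  }
  if (any(d_dia <= 0) || any(d_sys < d_dia)) {
    stop("domain error: diameters must satisfy d_sys >= d_dia > 0", call. = FALSE)
  }
  if (any(d_sys == d_dia)) {
    stop("zero-strain error: d_sys equals d_dia", call. = FALSE)
  }
  log(p_sys / p_dia) / ((d_sys - d_dia) / d_dia)
}

#' Volumetric flow from a Doppler velocity waveform
#'
#' Multiplies velocity (cm/s) by the diastolic cross-sectional area of the
#' artery, assuming a circular orifice: `area = pi * (d/2)^2` with the
#' diameter converted from mm to cm, giving flow in mL/s.
#'
#' @param velocity A [sampled_signal()] or [ensemble_beat()] in cm/s.
#' @param diastolic_diameter_mm Diastolic lumen diameter, mm (> 0).
#' @return The flow waveform (same class as `velocity`, units mL/s) with the
#'   diameter and `cross_sectional_area_cm2` stored as attributes.
#' @export
volumetric_flow <- function(velocity, diastolic_diameter_mm) {
  if (diastolic_diameter_mm <= 0) {
    stop("domain error: diameter must be positive", call. = FALSE)
  }
  area_cm2 <- pi * (diastolic_diameter_mm / 20)^2
  out <- sig_replace(velocity, sig_values(velocity) * area_cm2)
  attr(out, "units") <- "mL/s"
  attr(out, "diastolic_diameter_mm") <- diastolic_diameter_mm
  attr(out, "cross_sectional_area_cm2") <- area_cm2
  class(out) <- unique(c("flow_beat", class(out)))
  out
}

# linear resampling of `flow` onto the (normalized) time base of `pressure`
match_time_base <- function(flow, pressure) {
  nq <- nrow(flow); np <- nrow(pressure)
  if (nq == np) return(sig_values(flow))
  stats::approx(seq(0, 1, length.out = nq), sig_values(flow),
                xout = seq(0, 1, length.out = np))$y
}

#' Time-domain characteristic impedance
#'
#' `Zc = max(dP/dt) / max(dQ/dt)`, both derivative maxima taken over the full
#' cycle with centered finite differences. The flow beat is resampled to the
#' pressure time base when lengths differ.
#'
#' @param pressure An [ensemble_beat()] in mmHg.
#' @param flow A flow beat in mL/s (see [volumetric_flow()]).
#' @return Zc in mmHg s/mL.
#' @export
#' @examples
#' wk <- simulate_windkessel(0.1, 1, 1.5, 60, 70, sampling_rate = 500, n_beats = 1)
#' characteristic_impedance(wk$pressure, wk$flow)
characteristic_impedance <- function(pressure, flow) {
  q <- match_time_base(flow, pressure)
  fs <- sig_rate(pressure)
  dq_max <- max(sig_values(signal_derivative(sampled_signal(q, fs))))
  if (dq_max <= 0) {
    stop("degenerate flow: maximum flow derivative is not positive", call. = FALSE)
  }
  dp_max <- max(sig_values(signal_derivative(pressure)))
  dp_max / dq_max
}

#' Forward/backward wave separation
#'
#' Splits the pulsatile pressure into its forward- and backward-travelling
#' components in the time domain:
#' `Pf = (dP + Zc * dQ) / 2`, `Pb = (dP - Zc * dQ) / 2`, where
#' `dP = P - min(P)` and `dQ` is the flow referenced to its value at the
#' pressure foot (so venous-like diastolic dips do not bias the reference).
#' Amplitudes are peak minus foot value of each separated wave and the
#' reflection index is `RIx = Pb amplitude / Pf amplitude`.
#'
#' @param pressure An [ensemble_beat()] in mmHg.
#' @param flow A flow beat in mL/s on the same cycle.
#' @param zc Characteristic impedance in mmHg s/mL (> 0); see
#'   [characteristic_impedance()].
#' @return An object of class `wave_separation`: scalars `zc`,
#'   `pf_amplitude`, `pb_amplitude`, `reflection_index`, and a `waves` tibble
#'   (`time_s`, `dp`, `dq`, `pf`, `pb`). `Pf + Pb` reconstructs `dP`
#'   exactly. Use [tidy()][generics::tidy] / [glance()][generics::glance] /
#'   [ggplot2::autoplot()].
#' @export
wave_separation <- function(pressure, flow, zc) {
  if (zc <= 0) stop("domain error: `zc` must be positive", call. = FALSE)
  fs <- sig_rate(pressure)
  p <- sig_values(pressure)
  q <- match_time_base(flow, pressure)
  i_foot <- max(1L, min(length(p), round(detect_foot(pressure) * fs) + 1L))
  dp <- p - min(p)
  dq <- q - q[i_foot]
  pf <- (dp + zc * dq) / 2
  pb <- (dp - zc * dq) / 2
  pf_amp <- max(pf) - pf[i_foot]
  pb_amp <- max(pb) - pb[i_foot]
  rix <- pb_amp / pf_amp
  if (is.finite(rix) && rix > 1) {
    warning("reflection index exceeds 1 (backward wave larger than forward); ",
            "check calibration and flow scaling", call. = FALSE)
  }
  structure(
    list(
      waves = tibble::tibble(time_s = pressure$time_s, dp = dp, dq = dq,
                             pf = pf, pb = pb),
      zc = zc, pf_amplitude = pf_amp, pb_amplitude = pb_amp,
      reflection_index = rix, foot_index = i_foot
    ),
    class = "wave_separation"
  )
}

#' @export
print.wave_separation <- function(x, ...) {
  cat(sprintf(
    "<wave_separation> Zc = %.4g mmHg s/mL | Pf = %.4g mmHg | Pb = %.4g mmHg | RIx = %.3f\n",
    x$zc, x$pf_amplitude, x$pb_amplitude, x$reflection_index
  ))
  invisible(x)
}
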