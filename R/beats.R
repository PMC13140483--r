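#' Beat onsets for a sampled signal
#'
#' A set of beat anchors (R-wave or pressure-foot onsets) as a tibble of
#' sample indices and times. Onsets must be strictly increasing and imply
#' physiologic beat periods.
#'
#' @param onset_idx Strictly increasing integer sample indices (1-based).
#' @param sampling_rate Sampling rate of the parent signal, Hz.
#' @param anchor `"r_wave"` or `"foot"`.
#' @return A tibble of class `beat_set` with columns `onset_idx`,
#'   `onset_time_s`.
#' @export
beat_set <- function(onset_idx, sampling_rate, anchor = c("r_wave", "foot")) {
  anchor <- match.arg(anchor)
  onset_idx <- as.integer(onset_idx)
  if (length(onset_idx) < 2 || any(diff(onset_idx) <= 0)) {
    stop("`onset_idx` must contain at least 2 strictly increasing indices",
         call. = FALSE)
  }
  out <- tibble::tibble(onset_idx = onset_idx,
                        onset_time_s = (onset_idx - 1) / sampling_rate)
  structure(out, anchor = anchor, sampling_rate = sampling_rate,
            class = c("beat_set", class(out)))
}

#' Detect beat onsets
#'
#' For `anchor = "r_wave"` the signal is band-pass filtered in the QRS band
#' (5-25 Hz, zero-phase Butterworth) and onsets are placed at local maxima of
#' the filtered trace; for `anchor = "foot"` onsets are placed at the maxima
#' of the first derivative (the steepest upstroke of each pressure/velocity
#' beat). Candidate onsets implying beat periods outside the physiologic
#' bounds are dropped.
#'
#' @param signal A [sampled_signal()] long enough to contain at least 2 beats.
#' @param anchor Anchor kind, `"r_wave"` or `"foot"`.
#' @param min_period_s,max_period_s Physiologic beat-period bounds, seconds.
#' @return A [beat_set()].
#' @export
#' @examples
#' ecg <- simulate_ecg(60, duration_s = 10)
#' nrow(detect_beats(ecg))
detect_beats <- function(signal, anchor = c("r_wave", "foot"),
                         min_period_s = 0.33, max_period_s = 2.0) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(signal, "sampled_signal"))
  fs <- sig_rate(signal)
  v <- sig_values(signal)
  if (anchor == "r_wave") {
    bf <- signal::butter(2, c(5, 25) / (fs / 2), type = "pass")
    score <- signal::filtfilt(bf, v - mean(v))
  } else {
    score <- c(diff(v), 0) * fs
    # light smoothing so sample noise does not fragment the upstroke peak
    k <- max(1L, round(0.01 * fs))
    score <- stats::filter(score, rep(1 / k, k), sides = 2)
    score[is.na(score)] <- 0
    score <- as.numeric(score)
  }
  thr <- 0.4 * stats::quantile(score, 0.995, names = FALSE)
  if (!is.finite(thr) || thr <= 0 || max(score) <= 1e-12) {
    stop("insufficient beats: no onset candidates found (flat or featureless signal)",
         call. = FALSE)
  }
  cand <- which(score > thr &
                  score >= c(-Inf, score[-length(score)]) &
                  score > c(score[-1], Inf))
  # greedy non-maximum suppression at the minimum physiologic period
  cand <- cand[order(-score[cand])]
  keep <- logical(0)
  sel <- integer(0)
  min_gap <- round(min_period_s * fs)
  for (i in cand) {
    if (!length(sel) || all(abs(sel - i) >= min_gap)) sel <- c(sel, i)
  }
  sel <- sort(sel)
  if (length(sel) < 2) {
    stop("insufficient beats: fewer than 2 onsets detected", call. = FALSE)
  }
  beat_set(sel, fs, anchor)
}

# half-open [onset_i, onset_{i+1}) sample ranges fully inside `window_idx`
segment_beats <- function(beats, n_samples, window_end_idx = n_samples) {
  on <- beats$onset_idx
  purrr::keep(
    purrr::map(seq_len(length(on) - 1), function(i) on[i]:(on[i + 1] - 1)),
    function(ix) max(ix) + 1 <= window_end_idx
  )
}

#' Ensemble-average beats over an epoch
#'
#' Segments the signal into half-open beats `[onset_i, onset_{i+1})` that are
#' complete within the first `epoch_s` seconds, drops artifact beats whose
#' peak-to-foot amplitude deviates more than `artifact_sd` standard deviations
#' from the epoch median amplitude, time-normalizes each remaining beat to
#' the median beat length by linear resampling, and averages pointwise.
#'
#' A warning is issued when fewer than 7 beats contribute, mirroring the
#' quality-control expectation that an ensemble set contain 7-10 beats.
#'
#' @param signal A [sampled_signal()].
#' @param beats A [beat_set()] for `signal`.
#' @param epoch_s Epoch length in seconds; `NULL` uses the whole signal.
#'   Default 20 s, the standard tonometry averaging epoch.
#' @param artifact_sd Amplitude-outlier rejection threshold, in SDs.
#' @return An [ensemble_beat()] with `n_beats_averaged` recorded.
#' @export
ensemble_average <- function(signal, beats, epoch_s = 20, artifact_sd = 3) {
  stopifnot(inherits(signal, "sampled_signal"), inherits(beats, "beat_set"))
  fs <- sig_rate(signal)
  n <- nrow(signal)
  if (is.null(epoch_s)) epoch_s <- n / fs
  if (epoch_s > n / fs + 1e-9) {
    stop("window error: epoch (", epoch_s, " s) longer than signal (",
         signif(n / fs, 4), " s)", call. = FALSE)
  }
  segs <- segment_beats(beats, n, window_end_idx = floor(epoch_s * fs))
  if (length(segs) < 2) {
    stop("insufficient beats: need at least 2 complete beats inside the epoch",
         call. = FALSE)
  }
  v <- sig_values(signal)
  amps <- purrr::map_dbl(segs, function(ix) max(v[ix]) - min(v[ix]))
  # robust SD (scaled MAD) so a single corrupted beat cannot mask itself
  s <- stats::mad(amps)
  if (is.finite(s) && s > 1e-9 * max(abs(amps))) {
    ok <- abs(amps - stats::median(amps)) <= artifact_sd * s
    if (any(!ok)) {
      message(sum(!ok), " beat(s) rejected as amplitude artifacts")
      segs <- segs[ok]
    }
  }
  if (length(segs) < 7) {
    warning("only ", length(segs),
            " beats averaged; ensemble sets should contain 7-10 beats",
            call. = FALSE)
  }
  len <- round(stats::median(lengths(segs)))
  mat <- vapply(segs, function(ix) {
    y <- v[ix]
    if (length(y) == len) return(y)
    stats::approx(seq_along(y), y, xout = seq(1, length(y), length.out = len))$y
  }, numeric(len))
  ensemble_beat(rowMeans(mat), fs, sig_units(signal),
                attr(signal, "label") %||% "", n_beats_averaged = length(segs))
}

#' Time-average of a beat
#'
#' @param beat An [ensemble_beat()] (or any [sampled_signal()]).
#' @return The mean of the waveform over the cycle.
#' @export
signal_mean <- function(beat) mean(sig_values(beat))

#' First time-derivative of a waveform
#'
#' Centered finite differences scaled by the sampling rate, with one-sided
#' differences at the ends; exact on linear segments.
#'
#' @param beat A [sampled_signal()] or [ensemble_beat()].
#' @return A [sampled_signal()] of the same length, units per second.
#' @export
signal_derivative <- function(beat) {
  v <- sig_values(beat)
  fs <- sig_rate(beat)
  n <- length(v)
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) * fs
  d[n] <- (v[n] - v[n - 1]) * fs
  if (n > 2) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * fs / 2
  u <- sig_units(beat)
  sampled_signal(d, fs, if (nzchar(u)) paste0(u, "/s") else "1/s",
                 paste0("d/dt ", attr(beat, "label") %||% ""))
}
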