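#' Uniformly sampled physiological signal
#'
#' The basic carrier for every waveform in the package: a tibble with columns
#' `time_s` and `value`, carrying the sampling rate, units and a label as
#' attributes. Time starts at 0 and advances by `1/sampling_rate`.
#'
#' @param value Numeric vector of samples (at least 2, no missing values).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param units Unit string, e.g. `"mmHg"`, `"cm/s"`.
#' @param label Optional free-text label (signal site or channel name).
#'
#' @return A tibble of class `sampled_signal` with columns `time_s`, `value`.
#' @export
#' @examples
#' s <- sampled_signal(sin(2 * pi * seq(0, 1, by = 1e-3)), 1000, "mmHg")
#' sig_rate(s)
sampled_signal <- function(value, sampling_rate, units = "", label = "") {
  if (!is.numeric(value) || length(value) < 2) {
    stop("`value` must be a numeric vector with at least 2 samples", call. = FALSE)
  }
  if (anyNA(value)) {
    stop("signal contains missing values; gaps must be resolved at ingest", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number (Hz)", call. = FALSE)
  }
  out <- tibble::tibble(
    time_s = (seq_along(value) - 1) / sampling_rate,
    value = as.numeric(value)
  )
  structure(
    out,
    sampling_rate = sampling_rate,
    units = units,
    label = label,
    class = c("sampled_signal", class(out))
  )
}

#' One ensemble-averaged cardiac cycle
#'
#' A single-beat waveform produced by (or compatible with) [ensemble_average()],
#' anchored at the beat onset. Shares the `sampled_signal` layout and
#' additionally records how many beats were averaged.
#'
#' @inheritParams sampled_signal
#' @param n_beats_averaged Number of beats that went into the average (>= 1).
#' @return A tibble of class `ensemble_beat` (also a `sampled_signal`).
#' @export
ensemble_beat <- function(value, sampling_rate, units = "", label = "",
                          n_beats_averaged = 1L) {
  if (n_beats_averaged < 1) stop("`n_beats_averaged` must be >= 1", call. = FALSE)
  s <- sampled_signal(value, sampling_rate, units, label)
  attr(s, "n_beats_averaged") <- as.integer(n_beats_averaged)
  class(s) <- c("ensemble_beat", class(s))
  s
}

#' @rdname sampled_signal
#' @param x A `sampled_signal`.
#' @export
sig_rate <- function(x) attr(x, "sampling_rate")

#' @rdname sampled_signal
#' @export
sig_units <- function(x) attr(x, "units")

#' @rdname sampled_signal
#' @export
sig_values <- function(x) x[["value"]]

# rebuild a signal with new values but the same metadata
sig_replace <- function(x, value) {
  s <- sampled_signal(value, sig_rate(x), sig_units(x), attr(x, "label") %||% "")
  nb <- attr(x, "n_beats_averaged")
  if (!is.null(nb)) {
    attr(s, "n_beats_averaged") <- nb
    class(s) <- c("ensemble_beat", class(s))
  }
  s
}

#' Coerce a data frame to a sampled signal
#'
#' Validates that the `time_s` column is uniform (relative jitter below
#' `tol_ppm` parts per million of the sampling interval) and consistent with
#' `sampling_rate` if given.
#'
#' @param df Data frame with columns `time_s` and `value`.
#' @param sampling_rate Optional rate in Hz; inferred from the time column when
#'   `NULL`.
#' @param units,label Signal metadata.
#' @param tol_ppm Allowed relative jitter of the time grid, in ppm.
#' @return A `sampled_signal`.
#' @export
as_sampled_signal <- function(df, sampling_rate = NULL, units = "", label = "",
                              tol_ppm = 1) {
  stopifnot(all(c("time_s", "value") %in% names(df)))
  t <- df[["time_s"]]
  dt <- diff(t)
  if (length(dt) < 1 || any(dt <= 0)) {
    stop("time column must be strictly increasing", call. = FALSE)
  }
  step <- stats::median(dt)
  if (max(abs(dt - step)) > tol_ppm * 1e-6 * step) {
    stop("non-uniform time column: sample spacing jitter exceeds ", tol_ppm,
         " ppm (gap or irregular grid)", call. = FALSE)
  }
  fs <- 1 / step
  if (!is.null(sampling_rate) &&
      abs(fs - sampling_rate) > tol_ppm * 1e-6 * sampling_rate) {
    stop("time column inconsistent with declared sampling_rate", call. = FALSE)
  }
  sampled_signal(df[["value"]], sampling_rate %||% fs, units, label)
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf(
    "<%s> %d samples @ %g Hz (%.3f s)%s%s\n",
    class(x)[1], nrow(x), sig_rate(x), nrow(x) / sig_rate(x),
    if (nzchar(sig_units(x))) paste0(" [", sig_units(x), "]") else "",
    if (nzchar(attr(x, "label") %||% "")) paste0(" ", attr(x, "label")) else ""
  ))
  NextMethod()
}
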