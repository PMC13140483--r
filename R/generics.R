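#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a wave-separation result
#'
#' @param x A `wave_separation` object.
#' @param ... Unused.
#' @return The `waves` tibble: `time_s`, pulsatile pressure `dp`, referenced
#'   flow `dq`, forward wave `pf`, backward wave `pb`.
#' @export
#' @exportS3Method tidy
tidy.wave_separation <- function(x, ...) x$waves

#' One-row summary of a wave-separation result
#'
#' @param x A `wave_separation` object.
#' @param ... Unused.
#' @return Tibble: `zc`, `pf_amplitude`, `pb_amplitude`, `reflection_index`.
#' @export
#' @exportS3Method glance
glance.wave_separation <- function(x, ...) {
  tibble::tibble(zc = x$zc, pf_amplitude = x$pf_amplitude,
                 pb_amplitude = x$pb_amplitude,
                 reflection_index = x$reflection_index)
}

#' Tidy a CVR result
#'
#' @param x A `cvr_result` object.
#' @param ... Unused.
#' @return The per-repeat tibble with the `valid` flag.
#' @export
#' @exportS3Method tidy
tidy.cvr_result <- function(x, ...) x$per_repeat

#' One-row summary of a CVR result
#'
#' @param x A `cvr_result` object.
#' @param ... Unused.
#' @return Tibble: `cvr_abs` (cm/s/mmHg), `cvr_rel` (%/mmHg),
#'   `baseline_mcav`, `n_valid`.
#' @export
#' @exportS3Method glance
glance.cvr_result <- function(x, ...) {
  tibble::tibble(cvr_abs = x$cvr_abs, cvr_rel = x$cvr_rel,
                 baseline_mcav = x$baseline_mcav, n_valid = x$n_valid)
}

#' Tidy Doppler metrics
#'
#' @param x A `doppler_metrics` object.
#' @param ... Unused.
#' @return The per-epoch tibble.
#' @export
#' @exportS3Method tidy
tidy.doppler_metrics <- function(x, ...) x$per_epoch

#' One-row summary of Doppler metrics
#'
#' @param x A `doppler_metrics` object.
#' @param ... Unused.
#' @return The aggregate summary tibble.
#' @export
#' @exportS3Method glance
glance.doppler_metrics <- function(x, ...) x$summary
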