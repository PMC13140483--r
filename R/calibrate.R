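#' Average duplicate cuff readings under the 5 mmHg agreement rule
#'
#' Consecutive duplicate cuff measurements are accepted and averaged when both
#' systolic and diastolic agree within `tol_mmhg`; otherwise an error asks for
#' repeated measurement, mirroring the screening procedure.
#'
#' @param readings Tibble/data frame with columns `systolic`, `diastolic`
#'   (mmHg), one row per measurement (>= 2 rows).
#' @param tol_mmhg Agreement tolerance, mmHg.
#' @return A one-row tibble with the averaged `systolic` and `diastolic`.
#' @export
cuff_reading <- function(readings, tol_mmhg = 5) {
  stopifnot(all(c("systolic", "diastolic") %in% names(readings)))
  if (nrow(readings) < 1) stop("no cuff readings supplied", call. = FALSE)
  if (any(readings$systolic <= readings$diastolic) ||
      any(readings$diastolic <= 0)) {
    stop("cuff readings must satisfy systolic > diastolic > 0", call. = FALSE)
  }
  if (nrow(readings) >= 2) {
    last2 <- utils::tail(readings, 2)
    if (diff(range(last2$systolic)) > tol_mmhg ||
        diff(range(last2$diastolic)) > tol_mmhg) {
      stop("duplicate cuff readings differ by more than ", tol_mmhg,
           " mmHg; repeat the measurement", call. = FALSE)
    }
    readings <- last2
  }
  tibble::tibble(systolic = mean(readings$systolic),
                 diastolic = mean(readings$diastolic))
}

new_pressure_beat <- function(beat, site) {
  v <- sig_values(beat)
  attr(beat, "site") <- site
  attr(beat, "systolic") <- max(v)
  attr(beat, "diastolic") <- min(v)
  attr(beat, "mean") <- mean(v)
  attr(beat, "pulse_pressure") <- max(v) - min(v)
  attr(beat, "units") <- "mmHg"
  class(beat) <- unique(c("pressure_beat", class(beat)))
  beat
}

#' Calibrate a raw brachial waveform to cuff pressures
#'
#' Affine rescaling sending the waveform minimum to the diastolic cuff
#' pressure and the maximum to the systolic cuff pressure. Shape is exactly
#' preserved (correlation 1 with the raw trace).
#'
#' @param raw An [ensemble_beat()] (any units) with nonzero amplitude.
#' @param cuff A one-row data frame with `systolic` and `diastolic` in mmHg
#'   (see [cuff_reading()]), or a length-2 numeric `c(systolic, diastolic)`.
#' @return A calibrated `pressure_beat` in mmHg; see [pressure_summary()].
#' @export
#' @examples
#' raw <- ensemble_beat(sin(seq(0, 2 * pi, length.out = 200))^2, 200)
#' b <- calibrate_brachial(raw, c(120, 80))
#' pressure_summary(b)
calibrate_brachial <- function(raw, cuff) {
  if (is.numeric(cuff)) cuff <- tibble::tibble(systolic = cuff[1], diastolic = cuff[2])
  stopifnot(cuff$systolic > cuff$diastolic)
  v <- sig_values(raw)
  amp <- max(v) - min(v)
  if (amp <= 0) stop("zero-amplitude beat: cannot calibrate a flat waveform",
                     call. = FALSE)
  scaled <- cuff$diastolic + (v - min(v)) / amp * (cuff$systolic - cuff$diastolic)
  out <- sig_replace(raw, scaled)
  new_pressure_beat(out, site = "brachial")
}

#' Mean arterial pressure from a calibrated brachial beat
#'
#' The time-average of the calibrated waveform over one full cycle (the
#' waveform-integration definition, not the diastolic + pulse-pressure/3 form
#' factor; see [calibrate_carotid()] `map_method` for the alternative).
#'
#' @param brachial A calibrated `pressure_beat` from [calibrate_brachial()].
#' @param method `"integral"` (default) or `"form_factor"`
#'   (diastolic + pulse pressure / 3).
#' @return MAP in mmHg.
#' @export
derive_map <- function(brachial, method = c("integral", "form_factor")) {
  method <- match.arg(method)
  v <- sig_values(brachial)
  if (method == "integral") mean(v) else min(v) + (max(v) - min(v)) / 3
}

#' Calibrate a raw carotid waveform to brachial diastolic and mean pressure
#'
#' The standard tonometric transfer: an affine map anchoring the carotid
#' waveform minimum at the brachial diastolic pressure and its mean at the
#' brachial MAP (both assumed unchanged between sites). Carotid systolic
#' pressure is then the mapped maximum, an output of the calibration.
#'
#' @param raw_carotid An [ensemble_beat()] (any units) whose mean exceeds its
#'   minimum.
#' @param brachial_diastolic Brachial diastolic pressure, mmHg.
#' @param brachial_map Brachial mean arterial pressure, mmHg
#'   (> `brachial_diastolic`).
#' @return A calibrated carotid `pressure_beat` in mmHg.
#' @export
calibrate_carotid <- function(raw_carotid, brachial_diastolic, brachial_map) {
  if (brachial_map <= brachial_diastolic) {
    stop("`brachial_map` must exceed `brachial_diastolic`", call. = FALSE)
  }
  v <- sig_values(raw_carotid)
  denom <- mean(v) - min(v)
  if (denom <= 0) {
    stop("degenerate carotid shape: waveform mean equals its minimum",
         call. = FALSE)
  }
  scaled <- brachial_diastolic +
    (v - min(v)) / denom * (brachial_map - brachial_diastolic)
  new_pressure_beat(sig_replace(raw_carotid, scaled), site = "carotid")
}

#' Summary of a calibrated pressure beat
#'
#' @param beat A `pressure_beat`.
#' @return One-row tibble: `site`, `systolic`, `diastolic`, `mean`,
#'   `pulse_pressure` (mmHg).
#' @export
pressure_summary <- function(beat) {
  stopifnot(inherits(beat, "pressure_beat"))
  tibble::tibble(
    site = attr(beat, "site"),
    systolic = attr(beat, "systolic"),
    diastolic = attr(beat, "diastolic"),
    mean = attr(beat, "mean"),
    pulse_pressure = attr(beat, "pulse_pressure")
  )
}
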