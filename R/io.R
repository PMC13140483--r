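#' Read and write waveform CSV files
#'
#' The interchange dialect for all waveforms: a plain CSV with columns
#' `time_s,value`, preceded by `#`-prefixed metadata lines of the form
#' `# key=value`. `units` and `sampling_rate` are required; any additional
#' keys (e.g., ground-truth generator parameters) round-trip unchanged.
#' Ingest validates the time column against the declared sampling rate to
#' within 1 ppm; gaps or jitter are a format error.
#'
#' @param path File path.
#' @return [read_waveform_csv()] returns a [sampled_signal()] with any extra
#'   metadata in the `meta` attribute; [write_waveform_csv()] returns `path`
#'   invisibly.
#' @export
read_waveform_csv <- function(path) {
  lines <- readr::read_lines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#\\s*", "", meta_lines), "=", fixed = TRUE)
  meta <- stats::setNames(
    lapply(kv, function(x) paste(x[-1], collapse = "=")),
    vapply(kv, `[`, "", 1)
  )
  meta <- lapply(meta, trimws)
  names(meta) <- trimws(names(meta))
  for (k in c("units", "sampling_rate")) {
    if (is.null(meta[[k]])) {
      stop("format error: missing required metadata field `", k, "` in ", path,
           call. = FALSE)
    }
  }
  fs <- suppressWarnings(as.numeric(meta$sampling_rate))
  if (!is.finite(fs) || fs <= 0) {
    stop("format error: invalid sampling_rate in ", path, call. = FALSE)
  }
  known_units <- c("mmHg", "cm/s", "mL/s", "mV", "a.u.")
  if (!meta$units %in% known_units) {
    stop("format error: unknown unit string `", meta$units,
         "` in field `units` (expected one of: ",
         paste(known_units, collapse = ", "), ")", call. = FALSE)
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  sig <- as_sampled_signal(df, sampling_rate = fs, units = meta$units,
                           label = meta$label %||% "")
  extra <- meta[setdiff(names(meta), c("units", "sampling_rate", "label"))]
  attr(sig, "meta") <- extra
  sig
}

#' @rdname read_waveform_csv
#' @param signal A [sampled_signal()].
#' @param meta Optional named list of extra metadata to embed (e.g.,
#'   ground-truth parameters); scalars only.
#' @export
write_waveform_csv <- function(signal, path, meta = list()) {
  stopifnot(inherits(signal, "sampled_signal"))
  gt <- attr(signal, "meta") %||% list()
  meta <- utils::modifyList(gt, meta)
  hdr <- c(
    sprintf("# units=%s", sig_units(signal)),
    sprintf("# sampling_rate=%.17g", sig_rate(signal)),
    if (nzchar(attr(signal, "label") %||% "")) {
      sprintf("# label=%s", attr(signal, "label"))
    },
    vapply(names(meta), function(k) sprintf("# %s=%s", k, meta[[k]]), "")
  )
  body <- paste(sprintf("%.17g", signal$time_s), sprintf("%.17g", signal$value),
                sep = ",")
  readr::write_lines(c(hdr, "time_s,value", body), path)
  invisible(path)
}
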