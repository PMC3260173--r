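#' Construct a scan table
#'
#' Scans are rows of a tibble; the peak list of each scan is a nested tibble
#' (`mz`, `intensity`, optionally `delta` for neutral-loss annotation) in the
#' `peaks` list column. One row describes one acquisition event: a survey
#' scan (`ms_level` 1), a full MS/MS scan (`ms_level` 2 with `precursor_mz`),
#' a precursor-ion scan (`mode` `"pis"` with `monitored_fragment_mz`) or a
#' neutral-loss scan (`mode` `"nls"` with `neutral_loss_delta`).
#'
#' @param sample_id sample identifier.
#' @param ms_level 1 or 2.
#' @param polarity +1 or -1.
#' @param mode `"full"`, `"pis"` or `"nls"`.
#' @param peaks a data frame with numeric `mz` and `intensity`.
#' @param precursor_mz precursor m/z (full MS/MS only).
#' @param monitored_fragment_mz monitored fragment m/z (PIS only).
#' @param neutral_loss_delta monitored mass difference (NLS only).
#' @param scan_index ordinal of the scan within its sample.
#' @param replicate optional replicate label (used to group transposed scans).
#' @param virtual TRUE for transposed (virtual) MS/MS scans.
#' @return A one-row scan tibble.
#' @export
scan_tbl <- function(sample_id, ms_level, polarity, mode = "full",
                     peaks = tibble::tibble(mz = numeric(), intensity = numeric()),
                     precursor_mz = NA_real_, monitored_fragment_mz = NA_real_,
                     neutral_loss_delta = NA_real_, scan_index = 1L,
                     replicate = NA_integer_, virtual = FALSE) {
  if (!ms_level %in% c(1, 2)) stop("ms_level must be 1 or 2", call. = FALSE)
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1", call. = FALSE)
  if (!mode %in% c("full", "pis", "nls")) stop("unknown scan mode: ", mode, call. = FALSE)
  if (mode == "pis" && is.na(monitored_fragment_mz)) {
    stop("PIS scan requires monitored_fragment_mz", call. = FALSE)
  }
  if (mode == "nls") {
    if (is.na(neutral_loss_delta)) stop("NLS scan requires neutral_loss_delta", call. = FALSE)
    if (neutral_loss_delta <= 0) stop("neutral_loss_delta must be positive", call. = FALSE)
  }
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("mz", "intensity") %in% names(peaks)))
  if (nrow(peaks) > 0) {
    if (any(peaks$mz <= 0)) stop("peak m/z must be positive", call. = FALSE)
    if (any(peaks$intensity < 0)) stop("peak intensity must be non-negative", call. = FALSE)
    peaks <- dplyr::arrange(peaks, .data$mz)
  }
  tibble::tibble(
    sample_id = as.character(sample_id),
    scan_index = as.integer(scan_index),
    ms_level = as.integer(ms_level),
    polarity = as.integer(polarity),
    mode = mode,
    precursor_mz = as.numeric(precursor_mz),
    monitored_fragment_mz = as.numeric(monitored_fragment_mz),
    neutral_loss_delta = as.numeric(neutral_loss_delta),
    replicate = as.integer(replicate),
    virtual = isTRUE(virtual),
    peaks = list(peaks)
  )
}

#' Unnest a scan table into a long peak table
#'
#' @param scans a scan tibble.
#' @return A tibble with one row per peak plus the scan metadata.
#' @export
peaks_long <- function(scans) {
  scans |>
    dplyr::mutate(.scan = dplyr::row_number()) |>
    tidyr::unnest("peaks")
}
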