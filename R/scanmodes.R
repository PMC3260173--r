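#' Transpose precursor-ion scans into virtual MS/MS spectra
#'
#' Each precursor-ion scan records, along the precursor m/z axis, the signal
#' of one monitored fragment. The precursor axes of all scans are first
#' aligned with the same grouping rule used for MasterScan construction;
#' each aligned precursor mass then becomes a virtual MS/MS spectrum of the
#' form `[precursor mass]: [frag1, abundance], ..., [fragn, abundance]`,
#' whose fragment peaks sit at the nominal monitored m/z values with the
#' precursor's intensity in the corresponding scan. The result differs from
#' a DDA dataset only in carrying no survey spectra, so the usual MasterScan
#' and query machinery applies unchanged.
#'
#' One virtual scan is emitted per precursor cluster and (sample, replicate)
#' combination with signal; virtual scans are flagged so that fragment
#' matching uses the absolute unit-resolution tolerance instead of ppm.
#'
#' @param pis_scans scan tibble with `mode == "pis"`.
#' @param model [resolution_model()] for the precursor axis alignment.
#' @return A scan tibble of virtual full MS/MS scans (`virtual = TRUE`).
#' @export
transpose_pis <- function(pis_scans, model) {
  transpose_scanning(pis_scans, model, kind = "pis")
}

#' Transpose neutral-loss scans into virtual MS/MS spectra
#'
#' Like [transpose_pis()], but each scan monitors a fixed neutral mass
#' difference: the virtual fragment peak is placed at `precursor_mz - delta`
#' and annotated with the loss, so queries may match either the fragment
#' m/z or the loss itself.
#'
#' @param nls_scans scan tibble with `mode == "nls"`.
#' @inheritParams transpose_pis
#' @export
transpose_nls <- function(nls_scans, model) {
  transpose_scanning(nls_scans, model, kind = "nls")
}

transpose_scanning <- function(scans, model, kind) {
  if (nrow(scans) == 0) return(scan_tbl("none", 2, -1)[0, ])
  if (any(scans$mode != kind)) {
    stop("expected scans with mode '", kind, "'", call. = FALSE)
  }
  if (kind == "pis" && any(is.na(scans$monitored_fragment_mz))) {
    stop("PIS scan without monitored fragment m/z", call. = FALSE)
  }
  if (kind == "nls") {
    if (any(is.na(scans$neutral_loss_delta))) {
      stop("NLS scan without neutral-loss delta", call. = FALSE)
    }
    if (any(scans$neutral_loss_delta <= 0)) {
      stop("neutral-loss delta must be positive", call. = FALSE)
    }
  }
  if (dplyr::n_distinct(scans$polarity) != 1) {
    stop("cannot transpose scans of mixed polarity", call. = FALSE)
  }
  pk <- peaks_long(scans)
  if (nrow(pk) == 0) return(scan_tbl("none", 2, -1)[0, ])
  pk$cluster <- group_peaks(pk$mz, pk$intensity, pk$.scan, model)
  pre_mz <- tapply(seq_len(nrow(pk)), pk$cluster, function(i) {
    stats::weighted.mean(pk$mz[i], pk$intensity[i])
  })
  pk$precursor_mz <- as.numeric(pre_mz[as.character(pk$cluster)])
  pk$frag_mz <- if (kind == "pis") pk$monitored_fragment_mz else {
    pk$precursor_mz - pk$neutral_loss_delta
  }
  grp <- unname(split(seq_len(nrow(pk)),
                      paste(pk$sample_id, pk$replicate, pk$cluster, sep = "\r")))
  rows <- lapply(grp, function(i) {
    g <- pk[i, ]
    ord <- order(g$frag_mz)
    g <- g[ord, ]
    dup <- duplicated(g$frag_mz)
    peaks <- if (any(dup)) {
      tot <- rowsum(g$intensity, g$frag_mz)
      p <- tibble::tibble(mz = as.numeric(rownames(tot)),
                          intensity = as.vector(tot))
      if (kind == "nls") {
        p$delta <- lapply(split(g$neutral_loss_delta, g$frag_mz),
                          function(d) sort(unique(d)))
      }
      p
    } else {
      p <- tibble::tibble(mz = g$frag_mz, intensity = g$intensity)
      if (kind == "nls") p$delta <- as.list(g$neutral_loss_delta)
      p
    }
    list(sample_id = g$sample_id[1], replicate = g$replicate[1],
         polarity = g$polarity[1], precursor_mz = g$precursor_mz[1],
         scan_index = min(g$scan_index), peaks = peaks)
  })
  out <- tibble::tibble(
    sample_id = vapply(rows, `[[`, character(1), "sample_id"),
    scan_index = vapply(rows, `[[`, integer(1), "scan_index"),
    ms_level = 2L,
    polarity = vapply(rows, `[[`, integer(1), "polarity"),
    mode = "full",
    precursor_mz = vapply(rows, `[[`, numeric(1), "precursor_mz"),
    monitored_fragment_mz = NA_real_,
    neutral_loss_delta = NA_real_,
    replicate = vapply(rows, `[[`, integer(1), "replicate"),
    virtual = TRUE,
    peaks = lapply(rows, `[[`, "peaks")
  )
  out <- out[order(out$precursor_mz, out$sample_id), ]
  tibble::remove_rownames(out)
}
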