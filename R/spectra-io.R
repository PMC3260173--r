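#' Read a centroided mzXML file into a scan table
#'
#' One scan tibble row is produced per `<scan>` element, with ms level,
#' polarity, precursor m/z (when present) and decoded peak arrays mapped
#' onto the scan fields; all scans get `mode = "full"`. Only centroided
#' data are supported: profile spectra must be centroided upstream.
#'
#' @param path mzXML file.
#' @param sample_id sample identity to record (mzXML carries none); defaults
#'   to the file name without extension.
#' @return A scan tibble.
#' @export
read_mzxml <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzXML requires the mzR package", call. = FALSE)
  }
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) stop("malformed mzXML '", path, "': ",
                                              conditionMessage(e), call. = FALSE))
  on.exit(mzR::close(handle))
  hdr <- suppressWarnings(mzR::header(handle))
  if (nrow(hdr) == 0) stop("mzXML '", path, "' contains no scans", call. = FALSE)
  if (any(!is.na(hdr$centroided) & !hdr$centroided)) {
    bad <- hdr$seqNum[!is.na(hdr$centroided) & !hdr$centroided]
    stop("scan(s) ", paste(bad, collapse = ", "), " in '", path,
         "' are profile mode; centroid the data first", call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(hdr)), function(i) {
    pk <- suppressWarnings(mzR::peaks(handle, i))
    pk <- tibble::tibble(mz = as.numeric(pk[, 1]),
                         intensity = as.numeric(pk[, 2]))
    scan_tbl(sample_id,
             ms_level = hdr$msLevel[i],
             polarity = if (hdr$polarity[i] == 1) 1L else -1L,
             mode = "full",
             peaks = pk,
             precursor_mz = if (hdr$msLevel[i] > 1 && !is.na(hdr$precursorMZ[i]) &&
                                hdr$precursorMZ[i] > 0) hdr$precursorMZ[i] else NA_real_,
             scan_index = hdr$seqNum[i])
  })
}

#' Write a scan table to mzXML
#'
#' Emits centroided, uncompressed 32-bit network-order peak data (one
#' `<scan>` per row); the counterpart of [read_mzxml()], used by the
#' synthetic-data generator so the reader is exercised on generated files.
#'
#' @param scans scan tibble (mode `"full"` only).
#' @param path output file.
#' @export
write_mzxml <- function(scans, path) {
  if (any(scans$mode != "full")) {
    stop("write_mzxml() supports full scans only", call. = FALSE)
  }
  encode <- function(pk) {
    if (nrow(pk) == 0) return("")
    v <- as.numeric(rbind(pk$mz, pk$intensity))
    gsub("\n", "", jsonlite::base64_enc(writeBin(v, raw(), size = 4, endian = "big")),
         fixed = TRUE)
  }
  scan_el <- function(i) {
    s <- scans[i, ]
    pk <- s$peaks[[1]]
    pre <- if (!is.na(s$precursor_mz)) {
      sprintf('\n    <precursorMz precursorIntensity="0">%.9f</precursorMz>', s$precursor_mz)
    } else ""
    sprintf(paste0(
      '  <scan num="%d" msLevel="%d" peaksCount="%d" polarity="%s" centroided="1">%s\n',
      '    <peaks compressionType="none" compressedLen="0" precision="32" ',
      'byteOrder="network" contentType="m/z-int">%s</peaks>\n  </scan>'),
      i, s$ms_level, nrow(pk), if (s$polarity > 0) "+" else "-", pre, encode(pk))
  }
  body <- paste(vapply(seq_len(nrow(scans)), scan_el, character(1)), collapse = "\n")
  txt <- paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">\n',
    sprintf(' <msRun scanCount="%d">\n', nrow(scans)),
    body, "\n </msRun>\n</mzXML>\n")
  writeLines(txt, path)
  invisible(path)
}

#' Read a two-column peak list (.csv or .dta) as one scan
#'
#' The csv dialect sniffs comma or tab from the first line and skips an
#' optional single header line (detected by a non-numeric first field). The
#' dta dialect is whitespace-delimited with the conventional first line
#' `precursorMass charge`, recorded as the scan's precursor m/z.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"dta"`.
#' @param sample_id,ms_level,polarity,mode scan metadata to attach (the
#'   formats themselves carry none).
#' @param monitored_fragment_mz,neutral_loss_delta,precursor_mz,scan_index
#'   further metadata, per scan mode.
#' @return A one-row scan tibble.
#' @export
read_peaklist <- function(path, dialect = c("csv", "dta"), sample_id,
                          ms_level = 1, polarity = -1, mode = "full",
                          monitored_fragment_mz = NA_real_,
                          neutral_loss_delta = NA_real_,
                          precursor_mz = NA_real_, scan_index = 1L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  first_data <- 1L
  if (dialect == "csv") {
    sep <- if (grepl("\t", lines[1])) "\t" else ","
    split_line <- function(x) trimws(strsplit(x, sep, fixed = TRUE)[[1]])
    f1 <- split_line(lines[1])
    if (length(f1) >= 1 && is.na(suppressWarnings(as.numeric(f1[1])))) first_data <- 2L
  } else {
    split_line <- function(x) strsplit(trimws(x), "[ \t]+")[[1]]
    head_fields <- suppressWarnings(as.numeric(split_line(lines[1])))
    if (length(head_fields) == 2 && !anyNA(head_fields)) {
      precursor_mz <- head_fields[1]
      if (ms_level == 1) ms_level <- 2
      first_data <- 2L
    }
  }
  rows <- lines[seq.int(first_data, length.out = max(0, length(lines) - first_data + 1))]
  parsed <- lapply(seq_along(rows), function(i) {
    v <- suppressWarnings(as.numeric(split_line(rows[i])))
    if (length(v) < 2 || anyNA(v[1:2])) {
      stop("non-numeric peak row at line ", i + first_data - 1L, " of '", path, "'",
           call. = FALSE)
    }
    v[1:2]
  })
  pk <- if (length(parsed) == 0) {
    tibble::tibble(mz = numeric(), intensity = numeric())
  } else {
    m <- do.call(rbind, parsed)
    tibble::tibble(mz = m[, 1], intensity = m[, 2])
  }
  scan_tbl(sample_id, ms_level = ms_level, polarity = polarity, mode = mode,
           peaks = pk, precursor_mz = precursor_mz,
           monitored_fragment_mz = monitored_fragment_mz,
           neutral_loss_delta = neutral_loss_delta, scan_index = scan_index)
}

#' Write identification records to the results .csv
#'
#' One row per record: query name, species annotation, molecular species,
#' sum composition, m/z, mass error (ppm) and one intensity column per
#' sample. Rows are ordered by query, then precursor m/z — deterministic
#' for identical inputs.
#'
#' @param records identification record tibble from [run_queries()].
#' @param path output file.
#' @param samples sample order for the intensity columns; defaults to the
#'   union of samples seen in the records.
#' @export
write_results_csv <- function(records, path, samples = NULL) {
  if (is.null(samples)) {
    samples <- sort(unique(unlist(purrr::map(records$intensity, names))))
  }
  base <- records |>
    dplyr::select("query", "annotation", "molecular_species", "formula",
                  "precursor_mz", "error_ppm") |>
    dplyr::mutate(precursor_mz = round(.data$precursor_mz, 6),
                  error_ppm = round(.data$error_ppm, 3))
  for (s in samples) {
    base[[paste0("intensity_", s)]] <- purrr::map_dbl(
      records$intensity, ~ if (s %in% names(.x)) unname(.x[[s]]) else 0)
  }
  base <- dplyr::arrange(base, .data$query, .data$precursor_mz, .data$annotation)
  readr::write_csv(base, path)
  invisible(base)
}
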