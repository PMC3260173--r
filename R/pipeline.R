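#' Run the full interpretation pipeline
#'
#' import -> (transpose PIS/NLS) -> build MasterScan -> run queries ->
#' isotopic correction -> class normalization -> write results. Every stage
#' logs counts to stderr; any stage error aborts with a stage-labeled
#' message. Reruns with the same configuration produce byte-identical
#' output files.
#'
#' @param config experiment configuration: a YAML file path or an
#'   equivalent list. Keys: `files` (list of entries with `path`, `format`
#'   (`mzxml`/`csv`/`dta`), `sample_id`, `mode` (`full`/`pis`/`nls`),
#'   `ms_level`, `polarity`, and the mode-specific `monitored_fragment_mz`,
#'   `neutral_loss_delta` or `precursor_mz`), `settings` (any argument of
#'   [masterscan_settings()] in flat form: `r0`, `slope`, `m_ref`,
#'   `tol_ppm` or `tol_mz`, `virtual_tol`, `precursor_window`,
#'   `min_intensity`, `min_occupancy`, `occupancy_basis`) and `output`
#'   (`results`, `masterscan`, `profiles`).
#' @param mfql_paths character vector of `.mfql` query files.
#' @return Invisibly, a list with `records`, `profiles`, `masterscan`.
#' @export
run_pipeline <- function(config, mfql_paths) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (length(mfql_paths) < 1) stop("[queries] at least one query is required", call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  scans <- stage("import", {
    if (is.null(config$files) || length(config$files) == 0) {
      stop("config lists no input files")
    }
    purrr::map_dfr(seq_along(config$files), function(i) {
      f <- config$files[[i]]
      fmt <- f$format %||% tools::file_ext(f$path)
      if (tolower(fmt) == "mzxml") {
        read_mzxml(f$path, sample_id = f$sample_id)
      } else {
        read_peaklist(f$path, dialect = tolower(fmt),
                      sample_id = f$sample_id,
                      ms_level = f$ms_level %||% 1,
                      polarity = f$polarity %||% -1,
                      mode = f$mode %||% "full",
                      monitored_fragment_mz = f$monitored_fragment_mz %||% NA_real_,
                      neutral_loss_delta = f$neutral_loss_delta %||% NA_real_,
                      precursor_mz = f$precursor_mz %||% NA_real_,
                      scan_index = i)
      }
    })
  })
  message("[import] ", nrow(scans), " scans from ", length(config$files),
          " file(s), ", dplyr::n_distinct(scans$sample_id), " sample(s)")

  settings <- stage("settings", pipeline_settings(config$settings))

  scans <- stage("transpose", {
    full <- dplyr::filter(scans, .data$mode == "full")
    pis <- dplyr::filter(scans, .data$mode == "pis")
    nls <- dplyr::filter(scans, .data$mode == "nls")
    virt <- dplyr::bind_rows(
      if (nrow(pis) > 0) transpose_pis(pis, settings$ms1_model),
      if (nrow(nls) > 0) transpose_nls(nls, settings$ms1_model))
    if (nrow(pis) + nrow(nls) > 0) {
      message("[transpose] ", nrow(pis) + nrow(nls), " scanning spectra -> ",
              nrow(virt), " virtual MS/MS spectra")
    }
    dplyr::bind_rows(full, virt)
  })

  ms <- stage("masterscan", build_masterscan(scans, settings))
  message("[masterscan] ", nrow(ms$ms1), " precursor clusters (",
          sum(ms$ms1$virtual), " virtual), ", nrow(ms$ms2),
          " fragment clusters after thresholds")

  queries <- stage("queries", purrr::map(mfql_paths, read_mfql))
  records <- stage("identify", run_queries(queries, ms))
  message("[identify] ", nrow(records), " records from ", length(queries),
          " query(ies)")

  records <- stage("isotope-correction", isotopic_correction(records, ms))
  profiles <- stage("normalize", class_normalize(records))

  stage("report", {
    if (!is.null(config$output$results)) {
      write_results_csv(records, config$output$results, samples = ms$samples)
      message("[report] results written to ", config$output$results)
    }
    if (!is.null(config$output$profiles)) {
      readr::write_csv(
        dplyr::mutate(profiles, abundance = round(.data$abundance, 9)),
        config$output$profiles)
      message("[report] profiles written to ", config$output$profiles)
    }
    if (!is.null(config$output$masterscan)) {
      save_masterscan(ms, config$output$masterscan)
      message("[report] MasterScan saved to ", config$output$masterscan)
    }
  })
  invisible(list(records = records, profiles = profiles, masterscan = ms))
}

pipeline_settings <- function(s) {
  s <- s %||% list()
  res1 <- resolution_model(s$r0 %||% 7500, s$slope %||% 0, s$m_ref %||% 700)
  res2 <- resolution_model(s$ms2_r0 %||% s$r0 %||% 7500,
                           s$ms2_slope %||% s$slope %||% 0,
                           s$ms2_m_ref %||% s$m_ref %||% 700)
  tol <- if (!is.null(s$tol_mz)) {
    mass_tolerance(s$tol_mz, "mz")
  } else {
    mass_tolerance(s$tol_ppm %||% 10, "ppm")
  }
  masterscan_settings(
    ms1_model = res1, ms2_model = res2, tol = tol,
    virtual_tol = s$virtual_tol %||% 0.5,
    precursor_window = s$precursor_window %||% 0.5,
    min_intensity = s$min_intensity %||% 0,
    min_occupancy = s$min_occupancy %||% 0,
    occupancy_basis = s$occupancy_basis %||% "samples")
}
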