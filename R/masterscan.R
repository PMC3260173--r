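MASTERSCAN_FORMAT_VERSION <- "1.0"

#' Processing settings for MasterScan construction and querying
#'
#' @param ms1_model,ms2_model [resolution_model()]s driving the peak-grouping
#'   tolerance at MS and MS/MS level. Default: 7500 FWHM, flat.
#' @param tol identification [mass_tolerance()] used when matching
#'   compositions to measured cluster m/z.
#' @param virtual_tol absolute tolerance (Th) for fragments of virtual
#'   (transposed) MS/MS spectra, where the fragment axis holds nominal
#'   monitored values rather than measured masses.
#' @param precursor_window half-width (Th) of the precursor selection window
#'   used to group MS/MS scans and attach them to survey clusters. Default
#'   0.5 Th (unit-resolution selection).
#' @param min_intensity minimal intensity constraint: clusters whose maximal
#'   per-sample intensity falls below it are dropped.
#' @param min_occupancy occupancy threshold in `[0, 1]`: minimum fraction of
#'   acquisitions in which a peak must appear; 1 keeps only peaks observed in
#'   each and every spectrum.
#' @param occupancy_basis `"samples"` (default) counts samples with signal;
#'   `"scans"` counts individual scans.
#' @export
masterscan_settings <- function(ms1_model = resolution_model(7500, 0, 700),
                                ms2_model = resolution_model(7500, 0, 700),
                                tol = mass_tolerance(10, "ppm"),
                                virtual_tol = 0.5,
                                precursor_window = 0.5,
                                min_intensity = 0,
                                min_occupancy = 0,
                                occupancy_basis = c("samples", "scans")) {
  occupancy_basis <- match.arg(occupancy_basis)
  if (min_occupancy < 0 || min_occupancy > 1) {
    stop("min_occupancy must lie in [0, 1]", call. = FALSE)
  }
  structure(list(ms1_model = ms1_model, ms2_model = ms2_model, tol = tol,
                 virtual_tol = virtual_tol, precursor_window = precursor_window,
                 min_intensity = min_intensity, min_occupancy = min_occupancy,
                 occupancy_basis = occupancy_basis),
            class = "masterscan_settings")
}

#' Merge repeated scans into a representative spectrum
#'
#' Peaks (within and across the scans) falling within the resolution-model
#' tolerance of each other are grouped; each group becomes one peak with the
#' intensity-weighted mean m/z and, as intensity, the summed member intensity
#' divided by the number of scans in which the group appears (so the merged
#' intensity does not grow with the number of acquisitions). Idempotent on a
#' single scan.
#'
#' @param scans scan tibble rows sharing sample, level, mode and precursor
#'   metadata.
#' @param model a [resolution_model()].
#' @param precursor_tol allowed spread of `precursor_mz` among the scans.
#' @return A one-row scan tibble; its peaks carry an `n_scans` column (number
#'   of scans contributing to each merged peak).
#' @export
merge_scans <- function(scans, model, precursor_tol = 1e-9) {
  if (nrow(scans) == 0) stop("no scans to merge", call. = FALSE)
  same <- function(x) length(unique(x)) <= 1
  if (!same(scans$sample_id) || !same(scans$ms_level) || !same(scans$mode) ||
      !same(scans$polarity) ||
      !same(scans$monitored_fragment_mz[!is.na(scans$monitored_fragment_mz)]) ||
      !same(scans$neutral_loss_delta[!is.na(scans$neutral_loss_delta)])) {
    stop("merge_scans() requires scans with identical metadata", call. = FALSE)
  }
  pre <- scans$precursor_mz
  if (any(!is.na(pre)) && diff(range(pre)) > precursor_tol) {
    stop("merge_scans(): precursor m/z differs beyond tolerance", call. = FALSE)
  }
  out <- scans[1, ]
  out$scan_index <- min(scans$scan_index)
  out$precursor_mz <- if (all(is.na(pre))) NA_real_ else mean(pre)
  plist <- scans$peaks
  scan_of <- rep(seq_along(plist), vapply(plist, nrow, integer(1)))
  mz <- unlist(lapply(plist, `[[`, "mz"), use.names = FALSE)
  int <- unlist(lapply(plist, `[[`, "intensity"), use.names = FALSE)
  has_delta <- any(vapply(plist, function(p) "delta" %in% names(p), logical(1)))
  if (length(mz) == 0) {
    out$peaks <- list(tibble::tibble(mz = numeric(), intensity = numeric(),
                                     n_scans = integer()))
    return(out)
  }
  cl <- group_peaks(mz, int, scan_of, model)
  tot <- rowsum(int, cl)
  wmz <- rowsum(mz * int, cl) / tot
  nsc <- unname(vapply(split(scan_of, cl), function(s) length(unique(s)),
                       integer(1)))
  merged <- tibble::tibble(mz = as.vector(wmz), intensity = as.vector(tot) / nsc,
                           n_scans = nsc)
  if (has_delta) {
    dl <- do.call(c, lapply(plist, function(p) {
      if ("delta" %in% names(p)) p$delta else rep(list(NULL), nrow(p))
    }))
    merged$delta <- unname(lapply(split(dl, cl), function(d) sort(unique(unlist(d)))))
  }
  ord <- order(merged$mz)
  out$peaks <- list(merged[ord, ])
  out
}

#' Align representative spectra across samples into peak clusters
#'
#' Peaks from different samples within the grouping tolerance form one
#' cluster; the cluster mass is the single intensity-weighted average over
#' all member peaks while the per-sample intensities are preserved
#' unchanged. A sample contributes at most one peak per cluster (nearest in
#' m/z wins; a displaced peak seeds its own cluster).
#'
#' @param reps scan tibble of representative spectra, one row per sample.
#' @param model a [resolution_model()].
#' @param n_samples denominator for sample occupancy; defaults to the number
#'   of distinct samples in `reps`.
#' @param n_scans_total denominator for scan occupancy (when the basis is
#'   `"scans"`).
#' @param occupancy_basis `"samples"` or `"scans"`.
#' @return A cluster tibble: `mz`, `occupancy`, `n_members`, `intensity`
#'   (named per-sample list column) and `deltas`.
#' @export
align_across_samples <- function(reps, model, n_samples = NULL,
                                 n_scans_total = NULL,
                                 occupancy_basis = "samples") {
  if (nrow(reps) == 0) stop("no spectra to align", call. = FALSE)
  if (is.null(n_samples)) n_samples <- dplyr::n_distinct(reps$sample_id)
  plist <- reps$peaks
  owner <- rep(reps$sample_id, vapply(plist, nrow, integer(1)))
  mz <- unlist(lapply(plist, `[[`, "mz"), use.names = FALSE)
  int <- unlist(lapply(plist, `[[`, "intensity"), use.names = FALSE)
  nsc <- unlist(lapply(plist, function(p) {
    if ("n_scans" %in% names(p)) p$n_scans else rep(1L, nrow(p))
  }), use.names = FALSE)
  dl <- do.call(c, lapply(plist, function(p) {
    if ("delta" %in% names(p)) p$delta else rep(list(NULL), nrow(p))
  }))
  if (is.null(n_scans_total)) n_scans_total <- sum(vapply(
    split(nsc, owner), max, numeric(1)))
  if (length(mz) == 0) {
    return(tibble::tibble(mz = numeric(), occupancy = numeric(),
                          n_members = integer(), intensity = list(),
                          deltas = list()))
  }
  cl <- group_peaks(mz, int, owner, model, unique_owner = TRUE)
  idx <- unname(split(seq_along(cl), cl))
  out <- tibble::tibble(
    mz = vapply(idx, function(i) {
      if (length(i) == 1) mz[i] else stats::weighted.mean(mz[i], int[i])
    }, numeric(1)),
    occupancy = if (occupancy_basis == "scans") {
      vapply(idx, function(i) sum(nsc[i]), numeric(1)) / n_scans_total
    } else {
      vapply(idx, function(i) length(unique(owner[i][int[i] > 0])), numeric(1)) / n_samples
    },
    n_members = lengths(idx),
    intensity = lapply(idx, function(i) stats::setNames(int[i], owner[i])),
    deltas = lapply(idx, function(i) sort(unique(unlist(dl[i]))))
  )
  out <- out[order(out$mz), ]
  tibble::remove_rownames(out)
}

#' Apply minimal-intensity and occupancy constraints
#'
#' Drops clusters whose maximal per-sample intensity is below
#' `min_intensity` or whose occupancy is below `min_occupancy`. An occupancy
#' threshold of 1 keeps only peaks observed in every acquisition.
#'
#' @param clusters a cluster tibble from [align_across_samples()].
#' @param min_intensity,min_occupancy thresholds.
#' @export
apply_thresholds <- function(clusters, min_intensity = 0, min_occupancy = 0) {
  if (nrow(clusters) == 0) return(clusters)
  keep <- purrr::map_lgl(clusters$intensity, ~ max(.x, 0) >= min_intensity) &
    clusters$occupancy >= min_occupancy
  clusters[keep, ]
}

#' Build a MasterScan from a full dataset of scans
#'
#' Survey (MS1) scans are merged per sample and aligned across samples into
#' precursor clusters; MS/MS scans are grouped by precursor m/z within the
#' selection window, merged and aligned per group, and attached to the
#' nearest precursor cluster. MS/MS groups with no survey peak in reach (in
#' particular, whole datasets transposed from precursor-ion or neutral-loss
#' scans, which carry no survey spectra at all) get a flagged virtual
#' precursor cluster whose per-sample intensity is the summed fragment
#' signal. Intensity and occupancy constraints are applied at both levels.
#'
#' @param scans scan tibble (one polarity).
#' @param settings a [masterscan_settings()].
#' @return A `master_scan` object.
#' @export
build_masterscan <- function(scans, settings = masterscan_settings()) {
  if (nrow(scans) == 0) stop("build_masterscan(): no scans", call. = FALSE)
  if (dplyr::n_distinct(scans$polarity) != 1) {
    stop("build_masterscan(): dataset mixes polarities", call. = FALSE)
  }
  if (any(scans$mode != "full")) {
    stop("build_masterscan(): transpose PIS/NLS scans first (see transpose_pis/transpose_nls)",
         call. = FALSE)
  }
  samples <- sort(unique(scans$sample_id))
  n_samples <- length(samples)

  ms1_scans <- dplyr::filter(scans, .data$ms_level == 1)
  ms1 <- if (nrow(ms1_scans) > 0) {
    reps <- ms1_scans |>
      dplyr::group_split(.data$sample_id) |>
      purrr::map(merge_scans, model = settings$ms1_model) |>
      dplyr::bind_rows()
    align_across_samples(reps, settings$ms1_model, n_samples = n_samples,
                         n_scans_total = nrow(ms1_scans),
                         occupancy_basis = settings$occupancy_basis) |>
      apply_thresholds(settings$min_intensity, settings$min_occupancy)
  } else {
    tibble::tibble(mz = numeric(), occupancy = numeric(), n_members = integer(),
                   intensity = list(), deltas = list())
  }
  ms1$virtual <- rep(FALSE, nrow(ms1))

  ms2_scans <- dplyr::filter(scans, .data$ms_level == 2)
  ms2_out <- list()
  if (nrow(ms2_scans) > 0) {
    if (any(is.na(ms2_scans$precursor_mz))) {
      stop("MS/MS scan without precursor m/z", call. = FALSE)
    }
    # group scans whose precursor m/z fall within one selection window:
    # split the sorted precursor values at gaps larger than the window.
    # Virtual (transposed) scans carry precursor values that are already
    # aligned cluster masses, so they group by near-exact equality instead.
    ord <- order(ms2_scans$precursor_mz, ms2_scans$sample_id, ms2_scans$scan_index)
    ms2_scans <- ms2_scans[ord, ]
    window <- ifelse(ms2_scans$virtual, 1e-6, settings$precursor_window)
    gap <- if (nrow(ms2_scans) == 1) FALSE else {
      c(FALSE, diff(ms2_scans$precursor_mz) >
          pmin(window[-1], window[-length(window)]))
    }
    ms2_scans$.grp <- cumsum(gap)
    grp_idx <- unname(split(seq_len(nrow(ms2_scans)), ms2_scans$.grp))
    v_virtual <- ms2_scans$virtual
    v_sample <- ms2_scans$sample_id
    v_pre <- ms2_scans$precursor_mz
    v_peaks <- ms2_scans$peaks
    for (ii in grp_idx) {
      if (all(v_virtual[ii]) && !anyDuplicated(v_sample[ii])) {
        # transposed scans: one scan per sample and fragment positions are
        # exact nominal values, so clustering reduces to exact grouping
        pkl <- v_peaks[ii]
        owner <- rep(v_sample[ii], vapply(pkl, nrow, integer(1)))
        fmz <- unlist(lapply(pkl, `[[`, "mz"), use.names = FALSE)
        fint <- unlist(lapply(pkl, `[[`, "intensity"), use.names = FALSE)
        has_dl <- any(vapply(pkl, function(p) "delta" %in% names(p), logical(1)))
        fdl <- if (has_dl) do.call(c, lapply(pkl, function(p) {
          if ("delta" %in% names(p)) p$delta else rep(list(NULL), nrow(p))
        })) else NULL
        u <- sort(unique(round(fmz, 6)))
        key <- match(round(fmz, 6), u)
        idx <- unname(split(seq_along(key), key))
        frags <- tibble::new_tibble(list(
          mz = vapply(idx, function(i) {
            if (length(i) == 1) fmz[i] else stats::weighted.mean(fmz[i], fint[i])
          }, numeric(1)),
          occupancy = vapply(idx, function(i) {
            length(unique(owner[i][fint[i] > 0]))
          }, numeric(1)) / n_samples,
          n_members = lengths(idx),
          intensity = lapply(idx, function(i) stats::setNames(fint[i], owner[i])),
          deltas = lapply(idx, function(i) {
            if (has_dl) sort(unique(unlist(fdl[i]))) else NULL
          })), nrow = length(idx))
        frags <- apply_thresholds(frags, settings$min_intensity,
                                  settings$min_occupancy)
        if (nrow(frags) == 0) next
        ms2_out[[length(ms2_out) + 1]] <- list(
          ref_mz = v_pre[ii[1]], frags = frags, virtual = TRUE,
          samples_present = unique(v_sample[ii]))
        next
      }
      g <- ms2_scans[ii, ]
      sub <- split(seq_len(nrow(g)),
                   paste(g$sample_id, g$replicate, sep = "\r"))
      reps <- dplyr::bind_rows(lapply(sub, function(i) {
        if (length(i) == 1) {
          r <- g[i, ]
          if (!"n_scans" %in% names(r$peaks[[1]])) {
            r$peaks[[1]]$n_scans <- rep(1L, nrow(r$peaks[[1]]))
          }
          r
        } else {
          merge_scans(g[i, ], model = settings$ms2_model, precursor_tol = Inf)
        }
      }))
      frags <- align_across_samples(reps, settings$ms2_model,
                                    n_samples = n_samples,
                                    n_scans_total = nrow(g),
                                    occupancy_basis = settings$occupancy_basis) |>
        apply_thresholds(settings$min_intensity, settings$min_occupancy)
      if (nrow(frags) == 0) next
      ref_mz <- stats::weighted.mean(
        reps$precursor_mz,
        vapply(reps$peaks, function(p) sum(p$intensity) + 1e-12, numeric(1)))
      ms2_out[[length(ms2_out) + 1]] <- list(
        ref_mz = ref_mz, frags = frags, virtual = any(g$virtual),
        samples_present = unique(g$sample_id))
    }
  }

  # attach fragment groups to precursor clusters (or create virtual ones)
  n_real_ms1 <- nrow(ms1) # only survey clusters are attachment candidates
  virt_rows <- list()
  ms2_parts <- list()
  for (grp in ms2_out) {
    pid <- NA_integer_
    if (n_real_ms1 > 0) {
      d <- abs(ms1$mz[seq_len(n_real_ms1)] - grp$ref_mz)
      if (min(d) <= settings$precursor_window) pid <- which.min(d)
    }
    if (is.na(pid)) {
      all_int <- unlist(grp$frags$intensity)
      per_sample <- vapply(samples, function(s) {
        sum(all_int[names(all_int) == s])
      }, numeric(1))
      per_sample <- per_sample[per_sample > 0]
      # virtual precursors face the same constraints as survey clusters
      if (length(per_sample) / n_samples < settings$min_occupancy ||
          max(per_sample, 0) < settings$min_intensity) {
        next
      }
      virt_rows[[length(virt_rows) + 1]] <- tibble::tibble(
        mz = grp$ref_mz,
        occupancy = length(per_sample) / n_samples,
        n_members = length(per_sample),
        intensity = list(per_sample),
        deltas = list(NULL),
        virtual = TRUE)
      pid <- n_real_ms1 + length(virt_rows)
    }
    frags <- grp$frags
    frags$precursor_id <- pid
    ms2_parts[[length(ms2_parts) + 1]] <- frags
  }
  if (length(virt_rows) > 0) ms1 <- dplyr::bind_rows(ms1, virt_rows)
  ms2 <- if (length(ms2_parts) > 0) {
    dplyr::bind_rows(ms2_parts)
  } else {
    tibble::tibble(precursor_id = integer(), mz = numeric(),
                   occupancy = numeric(), n_members = integer(),
                   intensity = list(), deltas = list())
  }

  # canonical ordering: precursor clusters by m/z, fragments by (precursor, m/z)
  ord <- order(ms1$mz)
  remap <- match(seq_len(nrow(ms1)), ord)
  ms1 <- ms1[ord, ]
  ms1$cluster_id <- seq_len(nrow(ms1))
  if (nrow(ms2) > 0) {
    ms2$precursor_id <- remap[ms2$precursor_id]
    ms2 <- dplyr::arrange(ms2, .data$precursor_id, .data$mz)
    ms2$cluster_id <- seq_len(nrow(ms2))
  } else {
    ms2$cluster_id <- integer(0)
  }
  cols1 <- c("cluster_id", "mz", "occupancy", "n_members", "virtual",
             "intensity", "deltas")
  cols2 <- c("precursor_id", "cluster_id", "mz", "occupancy", "n_members",
             "intensity", "deltas")
  structure(list(version = MASTERSCAN_FORMAT_VERSION,
                 polarity = scans$polarity[1],
                 samples = samples,
                 settings = settings,
                 ms1 = ms1[, cols1],
                 ms2 = ms2[, cols2]),
            class = "master_scan")
}

#' @export
print.master_scan <- function(x, ...) {
  cat("<master_scan> v", x$version, ", polarity ", sprintf("%+d", x$polarity),
      ", ", length(x$samples), " sample(s)\n", sep = "")
  cat("  precursor clusters: ", nrow(x$ms1),
      " (", sum(x$ms1$virtual), " virtual)\n", sep = "")
  cat("  fragment clusters:  ", nrow(x$ms2), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Long view of a MasterScan
#'
#' @param x a `master_scan`.
#' @param ... unused.
#' @return A tibble with one row per (cluster, sample) intensity.
#' @method tidy master_scan
#' @export
tidy.master_scan <- function(x, ...) {
  lvl <- function(tb, level) {
    if (nrow(tb) == 0) {
      return(tibble::tibble(level = character(), cluster_id = integer(),
                            precursor_id = integer(), mz = numeric(),
                            occupancy = numeric(), sample_id = character(),
                            intensity = numeric()))
    }
    tb |>
      dplyr::mutate(level = level,
                    precursor_id = if ("precursor_id" %in% names(tb)) {
                      .data$precursor_id
                    } else NA_integer_) |>
      dplyr::select("level", "cluster_id", "precursor_id", "mz", "occupancy",
                    "intensity") |>
      dplyr::mutate(intensity = purrr::map(.data$intensity, ~ tibble::tibble(
        sample_id = names(.x), intensity = unname(.x)))) |>
      tidyr::unnest("intensity")
  }
  dplyr::bind_rows(lvl(x$ms1, "ms1"), lvl(x$ms2, "ms2"))
}

#' One-row summary of a MasterScan
#' @inheritParams tidy.master_scan
#' @method glance master_scan
#' @export
glance.master_scan <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$samples),
    n_precursor_clusters = nrow(x$ms1),
    n_virtual_precursors = sum(x$ms1$virtual),
    n_fragment_clusters = nrow(x$ms2),
    polarity = x$polarity
  )
}

#' Plot the precursor-level content of a MasterScan
#'
#' @param object a `master_scan`.
#' @param ... unused.
#' @return A ggplot: summed precursor intensity vs m/z.
#' @method autoplot master_scan
#' @export
autoplot.master_scan <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$level == "ms1") |>
    dplyr::group_by(.data$mz) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
    ggplot2::labs(x = "m/z (Th)", y = "summed intensity",
                  title = "MasterScan precursor clusters") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

settings_to_list <- function(s) {
  list(ms1_model = unclass(s$ms1_model), ms2_model = unclass(s$ms2_model),
       tol = unclass(s$tol), virtual_tol = s$virtual_tol,
       precursor_window = s$precursor_window, min_intensity = s$min_intensity,
       min_occupancy = s$min_occupancy, occupancy_basis = s$occupancy_basis)
}

settings_from_list <- function(l) {
  masterscan_settings(
    ms1_model = do.call(resolution_model, l$ms1_model),
    ms2_model = do.call(resolution_model, l$ms2_model),
    tol = mass_tolerance(l$tol$value, l$tol$unit),
    virtual_tol = l$virtual_tol, precursor_window = l$precursor_window,
    min_intensity = l$min_intensity, min_occupancy = l$min_occupancy,
    occupancy_basis = l$occupancy_basis)
}

clusters_to_list <- function(tb) {
  purrr::map(seq_len(nrow(tb)), function(i) {
    r <- as.list(tb[i, setdiff(names(tb), c("intensity", "deltas"))])
    r$intensity <- as.list(tb$intensity[[i]])
    r$deltas <- tb$deltas[[i]]
    r
  })
}

clusters_from_list <- function(l, cols) {
  if (length(l) == 0) {
    tb <- tibble::tibble(cluster_id = integer(), mz = numeric(),
                         occupancy = numeric(), n_members = integer(),
                         virtual = logical(), precursor_id = integer(),
                         intensity = list(), deltas = list())
    return(tb[, cols])
  }
  tb <- purrr::map_dfr(l, function(r) {
    row <- tibble::as_tibble(r[setdiff(names(r), c("intensity", "deltas"))])
    row$intensity <- list(unlist(r$intensity))
    row$deltas <- list(if (length(r$deltas)) as.numeric(unlist(r$deltas)) else NULL)
    row
  })
  tb[, cols]
}

#' Persist and restore a MasterScan
#'
#' The on-disk container is versioned JSON holding the settings, the
#' aligned clusters with their per-sample intensities, and the mode
#' metadata; the round trip is lossless. Loading refuses files whose format
#' version does not match.
#'
#' @param ms a `master_scan`.
#' @param path file path.
#' @export
save_masterscan <- function(ms, path) {
  stopifnot(inherits(ms, "master_scan"))
  obj <- list(version = ms$version, polarity = ms$polarity,
              samples = as.list(ms$samples),
              settings = settings_to_list(ms$settings),
              ms1 = clusters_to_list(ms$ms1),
              ms2 = clusters_to_list(ms$ms2))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_masterscan
#' @export
load_masterscan <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot read MasterScan file '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  if (is.null(obj$version)) stop("not a MasterScan file (no version field)", call. = FALSE)
  if (!identical(obj$version, MASTERSCAN_FORMAT_VERSION)) {
    stop("MasterScan format version ", obj$version,
         " is not supported (this build reads version ",
         MASTERSCAN_FORMAT_VERSION, ")", call. = FALSE)
  }
  structure(list(version = obj$version,
                 polarity = as.integer(obj$polarity),
                 samples = as.character(unlist(obj$samples)),
                 settings = settings_from_list(obj$settings),
                 ms1 = clusters_from_list(obj$ms1, c("cluster_id", "mz", "occupancy",
                                                     "n_members", "virtual",
                                                     "intensity", "deltas")),
                 ms2 = clusters_from_list(obj$ms2, c("precursor_id", "cluster_id",
                                                     "mz", "occupancy", "n_members",
                                                     "intensity", "deltas"))),
            class = "master_scan")
}
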