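#' Isotopic correction of precursor and fragment intensities
#'
#' Within each lipid class, records are processed in order of ascending
#' precursor m/z. For every record, the predicted isotopologue intensities
#' (the isotope pattern of its assigned composition scaled by its M+0
#' intensity) are subtracted from any heavier record of the same class
#' whose precursor m/z sits at an isotopologue position within the MS1
#' tolerance — the classic case being the M+2 peak overlapping the species
#' with one double bond fewer. Corrected intensities are clipped at zero
#' and flagged. Fragment intensities are corrected analogously with the
#' fragment composition's own pattern.
#'
#' @param records identification-record tibble from [run_queries()].
#' @param ms the `master_scan` the records came from (supplies tolerances).
#' @param n_isotopologues how many isotopologues to predict per species.
#' @param neutron_spacing mass per isotopologue step in Da (13C dominant).
#' @return `records` with corrected `intensity`/`fragments` columns plus a
#'   logical `isotope_clipped` column.
#' @export
isotopic_correction <- function(records, ms, n_isotopologues = 4,
                                neutron_spacing = 1.00336) {
  if (nrow(records) == 0) return(records)
  no_comp <- purrr::map_lgl(records$composition, is.null)
  if (any(no_comp)) {
    warning(sum(no_comp), " record(s) without an assigned composition passed",
            " through uncorrected", call. = FALSE)
  }
  records$isotope_clipped <- FALSE
  tol <- ms$settings$tol
  for (cl in unique(records$class)) {
    ix <- which(records$class == cl & !no_comp)
    # one precursor cluster is one measured peak, whatever the number of
    # records bound to it: correct per cluster (best-ranked composition),
    # then propagate to every record of that cluster
    cluster_groups <- split(ix, records$precursor_id[ix])
    reps <- vapply(cluster_groups, `[[`, integer(1), 1)
    reps <- reps[order(records$precursor_mz[reps])]
    for (i in reps) {
      pat <- isotope_pattern(records$composition[[i]], n_isotopologues)$abundance
      for (j in reps) {
        if (records$precursor_mz[j] <= records$precursor_mz[i]) next
        k <- round((records$precursor_mz[j] - records$precursor_mz[i]) / neutron_spacing)
        if (k < 1 || k > n_isotopologues - 1) next
        expected <- records$precursor_mz[i] + k * neutron_spacing
        if (abs(records$precursor_mz[j] - expected) >
            tolerance_width(tol, records$precursor_mz[j])) next
        corr <- records$intensity[[i]] * pat[k + 1] / pat[1]
        new_int <- records$intensity[[j]] - corr[names(records$intensity[[j]])]
        if (any(new_int < 0)) records$isotope_clipped[j] <- TRUE
        records$intensity[[j]] <- pmax(new_int, 0)
      }
    }
    for (grp in cluster_groups) {
      rep_i <- grp[1]
      for (j in grp[-1]) {
        records$intensity[[j]] <- records$intensity[[rep_i]]
        records$isotope_clipped[j] <- records$isotope_clipped[rep_i]
      }
    }
    # fragment-level correction with the fragment's own composition; one
    # fragment cluster is likewise corrected once per composition
    frag_pool <- purrr::map_dfr(ix, function(i) {
      fr <- records$fragments[[i]]
      if (is.null(fr) || nrow(fr) == 0) return(NULL)
      dplyr::mutate(fr, .rec = i, .row = dplyr::row_number())
    })
    if (nrow(frag_pool) == 0) next
    fkey <- paste(frag_pool$cluster_id, frag_pool$formula)
    fgroups <- split(seq_len(nrow(frag_pool)), fkey)
    frep <- vapply(fgroups, `[[`, integer(1), 1)
    frep <- frep[order(frag_pool$mz[frep])]
    for (a in frep) {
      pat <- isotope_pattern(frag_pool$composition[[a]], n_isotopologues)$abundance
      for (b in frep) {
        if (frag_pool$mz[b] <= frag_pool$mz[a]) next
        k <- round((frag_pool$mz[b] - frag_pool$mz[a]) / neutron_spacing)
        if (k < 1 || k > n_isotopologues - 1) next
        if (abs(frag_pool$mz[b] - frag_pool$mz[a] - k * neutron_spacing) >
            tolerance_width(tol, frag_pool$mz[b])) next
        src <- frag_pool$intensity[[a]]
        corr <- src * pat[k + 1] / pat[1]
        old <- frag_pool$intensity[[b]]
        frag_pool$intensity[[b]] <- pmax(old - corr[names(old)], 0)
      }
    }
    for (g in seq_along(fgroups)) {
      newv <- frag_pool$intensity[[frep[[names(fgroups)[g]]]]]
      for (m in fgroups[[g]]) {
        records$fragments[[frag_pool$.rec[m]]]$intensity[[frag_pool$.row[m]]] <- newv
      }
    }
  }
  records
}

#' Class-normalized lipid profiles
#'
#' Per sample and lipid class, species intensities are divided by the class
#' total, giving relative abundances that sum to one. Records that collide
#' on the same sum annotation (isobaric species of one class, or the same
#' species reported as several molecular species) are combined by
#' summation before normalizing.
#'
#' @param records identification-record tibble.
#' @return A `lipid_profiles` tibble: `class`, `species`, `sample_id`,
#'   `intensity`, `abundance`.
#' @export
class_normalize <- function(records) {
  if (nrow(records) == 0) {
    return(structure(tibble::tibble(class = character(), species = character(),
                                    sample_id = character(), intensity = numeric(),
                                    abundance = numeric()),
                     class = c("lipid_profiles", class(tibble::tibble()))))
  }
  # records sharing one precursor cluster (isobaric molecular species of a
  # class, or several compositions matched to one cluster under the same
  # annotation) describe a single measured intensity: count it once, then
  # combine across distinct clusters that collide on the annotation
  long <- records |>
    dplyr::distinct(.data$class, .data$annotation, .data$precursor_id,
                    .keep_all = TRUE) |>
    dplyr::select("class", species = "annotation", "intensity") |>
    dplyr::mutate(intensity = purrr::map(.data$intensity, ~ tibble::tibble(
      sample_id = names(.x), intensity = unname(.x)))) |>
    tidyr::unnest("intensity") |>
    dplyr::group_by(.data$class, .data$species, .data$sample_id) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
  out <- long |>
    dplyr::group_by(.data$class, .data$sample_id) |>
    dplyr::mutate(abundance = if (sum(.data$intensity) > 0) {
      .data$intensity / sum(.data$intensity)
    } else NA_real_) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$class, .data$species, .data$sample_id)
  if (anyNA(out$abundance)) {
    warning("class total is zero for some sample(s); abundances set to NA",
            call. = FALSE)
  }
  structure(out, class = c("lipid_profiles", class(out)))
}

#' Concordance of two class profiles
#'
#' Mirrors the cross-platform comparison of relative species abundances:
#' per class, mean abundances per species (over samples) are matched by
#' annotation and the second profile is regressed on the first by ordinary
#' least squares with a free intercept.
#'
#' @param a,b `lipid_profiles` tibbles (e.g. from two acquisition modes).
#' @return A tibble per shared class: `class`, `n_shared`, `r_squared`,
#'   `slope`.
#' @export
profile_concordance <- function(a, b) {
  mean_prof <- function(p) {
    p |>
      dplyr::group_by(.data$class, .data$species) |>
      dplyr::summarise(abundance = mean(.data$abundance, na.rm = TRUE),
                       .groups = "drop")
  }
  joined <- dplyr::inner_join(mean_prof(a), mean_prof(b),
                              by = c("class", "species"),
                              suffix = c("_a", "_b"))
  if (nrow(joined) == 0) stop("profiles share no species", call. = FALSE)
  out <- joined |>
    dplyr::group_by(.data$class) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < 2) {
        stop("fewer than 2 shared species for class ", key$class, call. = FALSE)
      }
      fit <- stats::lm(abundance_b ~ abundance_a, data = g)
      tibble::tibble(class = key$class, n_shared = nrow(g),
                     r_squared = stats::cor(g$abundance_a, g$abundance_b)^2,
                     slope = unname(stats::coef(fit)[2]))
    }) |>
    dplyr::bind_rows()
  out
}

#' Plot class-normalized lipid profiles
#'
#' @param object a `lipid_profiles` tibble.
#' @param ... unused.
#' @return A ggplot: mean relative abundance per species, faceted by class,
#'   with per-sample points.
#' @method autoplot lipid_profiles
#' @export
autoplot.lipid_profiles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$species, y = .data$abundance)) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey70") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::facet_wrap(~class, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "relative abundance (class-normalized)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
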