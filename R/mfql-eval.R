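# Query evaluation over a MasterScan: for every precursor cluster, candidate
# compositions are enumerated per DEFINE constraint; fragment variables draw
# their candidates from the fragment clusters attached to that precursor;
# every assignment satisfying SUCHTHAT yields one identification record.

#' Evaluate one query against a MasterScan
#'
#' @param q an [parse_mfql()] query.
#' @param ms a `master_scan`.
#' @return An identification-record tibble: one row per satisfying variable
#'   assignment, with the species annotation (class plus total carbons and
#'   double bonds; the molecular species when both fatty acid moieties are
#'   resolved), the precursor composition, mass error, per-sample
#'   intensities and the bound fragments.
#' @export
evaluate_query <- function(q, ms) {
  stopifnot(inherits(q, "mfql_query"), inherits(ms, "master_scan"))
  if (q$polarity != ms$polarity) {
    stop("query '", q$name, "' addresses polarity ", sprintf("%+d", q$polarity),
         " but the MasterScan holds polarity ", sprintf("%+d", ms$polarity),
         call. = FALSE)
  }
  tol <- q$tolerance %||% ms$settings$tol
  vtol <- mass_tolerance(ms$settings$virtual_tol, "mz")
  frag_vars <- purrr::map_chr(
    purrr::keep(q$identify, ~ grepl("^MS2", .x$context)), "variable")
  if (length(frag_vars) > 0 && nrow(ms$ms2) == 0) {
    warning("query '", q$name,
            "' identifies fragments but the MasterScan has no MS/MS clusters",
            call. = FALSE)
    return(empty_records())
  }

  # the enumeration grid of a constraint box is mz-independent: build it once
  # per constraint, then matching a cluster is a vectorized filter
  grid_cache <- new.env(parent = emptyenv())
  constraint_grid <- function(constraint) {
    key <- format(constraint)
    if (exists(key, envir = grid_cache, inherits = FALSE)) {
      return(grid_cache[[key]])
    }
    g <- expand.grid(purrr::map(constraint$elements, ~ seq(.x[1], .x[2])))
    names(g) <- names(constraint$elements)
    mass <- as.vector(as.matrix(g) %*%
                        .element_masses[names(g)])
    chg <- constraint$charge
    cand_mz <- if (chg == 0) mass else (mass - chg * ELECTRON_MASS) / abs(chg)
    nC <- if ("C" %in% names(g)) g$C else 0
    nH <- if ("H" %in% names(g)) g$H else 0
    nN <- if ("N" %in% names(g)) g$N else 0
    nP <- if ("P" %in% names(g)) g$P else 0
    dbe <- nC + 1 - nH / 2 + (nN + nP) / 2
    in_dbr <- dbe >= constraint$dbr[1] & dbe <= constraint$dbr[2]
    out <- list(grid = g[in_dbr, , drop = FALSE], mz = cand_mz[in_dbr],
                dbe = dbe[in_dbr])
    grid_cache[[key]] <- out
    out
  }
  empty_hits <- tibble::tibble(formula = character(), exact_mz = numeric(),
                               error_ppm = numeric(), dbe = numeric(),
                               composition = list())
  enum <- function(mz, constraint, tolerance) {
    cg <- constraint_grid(constraint)
    keep <- which(abs(cg$mz - mz) <= tolerance_width(tolerance, mz))
    if (length(keep) == 0) return(empty_hits)
    comps <- lapply(keep, function(i) {
      do.call(composition, as.list(cg$grid[i, , drop = FALSE]))
    })
    err <- (mz - cg$mz[keep]) / cg$mz[keep] * 1e6
    ord <- order(abs(err), vapply(comps, format, character(1)))
    tibble::new_tibble(list(
      formula = vapply(comps, format, character(1))[ord],
      exact_mz = cg$mz[keep][ord],
      error_ppm = err[ord],
      dbe = cg$dbe[keep][ord],
      composition = comps[ord]), nrow = length(keep))
  }

  # signature of a constraint, to collapse swapped assignments of
  # interchangeable fragment variables
  sig <- purrr::map_chr(q$defines, format)

  records <- list()
  frag_split <- split(seq_len(nrow(ms$ms2)), ms$ms2$precursor_id)
  for (pi in seq_len(nrow(ms$ms1))) {
    pcand <- enum(ms$ms1$mz[pi], q$defines[[q$ms1_variable]], tol)
    if (nrow(pcand) == 0) next
    p <- list(cluster_id = ms$ms1$cluster_id[pi], mz = ms$ms1$mz[pi],
              virtual = ms$ms1$virtual[pi], intensity = ms$ms1$intensity[pi])
    fidx <- frag_split[[as.character(p$cluster_id)]]
    frags <- ms$ms2[fidx %||% integer(0), , drop = FALSE]
    if (length(frag_vars) > 0 && nrow(frags) == 0) next

    # candidate (cluster, composition) pairs per fragment variable
    fcands <- purrr::map(frag_vars, function(v) {
      ftol <- if (p$virtual) vtol else tol
      purrr::map_dfr(seq_len(nrow(frags)), function(fi) {
        hits <- enum(frags$mz[fi], q$defines[[v]], ftol)
        if (nrow(hits) == 0) return(NULL)
        dplyr::mutate(hits, frag_row = fi)
      })
    })
    names(fcands) <- frag_vars
    if (any(purrr::map_int(fcands, nrow) == 0) && length(frag_vars) > 0) next

    idx <- if (length(frag_vars) == 0) {
      expand.grid(p = seq_len(nrow(pcand)))
    } else {
      do.call(expand.grid,
              c(list(p = seq_len(nrow(pcand))),
                purrr::map(fcands, ~ seq_len(nrow(.x)))))
    }
    seen <- character(0)
    for (ai in seq_len(nrow(idx))) {
      pc <- pcand[idx$p[ai], ]
      binding <- list()
      binding[[q$ms1_variable]] <- list(
        chemsc = pc$composition[[1]], mass = p$mz,
        intensity = full_intensity(p$intensity[[1]], ms$samples),
        errppm = pc$error_ppm, virtual = p$virtual)
      ok <- TRUE
      for (v in frag_vars) {
        fc <- fcands[[v]][idx[[v]][ai], ]
        fr <- frags[fc$frag_row, ]
        binding[[v]] <- list(
          chemsc = fc$composition[[1]], mass = fr$mz,
          intensity = full_intensity(fr$intensity[[1]], ms$samples),
          errppm = if (p$virtual) NA_real_ else fc$error_ppm,
          cluster_id = fr$cluster_id)
      }
      if (!is.null(q$suchthat)) {
        ok <- isTRUE(eval_expr(q$suchthat, binding))
      }
      if (!ok) next
      key <- assignment_key(q, binding, sig)
      if (key %in% seen) next
      seen <- c(seen, key)
      records[[length(records) + 1]] <- make_record(q, ms, p, pc, binding, frag_vars)
    }
  }
  if (length(records) == 0) return(empty_records())
  out <- dplyr::bind_rows(records)
  dplyr::arrange(out, .data$precursor_mz, abs(.data$error_ppm), .data$formula)
}

#' Run several queries and collect one results table
#'
#' Results are concatenated per query (queries are independent: the same
#' query run twice reports twice) and ordered by query, then precursor m/z.
#'
#' @param queries list of `mfql_query` objects (or paths to `.mfql` files).
#' @param ms a `master_scan`.
#' @export
run_queries <- function(queries, ms) {
  if (length(queries) == 0) return(empty_records())
  queries <- purrr::map(queries, function(q) {
    if (is.character(q)) read_mfql(q) else q
  })
  out <- purrr::map_dfr(queries, evaluate_query, ms = ms)
  if (nrow(out) == 0) return(empty_records())
  out$query <- factor(out$query, levels = unique(purrr::map_chr(queries, "name")))
  out <- dplyr::arrange(out, .data$query, .data$precursor_mz, abs(.data$error_ppm))
  out$query <- as.character(out$query)
  out
}

empty_records <- function() {
  tibble::tibble(query = character(), class = character(),
                 annotation = character(), molecular_species = character(),
                 formula = character(), precursor_id = integer(),
                 precursor_mz = numeric(), error_ppm = numeric(),
                 composition = list(), intensity = list(), fragments = list(),
                 report = list())
}

full_intensity <- function(x, samples) {
  out <- stats::setNames(rep(0, length(samples)), samples)
  out[names(x)] <- x
  out
}

assignment_key <- function(q, binding, sig) {
  parts <- purrr::imap_chr(binding, function(b, v) {
    cl <- if (!is.null(b$cluster_id)) b$cluster_id else 0L
    paste0(sig[[v]] %||% "PR", "@", cl, ":", format(b$chemsc))
  })
  paste(sort(parts), collapse = "|")
}

make_record <- function(q, ms, p, pc, binding, frag_vars) {
  acyls <- purrr::compact(purrr::map(frag_vars, function(v) {
    a <- acyl_from_composition(binding[[v]]$chemsc)
    if (is.null(a)) NULL else c(a, list(variable = v))
  }))
  if (length(acyls) >= 2) {
    ord <- order(purrr::map_dbl(acyls, "chain"), purrr::map_dbl(acyls, "db"))
    acyls <- acyls[ord]
    annotation <- sprintf("%s %d:%d", q$name,
                          as.integer(sum(purrr::map_dbl(acyls, "chain"))),
                          as.integer(sum(purrr::map_dbl(acyls, "db"))))
    molecular <- paste0(q$name, " ", paste(
      purrr::map_chr(acyls, ~ sprintf("%d:%d", .x$chain, .x$db)),
      collapse = "/"))
  } else {
    annotation <- annotate_precursor(q$name, binding[[q$ms1_variable]]$chemsc,
                                     q$polarity)
    molecular <- NA_character_
  }
  frag_tb <- purrr::map_dfr(frag_vars, function(v) {
    b <- binding[[v]]
    tibble::tibble(variable = v, cluster_id = b$cluster_id,
                   mz = b$mass, formula = format(b$chemsc),
                   error_ppm = b$errppm, intensity = list(b$intensity),
                   composition = list(b$chemsc))
  })
  report <- purrr::map(q$report, eval_expr, binding = binding)
  tibble::tibble(
    query = q$name, class = q$name,
    annotation = annotation, molecular_species = molecular,
    formula = pc$formula,
    precursor_id = p$cluster_id, precursor_mz = p$mz,
    error_ppm = pc$error_ppm,
    composition = list(pc$composition[[1]]),
    intensity = list(binding[[q$ms1_variable]]$intensity),
    fragments = list(frag_tb),
    report = list(report))
}

eval_expr <- function(e, binding) {
  switch(e$type,
    num = e$v,
    comp = e$v,
    var = {
      b <- binding[[e$var]]
      if (is.null(b)) stop("unbound variable ", e$var, call. = FALSE)
      b[[e$attr]]
    },
    "not" = !isTRUE(eval_expr(e$e, binding)),
    "in" = {
      v <- eval_expr(e$e, binding)
      any(purrr::map_lgl(e$set, ~ isTRUE(v == .x)))
    },
    bin = {
      l <- eval_expr(e$l, binding)
      r <- eval_expr(e$r, binding)
      switch(e$op,
        "AND" = isTRUE(l) && isTRUE(r),
        "OR" = isTRUE(l) || isTRUE(r),
        "==" = if (inherits(l, "composition") || inherits(r, "composition")) {
          isTRUE(l == r)
        } else l == r,
        "!=" = if (inherits(l, "composition") || inherits(r, "composition")) {
          !isTRUE(l == r)
        } else l != r,
        "+" = l + r, "-" = l - r, "*" = l * r, "/" = l / r,
        "<" = l < r, ">" = l > r, "<=" = l <= r, ">=" = l >= r,
        stop("unknown operator ", e$op, call. = FALSE))
    },
    stop("unknown expression node ", e$type, call. = FALSE))
}
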