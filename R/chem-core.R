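#' Monoisotopic mass of a composition
#'
#' @param c an object coercible with [as_composition()].
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(c) {
  c <- as_composition(c)
  if (length(c) == 0) return(0)
  sum(.element_masses[names(c)] * unclass(c))
}

#' m/z of an ion
#'
#' The composition must be the full atomic composition of the ion (protons
#' already added or removed); the electron mass is accounted for.
#'
#' @param c ion composition.
#' @param charge signed integer charge, nonzero.
#' @return m/z in Th.
#' @examples
#' ion_mz("C16H31O2", -1) # 16:0 acyl anion, 255.233
#' @export
ion_mz <- function(c, charge) {
  if (length(charge) != 1 || charge == 0 || charge != round(charge)) {
    stop("charge must be a nonzero integer; use monoisotopic_mass() for neutrals",
         call. = FALSE)
  }
  (monoisotopic_mass(c) - charge * ELECTRON_MASS) / abs(charge)
}

#' Double-bond equivalents of a composition
#'
#' DBE = C + 1 - H/2 + (N + P)/2, treating nitrogen and phosphorus as
#' trivalent. Ionic compositions give half-integral values: e.g. a saturated
#' acyl anion CnH(2n-1)O2 has DBE 1.5.
#'
#' @inheritParams monoisotopic_mass
#' @return DBE (may be half-integral).
#' @examples
#' double_bond_equivalents("C16H31O2") # 1.5
#' @export
double_bond_equivalents <- function(c) {
  c <- as_composition(c)
  element_count(c, "C") + 1 - element_count(c, "H") / 2 +
    (element_count(c, "N") + element_count(c, "P")) / 2
}

#' Sum-composition constraints
#'
#' A constraint fixes a closed integer range per element, a double-bond
#' equivalent range, and a charge; it is the payload of an MFQL DEFINE
#' clause. `parse_constraint()` reads the shared textual syntax,
#' e.g. `"C[30..50] H[40..100] N[1..1] O[8..8] P[1..1]"`; an exact formula
#' (`"C5 H11 O4 N1 P1"`) is a degenerate box. Charge 0 denotes a neutral
#' fragment or loss.
#'
#' @param ... per-element ranges as length-2 vectors (or single counts),
#'   e.g. `C = c(30, 50), O = 8`.
#' @param dbr length-2 numeric, allowed DBE interval.
#' @param charge signed integer.
#' @return An object of class `sum_constraint`.
#' @examples
#' sum_constraint(C = c(10, 20), H = c(20, 40), O = 2, dbr = c(1.5, 7.5), charge = -1)
#' @export
sum_constraint <- function(..., dbr = c(-Inf, Inf), charge = -1L) {
  ranges <- list(...)
  if (length(ranges) == 0) stop("constraint needs at least one element range", call. = FALSE)
  unknown <- setdiff(names(ranges), .element_symbols)
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  ranges <- lapply(ranges, function(r) {
    if (length(r) == 1) r <- c(r, r)
    if (length(r) != 2 || any(!is.finite(r))) stop("element range must be finite", call. = FALSE)
    if (r[1] > r[2]) stop("element range has min > max", call. = FALSE)
    if (any(r < 0)) stop("element range must be non-negative", call. = FALSE)
    as.integer(r)
  })
  if (length(dbr) != 2 || dbr[1] > dbr[2]) stop("invalid DBR interval", call. = FALSE)
  structure(list(elements = ranges, dbr = as.numeric(dbr), charge = as.integer(charge)),
            class = "sum_constraint")
}

#' @rdname sum_constraint
#' @param text constraint text in the shared syntax.
#' @export
parse_constraint <- function(text, dbr = c(-Inf, Inf), charge = -1L) {
  s <- trimws(text)
  if (grepl("\\[", s)) {
    toks <- regmatches(s, gregexpr("[A-Z][a-z]?\\[[0-9]+\\.\\.[0-9]+\\]", s))[[1]]
    rest <- gsub("[A-Z][a-z]?\\[[0-9]+\\.\\.[0-9]+\\]", "", s)
    if (grepl("\\S", rest)) stop("cannot parse constraint: ", text, call. = FALSE)
    sym <- sub("\\[.*", "", toks)
    lo <- as.integer(sub(".*\\[([0-9]+)\\.\\..*", "\\1", toks))
    hi <- as.integer(sub(".*\\.\\.([0-9]+)\\]", "\\1", toks))
    ranges <- purrr::map2(lo, hi, c)
    names(ranges) <- sym
    do.call(sum_constraint, c(ranges, list(dbr = dbr, charge = charge)))
  } else {
    cmp <- as_composition(s)
    ranges <- purrr::map(as.list(unclass(cmp)), ~ c(.x, .x))
    do.call(sum_constraint, c(ranges, list(dbr = dbr, charge = charge)))
  }
}

#' @export
format.sum_constraint <- function(x, ...) {
  el <- paste0(names(x$elements),
               purrr::map_chr(x$elements, ~ sprintf("[%d..%d]", .x[1], .x[2])),
               collapse = " ")
  sprintf("%s, DBR [%s, %s], CHG %+d", el, x$dbr[1], x$dbr[2], x$charge)
}

#' @export
print.sum_constraint <- function(x, ...) {
  cat("<sum_constraint> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Mass tolerances
#'
#' A tolerance is either relative (`"ppm"`) or absolute (`"mz"`, in Th).
#' `tolerance_width()` converts it to Th at a given m/z.
#'
#' @param value tolerance magnitude.
#' @param unit `"ppm"` or `"mz"`.
#' @export
mass_tolerance <- function(value, unit = c("ppm", "mz")) {
  unit <- match.arg(unit)
  if (value <= 0) stop("tolerance must be positive", call. = FALSE)
  structure(list(value = value, unit = unit), class = "mass_tolerance")
}

#' @rdname mass_tolerance
#' @param tol a `mass_tolerance`.
#' @param mz m/z at which to evaluate.
#' @export
tolerance_width <- function(tol, mz) {
  stopifnot(inherits(tol, "mass_tolerance"))
  if (tol$unit == "ppm") mz * tol$value * 1e-6 else tol$value
}

#' Enumerate compositions matching an m/z under a constraint
#'
#' Exhaustively enumerates the constraint box and keeps every composition
#' whose ion m/z at the constraint's charge lies within the tolerance of
#' `mz` and whose DBE lies in the constraint's DBR interval. This is the
#' engine behind DEFINE clauses: queries state composition families rather
#' than exact masses.
#'
#' @param mz target m/z in Th.
#' @param k a [sum_constraint()] with finite element ranges.
#' @param tol a [mass_tolerance()].
#' @param max_box guard on the number of candidates enumerated.
#' @return A tibble sorted by absolute mass error: `formula`, `exact_mz`,
#'   `error_ppm`, `dbe`, and a `composition` list column.
#' @examples
#' enumerate_compositions(255.233,
#'   sum_constraint(C = c(10, 20), H = c(20, 40), O = 2, dbr = c(1.5, 7.5), charge = -1),
#'   mass_tolerance(5, "ppm"))
#' @export
enumerate_compositions <- function(mz, k, tol = mass_tolerance(5, "ppm"),
                                   max_box = 2e6) {
  stopifnot(inherits(k, "sum_constraint"))
  sizes <- purrr::map_dbl(k$elements, ~ .x[2] - .x[1] + 1)
  if (prod(sizes) > max_box) {
    stop("constraint box too large (", format(prod(sizes), big.mark = ","),
         " candidates)", call. = FALSE)
  }
  grid <- do.call(expand.grid, purrr::map(k$elements, ~ seq(.x[1], .x[2])))
  names(grid) <- names(k$elements)
  mass <- as.vector(as.matrix(grid) %*% .element_masses[names(grid)])
  chg <- k$charge
  cand_mz <- if (chg == 0) mass else (mass - chg * ELECTRON_MASS) / abs(chg)
  nC <- if ("C" %in% names(grid)) grid$C else 0
  nH <- if ("H" %in% names(grid)) grid$H else 0
  nN <- if ("N" %in% names(grid)) grid$N else 0
  nP <- if ("P" %in% names(grid)) grid$P else 0
  dbe <- nC + 1 - nH / 2 + (nN + nP) / 2
  keep <- abs(cand_mz - mz) <= tolerance_width(tol, mz) &
    dbe >= k$dbr[1] & dbe <= k$dbr[2]
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0) {
    return(tibble::tibble(formula = character(), exact_mz = numeric(),
                          error_ppm = numeric(), dbe = numeric(),
                          composition = list()))
  }
  comps <- purrr::map(seq_len(nrow(grid)),
                      ~ do.call(composition, as.list(grid[.x, , drop = FALSE])))
  out <- tibble::tibble(
    formula = purrr::map_chr(comps, format),
    exact_mz = cand_mz[keep],
    error_ppm = (mz - cand_mz[keep]) / cand_mz[keep] * 1e6,
    dbe = dbe[keep],
    composition = comps
  )
  dplyr::arrange(out, abs(.data$error_ppm), .data$formula)
}

#' Natural isotope pattern of a composition
#'
#' Convolves per-element isotopologue distributions (natural abundances,
#' binomial/multinomial per element) and truncates to the first `n`
#' isotopologues, renormalizing to sum one.
#'
#' @inheritParams monoisotopic_mass
#' @param n number of isotopologues (M+0 .. M+(n-1)) to retain.
#' @return A tibble: `isotopologue` (nucleon offset) and `abundance`.
#' @examples
#' isotope_pattern("C38H73NO8P", n = 3)
#' @export
isotope_pattern <- function(c, n = 3) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  c <- as_composition(c)
  pat <- 1
  for (sym in names(c)) {
    single <- lipid_elements$abundance[[match(sym, lipid_elements$symbol)]]
    pat <- convolve_trunc(pat, power_trunc(single, unclass(c)[[sym]], n), n)
  }
  pat <- c(pat, rep(0, max(0, n - length(pat))))[seq_len(n)]
  tibble::tibble(isotopologue = seq_len(n) - 1L, abundance = pat / sum(pat))
}

# truncated polynomial product of abundance vectors
convolve_trunc <- function(a, b, n) {
  la <- length(a); lb <- length(b)
  out <- numeric(min(n, la + lb - 1))
  for (i in seq_len(la)) {
    jmax <- min(lb, length(out) - i + 1)
    if (jmax < 1) break
    idx <- i + seq_len(jmax) - 1
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

# truncated k-th power by binary exponentiation
power_trunc <- function(p, k, n) {
  out <- 1
  base <- p
  while (k > 0) {
    if (k %% 2 == 1) out <- convolve_trunc(out, base, n)
    base <- convolve_trunc(base, base, n)
    k <- k %/% 2
  }
  out
}
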