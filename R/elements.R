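#' Element table used for all mass arithmetic
#'
#' Monoisotopic masses (IUPAC 2013) and natural isotope abundances of the
#' elements supported in compositions. Isotope abundances are given per
#' nucleon offset from the monoisotopic species (M+0, M+1, M+2), already
#' normalized to sum to one.
#'
#' @format A tibble with one row per element:
#' \describe{
#'   \item{symbol}{element symbol}
#'   \item{mass}{monoisotopic mass in Da}
#'   \item{abundance}{list column: relative abundance at nucleon offsets 0, 1, 2}
#' }
#' @export
lipid_elements <- tibble::tibble(
  symbol = c("C", "H", "N", "O", "P", "S", "Na"),
  mass = c(12, 1.00782503207, 14.0030740048, 15.9949146196,
           30.97376163, 31.97207100, 22.9897692809),
  abundance = list(
    c(0.9893, 0.0107),
    c(0.999885, 0.000115),
    c(0.99636, 0.00364),
    c(0.99757, 0.00038, 0.00205),
    c(1),
    c(0.9499, 0.0075, 0.0425) / sum(c(0.9499, 0.0075, 0.0425)),
    c(1)
  )
)

#' Mass of the electron in Da
#' @export
ELECTRON_MASS <- 0.00054858

.element_symbols <- lipid_elements$symbol
.element_masses <- stats::setNames(lipid_elements$mass, lipid_elements$symbol)

#' Elemental compositions
#'
#' An elemental composition is a named integer vector of non-negative atom
#' counts, the currency of all mass arithmetic in the package. Compositions
#' add and subtract element-wise (`+`, `-`); subtraction that would produce a
#' negative count is an error. `==` tests exact element-wise equality.
#'
#' @param ... atom counts by element symbol, e.g. `composition(C = 16, H = 31, O = 2)`.
#' @return An object of class `composition`.
#' @examples
#' composition(C = 16, H = 31, O = 2) + composition(H = 1)
#' @export
composition <- function(...) {
  counts <- c(...)
  if (length(counts) == 0) {
    return(structure(stats::setNames(integer(0), character(0)), class = "composition"))
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("composition() requires named arguments (element symbols)", call. = FALSE)
  }
  unknown <- setdiff(names(counts), .element_symbols)
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(counts < 0)) stop("element counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts))) stop("element counts must be integers", call. = FALSE)
  counts <- tapply(as.integer(counts), names(counts), sum)
  counts <- counts[counts > 0]
  # canonical order: table order
  ord <- order(match(names(counts), .element_symbols))
  structure(stats::setNames(as.integer(counts)[ord], names(counts)[ord]),
            class = "composition")
}

#' Parse a molecular formula into a composition
#'
#' Accepts compact (`"C38H73NO8P"`) and spaced (`"C38 H73 N1 O8 P1"`) forms;
#' an omitted count means one atom.
#'
#' @param x a formula string, or an existing `composition` (returned as is).
#' @return A `composition`.
#' @examples
#' as_composition("C5 H11 O4 N1 P1")
#' @export
as_composition <- function(x) {
  if (inherits(x, "composition")) return(x)
  if (!is.character(x) || length(x) != 1) {
    stop("as_composition() expects a single formula string", call. = FALSE)
  }
  s <- gsub("\\s+", "", x)
  if (s == "") return(composition())
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse formula: ", x, call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Z][a-z]?", "", toks)
  cnt <- ifelse(cnt == "", "1", cnt)
  do.call(composition, as.list(stats::setNames(as.integer(cnt), sym)))
}

#' @export
format.composition <- function(x, ...) {
  if (length(x) == 0) return("(empty)")
  paste0(names(x), unclass(x), collapse = " ")
}

#' @export
print.composition <- function(x, ...) {
  cat("<composition> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
Ops.composition <- function(e1, e2) {
  if (.Generic %in% c("+", "-")) {
    a <- unclass(as_composition(e1)); b <- unclass(as_composition(e2))
    syms <- union(names(a), names(b))
    av <- stats::setNames(rep(0L, length(syms)), syms); av[names(a)] <- a
    bv <- stats::setNames(rep(0L, length(syms)), syms); bv[names(b)] <- b
    r <- if (.Generic == "+") av + bv else av - bv
    if (any(r < 0)) {
      stop("composition subtraction would give negative count for ",
           paste(syms[r < 0], collapse = ", "), call. = FALSE)
    }
    return(do.call(composition, as.list(r)))
  }
  if (.Generic == "==") {
    a <- unclass(as_composition(e1)); b <- unclass(as_composition(e2))
    syms <- union(names(a), names(b))
    av <- stats::setNames(rep(0L, length(syms)), syms); av[names(a)] <- a
    bv <- stats::setNames(rep(0L, length(syms)), syms); bv[names(b)] <- b
    return(all(av == bv))
  }
  if (.Generic == "!=") return(!(e1 == e2))
  stop("operation '", .Generic, "' not defined for compositions", call. = FALSE)
}

element_count <- function(x, symbol) {
  x <- unclass(as_composition(x))
  if (symbol %in% names(x)) unname(x[[symbol]]) else 0L
}
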