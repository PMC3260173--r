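#' Glycerophospholipid class registry
#'
#' Head-group constants for the classes wired into the simulator and the
#' annotation helpers. `anion_constant` is the composition that, added to
#' the two acyl-anion compositions, gives the [M-H]- molecular anion (for
#' PE this is the phosphoethanolamine head group plus glycerol backbone,
#' C5 H11 O4 N1 P1). `pos_adduct` is the cationizing agent in positive
#' mode ([M+H]+ for PE, [M+NH4]+ for PG) and `nls_loss` the head-group
#' neutral loss those adducts undergo (monoisotopic 141.02 and 189.04 Da).
#'
#' @format A tibble with columns `class`, `anion_constant`, `pos_adduct`,
#'   `nls_loss` (formula strings).
#' @export
lipid_classes <- tibble::tibble(
  class = c("PE", "PG"),
  anion_constant = c("C5H11NO4P", "C6H12O6P"),
  pos_adduct = c("H", "H4N"),
  nls_loss = c("C2H8NO4P", "C3H12NO6P")
)

class_info <- function(class) {
  i <- match(class, lipid_classes$class)
  if (is.na(i)) {
    stop("unsupported lipid class: ", class, " (supported: ",
         paste(lipid_classes$class, collapse = ", "), ")", call. = FALSE)
  }
  as.list(lipid_classes[i, ])
}

#' Acyl anion composition of a fatty acid
#'
#' A fatty acid with `chain` carbons and `db` double bonds fragments in
#' negative mode to the carboxylate anion C(chain) H(2*chain-1-2*db) O2
#' (e.g. 16:0 gives C16H31O2, m/z 255.233).
#'
#' @param chain carbon count of the fatty acid.
#' @param db number of double bonds.
#' @return A `composition`.
#' @export
acyl_anion <- function(chain, db) {
  h <- 2 * chain - 1 - 2 * db
  if (h < 1) stop("impossible fatty acid ", chain, ":", db, call. = FALSE)
  composition(C = chain, H = h, O = 2)
}

# interpret a composition as an acyl anion; NULL when it is not one
acyl_from_composition <- function(cmp) {
  cmp <- as_composition(cmp)
  cc <- element_count(cmp, "C"); hh <- element_count(cmp, "H")
  if (element_count(cmp, "O") != 2 || length(cmp) != 3) return(NULL)
  db <- (2 * cc - 1 - hh) / 2
  if (db < 0 || db != round(db)) return(NULL)
  list(chain = cc, db = as.integer(db))
}

# sum annotation ("PE 33:1") from the FA-part composition C(n) H(2n-2-2D) O4
sum_annotation_from_fa_part <- function(class, fa_part) {
  n <- element_count(fa_part, "C")
  D <- n - 1 - element_count(fa_part, "H") / 2
  if (n <= 0 || D < 0 || D != round(D)) return(NA_character_)
  sprintf("%s %d:%d", class, n, as.integer(D))
}

# derive "Class C:D" from a precursor composition and its charge
annotate_precursor <- function(class, precursor, charge) {
  info <- tryCatch(class_info(class), error = function(e) NULL)
  if (is.null(info)) return(NA_character_)
  res <- tryCatch({
    if (charge < 0) {
      fa <- as_composition(precursor) - as_composition(info$anion_constant)
    } else {
      neutral_const <- as_composition(info$anion_constant) + composition(H = 1)
      fa <- as_composition(precursor) - as_composition(info$pos_adduct) - neutral_const
    }
    sum_annotation_from_fa_part(class, fa)
  }, error = function(e) NA_character_)
  res
}
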