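#' Instrument resolution model
#'
#' Resolution (FWHM) is modeled as linear in m/z:
#' `R(m) = r0 + slope * (m - m_ref)`. The peak-grouping tolerance at m/z m is
#' `m / R(m)`, i.e. one FWHM.
#'
#' @param r0 resolution at the reference m/z.
#' @param slope change of resolution per Th.
#' @param m_ref reference m/z.
#' @export
resolution_model <- function(r0, slope = 0, m_ref = 0) {
  if (r0 <= 0) stop("r0 must be positive", call. = FALSE)
  structure(list(r0 = r0, slope = slope, m_ref = m_ref), class = "resolution_model")
}

#' @rdname resolution_model
#' @param model a `resolution_model`.
#' @param mz m/z at which the grouping tolerance is needed.
#' @return Tolerance in Th.
#' @export
tolerance_at <- function(model, mz) {
  stopifnot(inherits(model, "resolution_model"))
  r <- model$r0 + model$slope * (mz - model$m_ref)
  if (any(r <= 0)) {
    stop("resolution model gives non-positive resolution at m/z ",
         paste(signif(mz[r <= 0], 6), collapse = ", "), call. = FALSE)
  }
  mz / r
}
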