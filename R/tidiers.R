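#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted PRM response curve
#'
#' @param x A `response_curve_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient (`term`, `estimate`).
#' @export
tidy.response_curve_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' One-row summary of a fitted PRM response curve
#'
#' @param x A `response_curve_fit`.
#' @param ... Unused.
#' @return Tibble: `peptide_id`, `slope`, `intercept`, `r_squared`,
#'   `n_accepted`, `loq_fmol`, `lod_fmol`, `valid`, `reason`.
#' @export
glance.response_curve_fit <- function(x, ...) {
  tibble::tibble(peptide_id = x$peptide_id, slope = x$slope,
                 intercept = x$intercept, r_squared = x$r_squared,
                 n_accepted = length(x$accepted_levels),
                 loq_fmol = x$loq_fmol, lod_fmol = x$lod_fmol,
                 valid = x$valid, reason = x$reason)
}
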