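## Efficiency-corrected relative qPCR quantification (Pfaffl method).

#' Amplification factor from a standard-curve slope
#'
#' E = 10^(-1/slope), where `slope` is the regression slope of Ct against
#' log10 template dilution. Perfect doubling chemistry gives a slope of
#' about -3.3219 and E = 2.
#'
#' @param slope Regression slope (non-zero; negative for real assays).
#' @return Amplification factor E.
#' @export
amplification_factor <- function(slope) {
  check_that(is.numeric(slope) && all(slope != 0), "slope must be non-zero")
  10^(-1 / slope)
}

#' Primer efficiency as a percentage
#'
#' Efficiency% = (E - 1) * 100, so perfect doubling (E = 2) is 100%.
#'
#' @param E Amplification factor (> 1).
#' @return Efficiency in percent.
#' @export
efficiency_percent <- function(E) {
  check_that(is.numeric(E) && all(E > 1), "E must be greater than 1")
  (E - 1) * 100
}

#' Pfaffl relative expression ratio
#'
#' ratio = E_goi^dCt_goi / E_ref^dCt_ref, with dCt = Ct(control) -
#' Ct(treated) for both the gene of interest and the reference gene, so a
#' ratio above 1 means up-regulation in the treated condition.
#'
#' @param E_goi,E_ref Amplification factors (> 1).
#' @param dCt_goi,dCt_ref Ct differences (control - treated), in cycles.
#' @return Expression ratio (positive).
#' @export
pfaffl_ratio <- function(E_goi, dCt_goi, E_ref, dCt_ref) {
  check_that(all(E_goi > 1) && all(E_ref > 1), "amplification factors must exceed 1")
  (E_goi^dCt_goi) / (E_ref^dCt_ref)
}
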