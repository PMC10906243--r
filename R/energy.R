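# Free-energy transforms between observed selectivities (ee, dr) and the
# differential activation free energy DDG(kcal/mol) at which selectivity is
# modeled. DDG = RT ln(ratio of competing pathways).

#' Gas constant in kcal/(mol K)
#' @export
R_GAS_KCAL <- 1.987e-3

#' Convert enantiomeric excess to a free-energy difference
#'
#' `DDG = R T ln((1 + ee) / (1 - ee))` in kcal/mol. The sign of ee (which
#' product enantiomer predominates) carries through to the sign of DDG.
#'
#' @param ee Enantiomeric excess as a signed fraction, strictly inside
#'   (-1, 1).
#' @param temperature Temperature in K (default 293.15, i.e. 20 C).
#' @return DDG in kcal/mol.
#' @export
ee_to_ddg <- function(ee, temperature = 293.15) {
  stopifnot(all(temperature > 0))
  if (any(abs(ee) >= 1)) {
    stop("|ee| must be strictly less than 1 for the free-energy transform",
         call. = FALSE)
  }
  R_GAS_KCAL * temperature * log((1 + ee) / (1 - ee))
}

#' Convert a free-energy difference back to enantiomeric excess
#'
#' Inverse of [ee_to_ddg()]: `ee = tanh(DDG / (2 R T))`.
#'
#' @param ddg Free-energy difference in kcal/mol.
#' @param temperature Temperature in K.
#' @return Signed ee fraction in (-1, 1).
#' @export
ddg_to_ee <- function(ddg, temperature = 293.15) {
  stopifnot(all(temperature > 0))
  tanh(ddg / (2 * R_GAS_KCAL * temperature))
}

#' Convert a diastereomeric ratio to a free-energy difference
#'
#' `DDG = R T ln(syn / anti)` in kcal/mol.
#'
#' @param syn,anti Positive components of the syn:anti ratio (any common
#'   scale: 98 and 2, or 0.98 and 0.02).
#' @param temperature Temperature in K.
#' @return DDG in kcal/mol.
#' @export
dr_to_ddg <- function(syn, anti, temperature = 293.15) {
  stopifnot(all(temperature > 0))
  if (any(syn <= 0) || any(anti <= 0)) {
    stop("both dr components must be strictly positive", call. = FALSE)
  }
  R_GAS_KCAL * temperature * log(syn / anti)
}
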