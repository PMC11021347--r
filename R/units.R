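#' Unit conversions
#'
#' Single-sourced converters between the conventional clinical units and the
#' units used internally by the models: glucose in mmol/L, insulin in pmol/L,
#' glucagon in ng/L, C-peptide in nmol/L.
#'
#' @param x Numeric vector of concentrations.
#' @return Numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
glucose_mgdl_to_mmoll <- function(x) x / 18.016

#' @rdname units
#' @export
glucose_mmoll_to_mgdl <- function(x) x * 18.016

#' @rdname units
#' @export
insulin_uuml_to_pmoll <- function(x) x * 6.0

#' @rdname units
#' @export
insulin_pmoll_to_uuml <- function(x) x / 6.0
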