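#' Unit conversions
#'
#' Weights are stored in kilograms and heights in centimetres
#' internally; pounds and inches are accepted and produced at the I/O
#' boundary, matching how clients and clinicians see the data.
#'
#' @param lb,kg,inches,cm Numeric vectors.
#' @return Numeric vector in the target unit.
#' @examples
#' kg_to_lb(lb_to_kg(200)) # 200
#' @name units
NULL

#' @rdname units
#' @export
lb_to_kg <- function(lb) lb * 0.45359237

#' @rdname units
#' @export
kg_to_lb <- function(kg) kg / 0.45359237

#' @rdname units
#' @export
in_to_cm <- function(inches) inches * 2.54

#' @rdname units
#' @export
cm_to_in <- function(cm) cm / 2.54
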