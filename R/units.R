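#' Unit conversions for graft volumes and lengths
#'
#' The package works internally in micrometres (length) and cubic micrometres
#' (volume). Experimental protocols quote injected volumes in nanolitres or
#' microlitres and depths in millimetres; these helpers convert explicitly so
#' no function ever guesses units. 1 nL = 1e6 um^3, 1 uL = 1e9 um^3.
#'
#' @param x Numeric vector of values to convert.
#' @return Numeric vector in the target unit.
#' @examples
#' ul_to_um3(0.1)   # 100 nL as um^3
#' um3_to_nl(4.18879e6)
#' @name units
NULL

#' @rdname units
#' @export
nl_to_um3 <- function(x) x * 1e6

#' @rdname units
#' @export
ul_to_um3 <- function(x) x * 1e9

#' @rdname units
#' @export
um3_to_nl <- function(x) x / 1e6

#' @rdname units
#' @export
um3_to_ul <- function(x) x / 1e9

#' @rdname units
#' @export
mm_to_um <- function(x) x * 1e3

#' @rdname units
#' @export
um_to_mm <- function(x) x / 1e3
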