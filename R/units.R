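#' Unit conventions and conversions
#'
#' All geometry is in micrometres (um), time in milliseconds (ms), volume in
#' cubic micrometres (1 nl = 1e6 um^3), volumetric flow in um^3/ms and
#' pressure in pascal (Pa) internally; millimetres of mercury (mmHg) are
#' accepted at the interfaces (1 mmHg = 133.322 Pa).
#'
#' @param x numeric vector to convert.
#' @return converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
mmHg_to_Pa <- function(x) x * 133.322

#' @rdname units
#' @export
Pa_to_mmHg <- function(x) x / 133.322

#' @rdname units
#' @export
nl_to_um3 <- function(x) x * 1e6

#' @rdname units
#' @export
um3_to_nl <- function(x) x / 1e6
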