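#' Unit conversion helpers
#'
#' The public interface of this package speaks the units of the surgical
#' literature (millimetres, degrees, mmHg); all internal computation is SI.
#'
#' @param x numeric vector.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
m_to_mm <- function(x) x * 1e3

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * 133.322

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / 133.322

deg_to_rad <- function(x) x * pi / 180
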