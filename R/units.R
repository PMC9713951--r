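#' @keywords internal
"_PACKAGE"

## SI is used internally everywhere (Pa, m, kg/m^3); mmHg and ml appear only at
## I/O boundaries.

#' Unit conversions between mmHg and Pa
#'
#' All internal computation is in SI units; pressures cross the package
#' boundary in mmHg (the clinical convention for detrusor pressure).
#'
#' @param p pressure values, mmHg (`mmhg_to_pa`) or Pa (`pa_to_mmhg`).
#' @return numeric vector of converted pressures.
#' @export
#' @examples
#' mmhg_to_pa(15)
#' pa_to_mmhg(mmhg_to_pa(15))
mmhg_to_pa <- function(p) p * 133.322387415

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(p) p / 133.322387415

ml_to_m3 <- function(v) v * 1e-6
m3_to_ml <- function(v) v * 1e6

stop_domain <- function(...) stop(..., call. = FALSE)
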