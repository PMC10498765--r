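#' Unit conversion helpers
#'
#' All internal computation in ffrnet is in SI units: metres, square metres,
#' Pascals, cubic metres per second, Pa s/m^3. Clinical interfaces (file
#' formats, physiology inputs, printed results) use mmHg, L/min and mL/s;
#' these helpers convert between the two conventions.
#'
#' The conversion constant is 1 mmHg = 133.322 Pa.
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
Lmin_to_m3s <- function(x) x * 1e-3 / 60

#' @rdname units
#' @export
m3s_to_Lmin <- function(x) x * 60 * 1e3

#' @rdname units
#' @export
mLs_to_m3s <- function(x) x * 1e-6

#' @rdname units
#' @export
m3s_to_mLs <- function(x) x * 1e6

# length scale factors to metres, by declared unit
.length_factor <- function(unit) {
  switch(unit,
    m = 1, cm = 1e-2, mm = 1e-3,
    stop("unknown length unit: '", unit, "' (expected m, cm or mm)",
         call. = FALSE)
  )
}
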