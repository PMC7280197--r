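#' Physical constants and unit conversions
#'
#' `gyromagneticRatio()` returns the proton gyromagnetic ratio used throughout
#' the package when deriving Stejskal-Tanner b-values. All internal arithmetic
#' is in SI units (m, s, T); gradient amplitudes quoted in G/cm and radii in
#' micrometres are converted at the API boundary.
#'
#' @return Gyromagnetic ratio of the proton in rad s^-1 T^-1.
#' @examples
#' gyromagneticRatio()
#' @export
gyromagneticRatio <- function() 2.6752218744e8

## unit conversions (kept as internal helpers so the convention is in one place)
## 1 G/cm = 1e-4 T / 1e-2 m = 1e-2 T/m
gcmToTm <- function(g) g * 1e-2

## 1 s/mm^2 = 1e6 s/m^2
smm2ToSm2 <- function(b) b * 1e6
sm2ToSmm2 <- function(b) b * 1e-6

umToM <- function(r) r * 1e-6
mToUm <- function(r) r * 1e6
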