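#' Compartment and composite diffusion signal models
#'
#' Forward models for the normalised PGSE diffusion signal:
#' \describe{
#'   \item{ball}{isotropic hindered diffusion, \eqn{S = e^{-b\,d_{ball}}}.}
#'   \item{stick}{one-dimensional diffusion along orientation
#'     \eqn{n(\theta,\phi)}, \eqn{S = e^{-b\,d_{stick} (g\cdot n)^2}}.}
#'   \item{sphere}{restricted diffusion in an impermeable sphere,
#'     see [sphereSignal()].}
#' }
#' The composite VERDICT signal is the fraction-weighted sum
#' \eqn{S = f_{ball} S_{ball} + f_{sphere} S_{sphere} + f_{stick} S_{stick}}.
#'
#' @param b b-value(s) in s/mm^2.
#' @param dBall isotropic diffusivity (m^2/s).
#' @return normalised signal(s) in (0, 1].
#' @examples
#' ballSignal(1000, 2e-9)  # exp(-2)
#' @export
ballSignal <- function(b, dBall) {
  if (any(b < 0)) stop("negative b-value", call. = FALSE)
  if (dBall <= 0) stop("dBall must be positive", call. = FALSE)
  exp(-smm2ToSm2(b) * dBall)
}

#' @rdname ballSignal
#' @param g gradient direction(s): length-3 vector or n x 3 matrix of unit
#'   rows (zero rows allowed for b0 measurements).
#' @param dStick stick (pseudo)diffusivity (m^2/s).
#' @param theta,phi stick orientation in spherical coordinates (rad),
#'   \eqn{\theta \in [0, \pi]}, \eqn{\phi \in [0, 2\pi)}.
#' @export
stickSignal <- function(b, g, dStick, theta, phi) {
  if (any(b < 0)) stop("negative b-value", call. = FALSE)
  if (dStick <= 0) stop("dStick must be positive", call. = FALSE)
  if (is.null(dim(g))) g <- matrix(g, ncol = 3)
  nrm <- sqrt(rowSums(g^2))
  weighted <- b > 0
  if (any(abs(nrm[weighted] - 1) > 1e-6))
    stop("gradient directions must be unit vectors", call. = FALSE)
  n <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  proj2 <- as.vector(g %*% n)^2
  exp(-smm2ToSm2(b) * dStick * proj2)
}

#' Composite VERDICT ball/sphere/stick signal over a scheme
#'
#' Evaluates the three compartment signals for every measurement of a scheme
#' and returns their fraction-weighted sum. Fractions must lie in \[0, 1\]
#' and sum to one.
#'
#' @param scheme an [AcquisitionScheme-class].
#' @param params named list with elements `fBall`, `fSphere`, `fStick`,
#'   `dBall`, `dSphere`, `R` (micrometres), `dStick`, `theta`, `phi`.
#' @param nRoots series length for the sphere compartment.
#' @return normalised signal per measurement (b0 measurements give 1).
#' @export
verdictSignal <- function(scheme, params, nRoots = 40L) {
  f <- c(params$fBall, params$fSphere, params$fStick)
  if (any(f < -1e-9) || any(f > 1 + 1e-9) || abs(sum(f) - 1) > 1e-9)
    stop("fractions must lie in [0,1] and sum to 1", call. = FALSE)
  m <- scheme@measurements
  g <- as.matrix(m[, c("gx", "gy", "gz")])
  Sb <- ballSignal(m$b, params$dBall)
  Ss <- sphereSignal(m$G, m$delta, m$Delta, params$dSphere, params$R,
                     gamma = scheme@gamma, nRoots = nRoots)
  St <- stickSignal(m$b, g, params$dStick, params$theta, params$phi)
  params$fBall * Sb + params$fSphere * Ss + params$fStick * St
}

#' ADC and diffusion-kurtosis signal models
#'
#' `adcSignal` is the monoexponential decay \eqn{S = e^{-b\,ADC}};
#' `kurtosisSignal` is \eqn{S = e^{-b D_k + b^2 D_k^2 K / 6}}. With
#' \eqn{K = 0} the kurtosis model reduces exactly to the ADC model with
#' \eqn{ADC = D_k} (purely Gaussian diffusion).
#'
#' @param b b-value(s) in s/mm^2.
#' @param ADC apparent diffusion coefficient (m^2/s).
#' @return normalised signal(s).
#' @export
adcSignal <- function(b, ADC) {
  if (any(b < 0)) stop("negative b-value", call. = FALSE)
  if (ADC < 0) stop("ADC must be non-negative", call. = FALSE)
  exp(-smm2ToSm2(b) * ADC)
}

#' @rdname adcSignal
#' @param Dk kurtosis-corrected diffusivity (m^2/s).
#' @param K mean kurtosis (unitless, >= 0).
#' @export
kurtosisSignal <- function(b, Dk, K) {
  if (any(b < 0)) stop("negative b-value", call. = FALSE)
  if (Dk < 0 || K < 0) stop("Dk and K must be non-negative", call. = FALSE)
  bsi <- smm2ToSm2(b)
  exp(-bsi * Dk + bsi^2 * Dk^2 * K / 6)
}

#' Add Rician noise to a signal array
#'
#' Magnitude-MRI noise: each value S is replaced by
#' \eqn{\sqrt{(S + \epsilon_1)^2 + \epsilon_2^2}} with independent zero-mean
#' Gaussian perturbations of SD `sigma`. With `sigma = 0` the input is
#' returned unchanged.
#'
#' @param signal numeric array/vector of noiseless signals.
#' @param sigma noise SD (same units as `signal`). On the normalised signal
#'   scale sigma = 1/SNR.
#' @param seed optional integer seed for reproducibility.
#' @return noisy array of the same shape.
#' @export
addRicianNoise <- function(signal, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(signal)
  if (!is.null(seed)) set.seed(seed)
  n <- length(signal)
  noisy <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
                stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signal))) dim(noisy) <- dim(signal)
  noisy
}
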