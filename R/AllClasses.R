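#' @import methods
NULL

#' AcquisitionScheme: an ordered set of PGSE measurements
#'
#' Container for a pulsed-gradient spin-echo (PGSE) acquisition scheme. Each
#' measurement carries a gradient direction, gradient amplitude \eqn{|G|}
#' (T/m), pulse duration \eqn{\delta} (s), pulse separation \eqn{\Delta} (s)
#' and echo time TE (s), together with the derived Stejskal-Tanner b-value
#' in s/mm^2. Measurements with \eqn{G = 0} are b~0 reference images; every
#' diffusion-weighted measurement must have at least one b0 measurement with
#' the same TE so that TE-matched normalisation is possible.
#'
#' @slot measurements data.frame with one row per measurement and columns
#'   `gx`, `gy`, `gz` (unit direction, zero for b0), `G` (T/m), `Delta` (s),
#'   `delta` (s), `TE` (s), `b` (s/mm^2).
#' @slot gamma gyromagnetic ratio (rad s^-1 T^-1) used to derive b-values.
#'
#' @seealso [buildMouseProtocol()], [buildHumanProtocol()], [readScheme()]
#' @export
setClass("AcquisitionScheme",
  slots = c(measurements = "data.frame", gamma = "numeric")
)

setValidity("AcquisitionScheme", function(object) {
  m <- object@measurements
  required <- c("gx", "gy", "gz", "G", "Delta", "delta", "TE", "b")
  if (!all(required %in% names(m)))
    return(paste("measurements must have columns:", paste(required, collapse = ", ")))
  if (length(object@gamma) != 1L || object@gamma <= 0)
    return("gamma must be a single positive number")
  if (nrow(m) == 0L) return("scheme has no measurements")
  if (any(m$G < 0)) return("negative gradient amplitude")
  if (any(m$delta <= 0) || any(m$Delta <= m$delta))
    return("pulse timings must satisfy 0 < delta < Delta")
  nrm <- sqrt(m$gx^2 + m$gy^2 + m$gz^2)
  dw <- m$G > 0
  if (any(abs(nrm[dw] - 1) > 1e-6))
    return("diffusion-weighted measurements must have unit gradient direction")
  bref <- computeBValue(m$G, m$delta, m$Delta, gamma = object@gamma)
  rel <- abs(m$b - bref) / pmax(bref, 1e-12)
  if (any(rel[dw] > 1e-9)) return("stored b-values are inconsistent with (G, delta, Delta)")
  if (any(m$b[!dw] != 0)) return("b0 measurements must have b = 0")
  ## TE-matched normalisation must be possible while b0s are still present;
  ## a scheme with no b0s at all is a normalised scheme and is accepted
  if (any(!dw) && !all(unique(m$TE[dw]) %in% unique(m$TE[!dw])))
    return("every diffusion-weighted TE needs a TE-matched b0 measurement")
  TRUE
})

#' DwiVolume: a 4-D diffusion-weighted image bound to a scheme
#'
#' The fourth array dimension indexes measurements of the associated
#' [AcquisitionScheme-class]. Arrays use R's native column-major (x-fastest)
#' layout; the mask must share the spatial grid (no resampling is performed).
#'
#' @slot signal 4-D numeric array (x, y, z, measurement), non-negative.
#' @slot scheme [AcquisitionScheme-class] describing the 4th dimension.
#' @slot mask 3-D logical array selecting the region of interest.
#' @slot normalized logical flag: `TRUE` after TE-matched b0 normalisation
#'   (in which case the scheme contains no b0 measurements).
#' @export
setClass("DwiVolume",
  slots = c(signal = "array", scheme = "AcquisitionScheme",
            mask = "array", normalized = "logical")
)

setValidity("DwiVolume", function(object) {
  d <- dim(object@signal)
  if (length(d) != 4L) return("signal must be a 4-D array")
  if (d[4] != nrow(object@scheme@measurements))
    return("4th dimension must match the number of scheme measurements")
  if (!identical(dim(object@mask), d[1:3]))
    return("mask shape must equal the spatial shape of the signal")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (any(object@signal < 0, na.rm = TRUE)) return("signals must be non-negative")
  if (length(object@normalized) != 1L) return("normalized must be a single flag")
  TRUE
})

#' ParameterMaps: voxel-wise model-fit results on a 3-D grid
#'
#' Result container of [fitRoi()]. One 3-D array per fitted parameter, plus
#' per-voxel log-likelihood and BIC maps; voxels outside the fitted mask are
#' `NA`. For the VERDICT model the stick fraction map satisfies
#' `fStick == 1 - fSphere - fBall` exactly (closure, not a fitted parameter),
#' and voxels whose sphere-radius estimate lies at the upper fitting bound are
#' flagged in the logical `boundaryHit` map.
#'
#' @slot maps named list of 3-D numeric arrays (one per parameter).
#' @slot loglik 3-D array of maximised Rician log-likelihoods.
#' @slot bic 3-D array of BIC scores.
#' @slot boundaryHit 3-D logical array flagging radius-bound hits (VERDICT).
#' @slot mask 3-D logical array of fitted voxels.
#' @slot model model name ("verdict", "adc" or "kurtosis").
#' @slot config the [FitConfig-class] used for the fit.
#' @slot provenance list of run metadata (scheme hash, seed, voxel count).
#' @export
setClass("ParameterMaps",
  slots = c(maps = "list", loglik = "array", bic = "array",
            boundaryHit = "array", mask = "array", model = "character",
            config = "ANY", provenance = "list")
)

setValidity("ParameterMaps", function(object) {
  if (length(object@maps) == 0L) return("no parameter maps")
  d <- dim(object@maps[[1]])
  ok <- vapply(object@maps, function(m) identical(dim(m), d), logical(1))
  if (!all(ok)) return("all parameter maps must share one grid")
  if (!identical(dim(object@mask), d)) return("mask grid mismatch")
  TRUE
})

#' FitConfig: configuration of a voxel-wise model fit
#'
#' @slot model "verdict", "adc" or "kurtosis".
#' @slot mode "mouse" (6 fitted VERDICT parameters: fBall, fSphere, R, dStick,
#'   theta, phi) or "human" (5: dStick fixed).
#' @slot dSphere,dBall,dStick fixed compartment diffusivities (m^2/s);
#'   `dStick` is the fixed value in human mode and ignored as a fixed value in
#'   mouse mode, where it is fitted.
#' @slot rBounds sphere-radius bounds (micrometres).
#' @slot dStickBounds stick-diffusivity bounds for mouse-mode fitting (m^2/s);
#'   the lower bound defaults to free-water diffusion, 3.05e-9.
#' @slot nStartsGrid points per dimension of the coarse multi-start grid.
#' @slot nRestarts perturbed restarts of the best grid start.
#' @slot perturbSd relative perturbation scale for restarts.
#' @slot sigma Rician noise SD on the normalised signal scale, or the string
#'   "estimate" to derive it from repeated b0 measurements.
#' @slot seed integer seed controlling restart perturbations.
#' @export
setClass("FitConfig",
  slots = c(model = "character", mode = "character",
            dSphere = "numeric", dBall = "numeric", dStick = "numeric",
            rBounds = "numeric", dStickBounds = "numeric",
            nStartsGrid = "integer", nRestarts = "integer",
            perturbSd = "numeric", sigma = "ANY", seed = "integer")
)

setValidity("FitConfig", function(object) {
  if (!object@model %in% c("verdict", "adc", "kurtosis"))
    return("model must be one of verdict, adc, kurtosis")
  if (!object@mode %in% c("mouse", "human")) return("mode must be mouse or human")
  if (object@rBounds[1] <= 0 || diff(object@rBounds) <= 0)
    return("rBounds must be an increasing positive pair")
  if (diff(object@dStickBounds) <= 0) return("dStickBounds must be increasing")
  if (object@nStartsGrid < 1L) return("nStartsGrid must be >= 1")
  if (is.numeric(object@sigma) && object@sigma <= 0)
    return("sigma must be positive or \"estimate\"")
  TRUE
})

#' PhantomGroundTruth: labelled synthetic tumour geometry with true parameters
#'
#' Generated by [generatePhantom()]. The label map distinguishes background
#' (0), peri-tumoural shell (1), tumour rim (2) and tumour core (3); every
#' labelled voxel carries a full set of true VERDICT parameter values whose
#' compartment fractions sum to one.
#'
#' @slot labels 3-D integer array of region labels.
#' @slot params named list of 3-D arrays: fSphere, fBall, fStick, R (um),
#'   dStick (m^2/s), theta, phi.
#' @slot voxelSize voxel edge lengths in mm (length 3).
#' @export
setClass("PhantomGroundTruth",
  slots = c(labels = "array", params = "list", voxelSize = "numeric")
)

setValidity("PhantomGroundTruth", function(object) {
  p <- object@params
  need <- c("fSphere", "fBall", "fStick", "R", "dStick", "theta", "phi")
  if (!all(need %in% names(p)))
    return(paste("params must contain:", paste(need, collapse = ", ")))
  inside <- object@labels > 0
  s <- p$fSphere[inside] + p$fBall[inside] + p$fStick[inside]
  if (any(abs(s - 1) > 1e-9)) return("fractions must sum to 1 in labelled voxels")
  if (any(p$R[inside] <= 0)) return("radii must be positive")
  TRUE
})
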