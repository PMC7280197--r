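#' Generate a synthetic tumour phantom with known VERDICT parameters
#'
#' Builds an ellipsoidal tumour embedded in a 3-D grid, with a necrotic-like
#' core, a cellular rim and a surrounding peri-tumoural shell, mimicking the
#' regional contrast seen in glioblastoma (a rim of raised sphere fraction
#' around a core of low sphere fraction). Each region carries its own mean
#' parameter values; per-voxel fields are the region means plus a smoothed
#' Gaussian perturbation of configurable within-region SD, truncated to valid
#' ranges (fractions renormalised to sum to one).
#'
#' @param shape integer length-3 grid shape (each >= 8).
#' @param voxelSize voxel edge lengths in mm.
#' @param centre ellipsoid centre in voxel coordinates (default grid centre).
#' @param semiAxes outer (peri) semi-axes in voxels; the rim and core are
#'   concentric at `rimScale` and `coreScale` of the peri radius.
#' @param rimScale,coreScale relative radii of rim and core boundaries.
#' @param regionParams named list of per-region parameter lists (`core`,
#'   `rim`, `peri`), each with `fSphere`, `fBall`, `R` (um), `dStick`
#'   (m^2/s), `theta`, `phi`; `fStick` follows by closure.
#' @param withinSd named list of within-region SDs for `fSphere`, `R`,
#'   `dStick` (0 gives piecewise-constant fields).
#' @param seed integer seed.
#' @return a [PhantomGroundTruth-class]
#' @examples
#' ph <- generatePhantom(shape = c(12, 12, 6), seed = 1)
#' table(ph@labels)
#' @export
generatePhantom <- function(shape = c(16, 16, 8), voxelSize = c(0.3, 0.3, 0.5),
                            centre = NULL, semiAxes = NULL,
                            rimScale = 0.75, coreScale = 0.45,
                            regionParams = defaultRegionParams(),
                            withinSd = list(fSphere = 0.03, R = 0.4,
                                            dStick = 1e-9),
                            seed = 1L) {
  if (length(shape) != 3L || any(shape < 8))
    stop("shape must be a length-3 grid of at least 8 voxels per axis", call. = FALSE)
  if (is.null(centre)) centre <- (shape + 1) / 2
  if (is.null(semiAxes)) semiAxes <- shape / 2 - 1
  if (any(centre + semiAxes > shape + 0.5) || any(centre - semiAxes < 0.5))
    stop("geometry exceeds grid", call. = FALSE)
  set.seed(seed)
  ax <- array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), dim = shape)
  ay <- array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
              dim = shape)
  az <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), dim = shape)
  r2 <- ((ax - centre[1]) / semiAxes[1])^2 +
        ((ay - centre[2]) / semiAxes[2])^2 +
        ((az - centre[3]) / semiAxes[3])^2
  labels <- array(0L, dim = shape)
  labels[r2 <= 1] <- 1L                  # peri shell
  labels[r2 <= rimScale^2] <- 2L         # rim
  labels[r2 <= coreScale^2] <- 3L        # core
  regionOf <- c("peri", "rim", "core")

  smoothField <- function(sd) {
    if (sd == 0) return(array(0, dim = shape))
    f <- array(stats::rnorm(prod(shape)), dim = shape)
    ## separable 3-point smoothing, then rescale to requested SD
    k <- c(0.25, 0.5, 0.25)
    sm <- function(v) {
      n <- length(v)
      v2 <- c(v[1], v, v[n])
      k[1] * v2[1:n] + k[2] * v2[2:(n + 1)] + k[3] * v2[3:(n + 2)]
    }
    f <- apply(f, c(2, 3), sm)
    f <- aperm(apply(f, c(1, 3), sm), c(2, 1, 3))
    f <- aperm(apply(f, c(1, 2), sm), c(2, 3, 1))
    f / stats::sd(f) * sd
  }

  mk <- function(name, sd) {
    out <- array(NA_real_, dim = shape)
    pert <- smoothField(sd)
    for (lab in 1:3) {
      reg <- regionParams[[regionOf[lab]]]
      sel <- labels == lab
      out[sel] <- reg[[name]] + pert[sel]
    }
    out
  }
  fSphere <- pmin(pmax(mk("fSphere", withinSd$fSphere), 0.01), 0.95)
  fBall <- array(NA_real_, dim = shape)
  for (lab in 1:3) {
    reg <- regionParams[[regionOf[lab]]]
    sel <- labels == lab
    ## keep the region's stick fraction, rescale ball to preserve closure
    fBall[sel] <- (1 - fSphere[sel]) *
      reg$fBall / (reg$fBall + (1 - reg$fSphere - reg$fBall))
  }
  fStick <- 1 - fSphere - fBall
  R <- pmin(pmax(mk("R", withinSd$R), 0.5), 19.5)
  dStick <- pmin(pmax(mk("dStick", withinSd$dStick), 3.05e-9), 25e-9)
  theta <- mk("theta", 0); phi <- mk("phi", 0)

  new("PhantomGroundTruth", labels = labels,
      params = list(fSphere = fSphere, fBall = fBall, fStick = fStick,
                    R = R, dStick = dStick, theta = theta, phi = phi),
      voxelSize = voxelSize)
}

#' Default regional parameter means for the tumour phantom
#'
#' Rim values follow the pre-therapy tumour means (sphere fraction 0.54, ball
#' fraction 0.39, radius 10.6 um, stick diffusivity 10.8e-9 m^2/s); the core
#' emulates a necrotic centre (low sphere fraction, high ball fraction) and
#' the peri shell intermediate tissue with a slightly larger radius.
#'
#' @return named list of per-region parameter lists.
#' @export
defaultRegionParams <- function() {
  list(
    core = list(fSphere = 0.30, fBall = 0.63, R = 8.0, dStick = 10.8e-9,
                theta = 1.0, phi = 0.8),
    rim  = list(fSphere = 0.54, fBall = 0.39, R = 10.6, dStick = 10.8e-9,
                theta = 1.0, phi = 0.8),
    peri = list(fSphere = 0.42, fBall = 0.50, R = 12.0, dStick = 10.8e-9,
                theta = 1.0, phi = 0.8)
  )
}

setMethod("show", "PhantomGroundTruth", function(object) {
  tab <- table(factor(object@labels, levels = 0:3,
                      labels = c("background", "peri", "rim", "core")))
  cat("PhantomGroundTruth", paste(dim(object@labels), collapse = " x "),
      "voxels\n")
  print(tab)
})

#' Synthesise a DWI volume from a phantom ground truth
#'
#' Evaluates the noiseless VERDICT signal per labelled voxel for every
#' measurement of the scheme (b0 measurements give S0), scales by `S0` and
#' adds Rician noise with \eqn{\sigma = S0 / SNR}. Background voxels carry
#' pure noise. The returned volume is raw (un-normalised) with the phantom's
#' labelled voxels as mask.
#'
#' @param truth a [PhantomGroundTruth-class].
#' @param scheme an [AcquisitionScheme-class].
#' @param snr signal-to-noise ratio of the b0 signal (`Inf` for noiseless).
#' @param s0 b0 signal level in arbitrary units.
#' @param seed integer seed.
#' @param dSphere,dBall fixed compartment diffusivities (m^2/s).
#' @return a raw [DwiVolume-class]
#' @export
synthesizeDwi <- function(truth, scheme, snr = 50, s0 = 1000, seed = 1L,
                          dSphere = 1e-9, dBall = 2e-9) {
  shape <- dim(truth@labels)
  nm <- nMeasurements(scheme)
  sig <- matrix(0, nrow = prod(shape), ncol = nm)
  idx <- which(truth@labels > 0)
  p <- truth@params
  for (v in idx) {
    params <- list(fSphere = p$fSphere[v], fBall = p$fBall[v],
                   fStick = p$fStick[v], R = p$R[v], dStick = p$dStick[v],
                   theta = p$theta[v], phi = p$phi[v],
                   dSphere = dSphere, dBall = dBall)
    sig[v, ] <- s0 * verdictSignal(scheme, params)
  }
  sigma <- if (is.finite(snr)) s0 / snr else 0
  sig <- addRicianNoise(sig, sigma, seed = seed)
  new("DwiVolume", signal = array(sig, dim = c(shape, nm)), scheme = scheme,
      mask = array(truth@labels > 0, dim = shape), normalized = FALSE)
}
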