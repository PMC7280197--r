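## Shared fixtures, built once per test run.

mouseScheme <- buildMouseProtocol()
humanScheme <- buildHumanProtocol()

## printed b-value table of the preclinical protocol, s/mm^2
## (rows: G in G/cm; columns: Delta = 10/20/30/40 ms at delta = 3 ms,
##  then Delta = 30/40 ms at delta = 10 ms)
printedMouseB <- list(
  delta3 = cbind(
    G = c(3.6, 7.2, 10.8, 14.4, 18.0, 21.6, 25.2, 28.8, 32.4, 36.0),
    matrix(c(8, 16, 24, 33,
             30, 63, 97, 130,
             68, 143, 218, 293,
             120, 254, 387, 521,
             188, 397, 606, 814,
             270, 571, 872, 1173,
             368, 778, 1187, 1596,
             481, 1016, 1550, 2085,
             609, 1285, 1962, 2639,
             752, 1587, 2422, 3257), ncol = 4, byrow = TRUE)),
  delta10 = cbind(
    G = c(4, 8, 12),
    matrix(c(305, 420, 1221, 1680, 2749, 3780), ncol = 2, byrow = TRUE))
)

## one-shell scheme (1 b0 + 3 directions): fewer measurements than VERDICT
## parameters, for precondition tests
tinyScheme <- function() {
  f <- tempfile(fileext = ".txt")
  writeLines(c(
    "VERSION: STEJSKALTANNER",
    "0 0 0 0    0.03 0.003 0.043",
    "1 0 0 0.2  0.03 0.003 0.043",
    "0 1 0 0.2  0.03 0.003 0.043",
    "0 0 1 0.2  0.03 0.003 0.043"), f)
  on.exit(unlink(f), add = TRUE)
  readScheme(f)
}

## reference mouse-tumour parameters (pre-therapy means)
baselineParams <- function(R = 10.6, fSphere = 0.54, fBall = 0.39) {
  list(fBall = fBall, fSphere = fSphere, fStick = 1 - fSphere - fBall,
       dBall = 2e-9, dSphere = 1e-9, R = R, dStick = 10.8e-9,
       theta = 1.0, phi = 0.5)
}

## noiseless normalised DW signal under the mouse protocol
mouseDwSignal <- function(params = baselineParams()) {
  verdictSignal(mouseScheme, params)[!isB0(mouseScheme)]
}

## tiny raw volume wrapping given per-voxel normalised DW signals, with
## matching TE-matched b0s at a given S0 and Rician noise
tinyRawVolume <- function(nVoxels, params = baselineParams(), snr = 50,
                          s0 = 1000, seed = 1) {
  clean <- verdictSignal(mouseScheme, params) * s0
  nm <- nMeasurements(mouseScheme)
  sig <- matrix(rep(clean, each = nVoxels), nrow = nVoxels)
  sigma <- if (is.finite(snr)) s0 / snr else 0
  sig <- addRicianNoise(sig, sigma, seed = seed)
  dim(sig) <- c(nVoxels, 1, 1, nm)
  dwiVolume(sig, mouseScheme)
}
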