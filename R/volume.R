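#' Construct a DwiVolume
#'
#' @param signal 4-D numeric array (x, y, z, measurement).
#' @param scheme [AcquisitionScheme-class] matching the 4th dimension.
#' @param mask optional 3-D logical ROI mask; defaults to all voxels.
#' @param normalized whether the signal is already b0-normalised.
#' @return a [DwiVolume-class]
#' @export
dwiVolume <- function(signal, scheme, mask = NULL, normalized = FALSE) {
  d <- dim(signal)
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  new("DwiVolume", signal = signal, scheme = scheme, mask = mask,
      normalized = normalized)
}

#' @describeIn nMeasurements measurements of the bound scheme
#' @export
setMethod("nMeasurements", "DwiVolume", function(x) nMeasurements(x@scheme))

#' @describeIn bValues b-values of the bound scheme
#' @export
setMethod("bValues", "DwiVolume", function(x) bValues(x@scheme))

#' @describeIn isB0 b0 indicator of the bound scheme
#' @export
setMethod("isB0", "DwiVolume", function(x) isB0(x@scheme))

setMethod("show", "DwiVolume", function(object) {
  d <- dim(object@signal)
  cat("DwiVolume", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "measurements\n")
  cat("  ", sum(object@mask), "voxels in mask;",
      if (object@normalized) "b0-normalised\n" else "raw signal\n")
})

#' Accessors for DwiVolume slots
#' @param x a [DwiVolume-class]
#' @return `dwiSignal`: the 4-D array; `dwiMask`: the 3-D logical mask;
#'   `dwiScheme`: the bound [AcquisitionScheme-class].
#' @export
dwiSignal <- function(x) x@signal

#' @rdname dwiSignal
#' @export
dwiMask <- function(x) x@mask

#' @rdname dwiSignal
#' @export
dwiScheme <- function(x) x@scheme

#' Normalise a DWI volume by its TE-matched b0 images
#'
#' Echo times are minimised per diffusion shell, so the T2 weighting of the
#' raw signal varies across shells. Dividing each diffusion-weighted
#' measurement voxelwise by the mean of the b~0 measurements acquired at the
#' same TE removes this variation. b0 measurements are dropped from the
#' output scheme; masked voxels with a non-positive b0 mean are excluded from
#' the output mask (flagged invalid).
#'
#' @param volume a raw [DwiVolume-class] whose scheme contains TE-matched b0s.
#' @return a normalised [DwiVolume-class] (signal dimensionless, b0s removed).
#' @export
normalizeToB0 <- function(volume) {
  if (volume@normalized) {
    b0 <- isB0(volume)
    if (!any(b0)) return(volume)
  }
  m <- volume@scheme@measurements
  b0 <- m$G == 0
  if (!any(b0)) stop("scheme error: no b0 measurements to normalise by", call. = FALSE)
  dw <- which(!b0)
  if (!all(m$TE[dw] %in% m$TE[b0]))
    stop("scheme error: diffusion-weighted TE without a matching b0", call. = FALSE)
  d <- dim(volume@signal)
  nvox <- prod(d[1:3])
  sig <- matrix(volume@signal, nrow = nvox)
  ## mean b0 per TE, voxelwise
  b0means <- vapply(unique(m$TE[b0]), function(te) {
    idx <- which(b0 & m$TE == te)
    if (length(idx) == 1L) sig[, idx] else rowMeans(sig[, idx, drop = FALSE])
  }, numeric(nvox))
  if (is.null(dim(b0means))) b0means <- matrix(b0means, nrow = nvox)
  colnames(b0means) <- as.character(unique(m$TE[b0]))
  teCol <- match(as.character(m$TE[dw]), colnames(b0means))
  out <- sig[, dw, drop = FALSE] / b0means[, teCol, drop = FALSE]
  invalid <- apply(b0means <= 0 | !is.finite(b0means), 1, any)
  out[invalid, ] <- NA_real_
  mask <- volume@mask & !array(invalid, dim = d[1:3])
  out[!is.finite(out)] <- NA_real_
  out[is.na(out)] <- 0
  newScheme <- new("AcquisitionScheme",
                   measurements = {
                     mm <- m[dw, , drop = FALSE]; rownames(mm) <- NULL; mm
                   },
                   gamma = volume@scheme@gamma)
  new("DwiVolume", signal = array(out, dim = c(d[1:3], length(dw))),
      scheme = newScheme, mask = mask, normalized = TRUE)
}

#' Estimate the Rician noise SD from repeated b0 measurements
#'
#' For each echo time with at least two b0 repeats, the voxelwise SD across
#' repeats divided by the voxelwise mean estimates the noise SD on the
#' normalised signal scale; the estimate is the median over masked voxels and
#' TE groups.
#'
#' @param volume a raw (un-normalised) [DwiVolume-class].
#' @return scalar noise SD relative to the b0 signal (1/SNR).
#' @export
estimateSigma <- function(volume) {
  m <- volume@scheme@measurements
  b0 <- m$G == 0
  d <- dim(volume@signal)
  sig <- matrix(volume@signal, nrow = prod(d[1:3]))
  mask <- as.vector(volume@mask)
  ests <- unlist(lapply(unique(m$TE[b0]), function(te) {
    idx <- which(b0 & m$TE == te)
    if (length(idx) < 2L) return(NULL)
    s <- sig[mask, idx, drop = FALSE]
    mu <- rowMeans(s)
    sd <- apply(s, 1, stats::sd)
    (sd / mu)[mu > 0]
  }))
  if (is.null(ests) || !length(ests))
    stop("sigma estimation needs >= 2 b0 repeats at one TE", call. = FALSE)
  stats::median(ests, na.rm = TRUE)
}
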