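#' Fit a model voxel-wise over an ROI
#'
#' Applies [fitVoxel()] to every masked voxel of a normalised
#' [DwiVolume-class] and assembles the results into [ParameterMaps-class].
#' A raw volume is first normalised via [normalizeToB0()]; if the
#' configuration requests `sigma = "estimate"`, the noise SD is estimated
#' from the b0 repeats of the raw volume before normalisation. The fit is
#' deterministic given the configuration seed.
#'
#' @param volume a [DwiVolume-class] (raw or normalised).
#' @param config a [FitConfig-class].
#' @return a [ParameterMaps-class]
#' @export
fitRoi <- function(volume, config) {
  if (!volume@normalized) {
    if (!is.numeric(config@sigma)) config@sigma <- estimateSigma(volume)
    volume <- normalizeToB0(volume)
  } else if (!is.numeric(config@sigma)) {
    stop("sigma = \"estimate\" needs a raw volume with b0 repeats", call. = FALSE)
  }
  mask <- volume@mask
  idx <- which(mask)
  if (!length(idx)) stop("empty mask", call. = FALSE)
  d <- dim(volume@signal)
  sig <- matrix(volume@signal, nrow = prod(d[1:3]))

  paramNames <- switch(config@model,
    verdict = c("fSphere", "fBall", "fStick", "R", "dStick", "theta", "phi"),
    adc = "ADC",
    kurtosis = c("Dk", "K"))
  empty <- array(NA_real_, dim = d[1:3])
  maps <- stats::setNames(rep(list(empty), length(paramNames)), paramNames)
  loglik <- empty; bic <- empty
  boundary <- array(FALSE, dim = d[1:3])

  baseSeed <- config@seed
  for (j in seq_along(idx)) {
    v <- idx[j]
    cfg <- config
    cfg@seed <- as.integer((baseSeed + j) %% .Machine$integer.max)
    fit <- fitVoxel(sig[v, ], volume@scheme, cfg)
    for (p in paramNames) maps[[p]][v] <- fit$params[[p]]
    loglik[v] <- fit$loglik
    bic[v] <- fit$bic
    boundary[v] <- fit$boundaryHit
  }
  new("ParameterMaps", maps = maps, loglik = loglik, bic = bic,
      boundaryHit = boundary, mask = mask, model = config@model,
      config = config,
      provenance = list(seed = baseSeed, nVoxels = length(idx),
                        schemeHash = rlang::hash(volume@scheme@measurements),
                        sigma = config@sigma))
}

#' @describeIn parameterMap extract one parameter's 3-D map
#' @export
setMethod("parameterMap", "ParameterMaps", function(x, name) {
  if (!name %in% names(x@maps))
    stop("unknown parameter: ", name, "; available: ",
         paste(names(x@maps), collapse = ", "), call. = FALSE)
  x@maps[[name]]
})

setMethod("show", "ParameterMaps", function(object) {
  cat("ParameterMaps (", object@model, "): ",
      paste(names(object@maps), collapse = ", "), "\n", sep = "")
  cat("  ", sum(object@mask), "fitted voxels; mean BIC =",
      format(mean(object@bic[object@mask], na.rm = TRUE), digits = 5), "\n")
  if (object@model == "verdict")
    cat("  boundary-hit fraction:",
        format(mean(object@boundaryHit[object@mask]), digits = 3), "\n")
})

#' BIC of a voxel fit
#'
#' Bayesian information criterion \eqn{BIC = \ln(n) k - 2 \ln(L)} with `n`
#' the number of fitted data points, `k` the number of fitted parameters and
#' `L` the maximised likelihood. Lower is better.
#'
#' @param fit a `VoxelFit` from [fitVoxel()].
#' @return scalar BIC.
#' @export
computeBIC <- function(fit) {
  log(fit$nMeas) * fit$k - 2 * fit$loglik
}

#' Compare candidate models voxel-wise by BIC
#'
#' Fits every configuration to the same masked voxels and selects, per voxel,
#' the model with the lowest BIC; also reports the ROI-mean BIC per model.
#'
#' @param volume a [DwiVolume-class].
#' @param configs named list of [FitConfig-class] objects (names default to
#'   each config's model).
#' @return list with `fits` (named list of [ParameterMaps-class]), `meanBIC`
#'   (named numeric), `bestModel` (3-D character array, `NA` outside mask),
#'   and `bestCounts` (table of per-voxel winners).
#' @export
compareModels <- function(volume, configs) {
  if (is.null(names(configs)) || any(!nzchar(names(configs))))
    names(configs) <- vapply(configs, function(c) c@model, character(1))
  fits <- lapply(configs, function(cfg) fitRoi(volume, cfg))
  n <- vapply(fits, function(f) f@provenance$nVoxels, numeric(1))
  if (length(unique(n)) != 1L)
    stop("models were fitted on different voxel sets", call. = FALSE)
  mask <- fits[[1]]@mask
  bicMat <- vapply(fits, function(f) f@bic[mask], numeric(sum(mask)))
  if (is.null(dim(bicMat))) bicMat <- matrix(bicMat, nrow = 1)
  winners <- names(configs)[apply(bicMat, 1, which.min)]
  best <- array(NA_character_, dim = dim(mask))
  best[mask] <- winners
  list(fits = fits,
       meanBIC = colMeans(bicMat),
       bestModel = best,
       bestCounts = table(factor(winners, levels = names(configs))))
}

#' Summarise parameter maps over the ROI
#'
#' Mean and SD of every parameter over valid masked voxels, the convention
#' used to report per-subject tumour values.
#'
#' @param maps a [ParameterMaps-class].
#' @return data.frame with columns `parameter`, `mean`, `sd`, `n`.
#' @export
summarizeRoi <- function(maps) {
  vals <- lapply(maps@maps, function(m) m[maps@mask & !is.na(m)])
  if (all(vapply(vals, length, integer(1)) == 0L))
    stop("no valid voxels to summarise", call. = FALSE)
  data.frame(
    parameter = names(vals),
    mean = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, function(v) if (length(v) > 1) stats::sd(v) else 0, numeric(1)),
    n = vapply(vals, length, integer(1)),
    row.names = NULL
  )
}
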