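## Voxel-wise constrained maximum-likelihood fitting under Rician noise.
##
## Constraints are handled by fitting in a transformed, unconstrained space:
##   fSphere = cos^2(u1), fBall = sin^2(u1) cos^2(u2)  (squared-cosine pairing,
##     so the three fractions are in [0,1] and sum to one by construction;
##     fStick follows by closure)
##   R and dStick map onto their bounds through scaled logistic functions
##   theta, phi are unconstrained angles
## Each voxel is fitted from a coarse grid of starts plus perturbed restarts
## of the best start, with a Nelder-Mead local optimiser.

logistic <- function(u) 1 / (1 + exp(-u))
logit <- function(p) log(p / (1 - p))

boundTo <- function(u, lo, hi) lo + (hi - lo) * logistic(u)
boundFrom <- function(x, lo, hi) {
  p <- pmin(pmax((x - lo) / (hi - lo), 1e-6), 1 - 1e-6)
  logit(p)
}

## fitting context: everything precomputable per (scheme, config)
fitContext <- function(scheme, config) {
  m <- scheme@measurements
  dw <- m$G > 0
  m <- m[dw, , drop = FALSE]
  key <- paste(m$delta, m$Delta)
  uk <- which(!duplicated(key))
  ctx <- list(
    b = m$b,
    bsi = smm2ToSm2(m$b),
    g = as.matrix(m[, c("gx", "gy", "gz")]),
    G2 = m$G^2,
    gamma = scheme@gamma,
    deltaU = m$delta[uk], DeltaU = m$Delta[uk],
    pairIdx = match(key, key[uk]),
    roots2 = sphereGPDRoots(40L)^2,
    Sball = exp(-smm2ToSm2(m$b) * config@dBall),
    config = config,
    nMeas = nrow(m)
  )
  ctx
}

## sphere signal per measurement for radius R (um), using precomputed context
ctxSphereSignal <- function(ctx, R) {
  Rm <- umToM(R)
  d <- ctx$config@dSphere
  a2 <- ctx$roots2 / Rm^2
  da2 <- d * a2
  den <- d^2 * a2^3 * (a2 * Rm^2 - 2)
  Fu <- vapply(seq_along(ctx$deltaU), function(i) {
    de <- ctx$deltaU[i]; De <- ctx$DeltaU[i]
    num <- 2 * da2 * de - 2 + 2 * exp(-da2 * de) + 2 * exp(-da2 * De) -
      exp(-da2 * (De - de)) - exp(-da2 * (De + de))
    sum(num / den)
  }, numeric(1))
  exp(-2 * ctx$gamma^2 * ctx$G2 * Fu[ctx$pairIdx])
}

ctxStickSignal <- function(ctx, dStick, theta, phi) {
  n <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  exp(-ctx$bsi * dStick * as.vector(ctx$g %*% n)^2)
}

## transform u -> named parameter list, per model/mode
uToParams <- function(u, ctx) {
  cfg <- ctx$config
  switch(cfg@model,
    verdict = {
      s1 <- cos(u[1])^2; s2 <- cos(u[2])^2
      fSphere <- s1; fBall <- (1 - s1) * s2
      R <- boundTo(u[3], cfg@rBounds[1], cfg@rBounds[2])
      if (cfg@mode == "mouse") {
        dStick <- boundTo(u[4], cfg@dStickBounds[1], cfg@dStickBounds[2])
        theta <- u[5]; phi <- u[6]
      } else {
        dStick <- cfg@dStick; theta <- u[4]; phi <- u[5]
      }
      list(fSphere = fSphere, fBall = fBall, fStick = 1 - (fSphere + fBall),
           R = R, dStick = dStick, theta = theta, phi = phi)
    },
    adc = list(ADC = boundTo(u[1], 0, 1e-8)),
    kurtosis = list(Dk = boundTo(u[1], 0, 1e-8), K = boundTo(u[2], 0, 10)))
}

ctxPredict <- function(u, ctx) {
  cfg <- ctx$config
  p <- uToParams(u, ctx)
  switch(cfg@model,
    verdict = p$fBall * ctx$Sball +
      p$fSphere * ctxSphereSignal(ctx, p$R) +
      p$fStick * ctxStickSignal(ctx, p$dStick, p$theta, p$phi),
    adc = exp(-ctx$bsi * p$ADC),
    kurtosis = exp(-ctx$bsi * p$Dk + ctx$bsi^2 * p$Dk^2 * p$K / 6))
}

## negative Rician log-likelihood in transformed space
ctxObjective <- function(u, ctx, observed, sigma) {
  nu <- ctxPredict(u, ctx)
  z <- observed * nu / sigma^2
  -sum(log(observed / sigma^2) - (observed^2 + nu^2) / (2 * sigma^2) +
         logBesselI0(z))
}

## start points in transformed space
startGrid <- function(ctx) {
  cfg <- ctx$config
  n <- cfg@nStartsGrid
  q <- seq_len(n) / (n + 1)
  switch(cfg@model,
    verdict = {
      fs <- q                               # fSphere starts
      Rs <- cfg@rBounds[1] + q * diff(cfg@rBounds)
      u1 <- acos(sqrt(fs))
      u2 <- acos(sqrt(0.9))                 # fBall ~ 90% of remainder
      uR <- boundFrom(Rs, cfg@rBounds[1], cfg@rBounds[2])
      if (cfg@mode == "mouse") {
        ds <- cfg@dStickBounds[1] + q * diff(cfg@dStickBounds)
        uD <- boundFrom(ds, cfg@dStickBounds[1], cfg@dStickBounds[2])
        grid <- expand.grid(u1 = u1, uR = uR, uD = uD)
        lapply(seq_len(nrow(grid)), function(i)
          c(grid$u1[i], u2, grid$uR[i], grid$uD[i], 1.0, 0.8))
      } else {
        th <- pi * q
        grid <- expand.grid(u1 = u1, uR = uR, th = th)
        lapply(seq_len(nrow(grid)), function(i)
          c(grid$u1[i], u2, grid$uR[i], grid$th[i], 0.8))
      }
    },
    adc = lapply(c(0.3e-9, 1e-9, 2.5e-9), function(a) boundFrom(a, 0, 1e-8)),
    kurtosis = {
      grid <- expand.grid(D = c(0.5e-9, 1e-9, 2e-9), K = c(0.2, 1))
      lapply(seq_len(nrow(grid)), function(i)
        c(boundFrom(grid$D[i], 0, 1e-8), boundFrom(grid$K[i], 0, 10)))
    })
}

#' Fit a diffusion model to one voxel's normalised signal
#'
#' Maximises the Rician log-likelihood of the configured model over bounded
#' parameters using multi-start Nelder-Mead optimisation in a transformed,
#' unconstrained space. The stick fraction is never fitted: it is computed by
#' closure as `1 - (fSphere + fBall)`.
#'
#' @param signal normalised diffusion-weighted signal vector (b0s removed),
#'   matching the diffusion-weighted measurements of `scheme`.
#' @param scheme an [AcquisitionScheme-class]; b0 measurements, if present,
#'   are ignored (the signal must then match the DW subset).
#' @param config a [FitConfig-class].
#' @return an object of class `VoxelFit`: list with `params` (named list),
#'   `loglik`, `bic`, `k`, `nMeas`, `converged`, `nRestartsAgreeing`,
#'   `boundaryHit` (radius at the upper bound, VERDICT only).
#' @examples
#' sch <- buildMouseProtocol()
#' truth <- list(fBall = 0.39, fSphere = 0.54, fStick = 0.07, dBall = 2e-9,
#'               dSphere = 1e-9, R = 10.6, dStick = 10.8e-9,
#'               theta = 1, phi = 0.5)
#' s <- verdictSignal(sch, truth)[!isB0(sch)]
#' \donttest{
#' fit <- fitVoxel(s, sch, fitConfig("verdict", "mouse", sigma = 1e-4))
#' fit$params$R
#' }
#' @export
fitVoxel <- function(signal, scheme, config) {
  ctx <- fitContext(scheme, config)
  if (length(signal) != ctx$nMeas)
    stop("signal length does not match the scheme's DW measurements", call. = FALSE)
  k <- nFittedParams(config)
  if (ctx$nMeas < k) stop("fewer measurements than parameters", call. = FALSE)
  if (!all(is.finite(signal)) || any(signal < 0))
    stop("signal must be finite and non-negative", call. = FALSE)
  sigma <- config@sigma
  if (!is.numeric(sigma))
    stop("fitVoxel needs a numeric sigma (estimate it from a raw volume first)",
         call. = FALSE)
  observed <- pmax(signal, 1e-12)   # Rician density support is m > 0

  starts <- startGrid(ctx)
  ## rank grid starts by their objective value and descend only from the
  ## most promising ones (bad corners of the grid almost never win)
  if (length(starts) > 9L && length(starts[[1]]) > 1L) {
    v0 <- vapply(starts, ctxObjective, numeric(1), ctx = ctx,
                 observed = observed, sigma = sigma)
    keep <- order(v0)[seq_len(max(9L, ceiling(length(starts) / 3)))]
    starts <- starts[keep]
  }
  runs <- lapply(starts, function(u0) {
    if (length(u0) == 1L) {
      opt <- stats::optim(u0, ctxObjective, ctx = ctx, observed = observed,
                          sigma = sigma, method = "Brent",
                          lower = -30, upper = 30)
    } else {
      ## coarse pass: the polish stage below supplies the final precision
      opt <- stats::optim(u0, ctxObjective, ctx = ctx, observed = observed,
                          sigma = sigma, method = "Nelder-Mead",
                          control = list(maxit = 300, reltol = 1e-7))
    }
    opt
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]

  ## perturbed restarts of the best start's optimum
  if (config@nRestarts > 0L && length(best$par) > 1L) {
    set.seed(config@seed)
    for (r in seq_len(config@nRestarts)) {
      u0 <- best$par + stats::rnorm(length(best$par), 0, config@perturbSd)
      opt <- stats::optim(u0, ctxObjective, ctx = ctx, observed = observed,
                          sigma = sigma, method = "Nelder-Mead",
                          control = list(maxit = 300, reltol = 1e-8))
      vals <- c(vals, opt$value)
      if (opt$value < best$value) best <- opt
    }
  }
  ## polish (Nelder-Mead restarts at the optimum tighten the simplex)
  converged <- is.null(best$convergence) || best$convergence == 0
  if (length(best$par) > 1L) {
    for (i in 1:3) {
      polish <- stats::optim(best$par, ctxObjective, ctx = ctx,
                             observed = observed, sigma = sigma,
                             method = "Nelder-Mead",
                             control = list(maxit = 1000, reltol = 1e-12))
      improved <- polish$value < best$value - 1e-9
      if (polish$value < best$value) best <- polish
      if (polish$convergence == 0) { converged <- TRUE; if (!improved) break }
    }
  }

  params <- uToParams(best$par, ctx)
  ## snap onto the zero-diffusivity boundary when it is statistically
  ## indistinguishable from the optimum (the Rician noise floor otherwise
  ## leaves a physically meaningless ~1e-13 m^2/s residual decay)
  if (config@model == "adc") {
    f0 <- ctxObjective(boundFrom(0, 0, 1e-8), ctx, observed, sigma)
    if (f0 <= best$value + 0.01) { params$ADC <- 0; best$value <- min(f0, best$value) }
  }
  params <- normalizeAngles(params)
  loglik <- -best$value
  agree <- sum(vals <= min(vals) + 1e-3)
  boundaryHit <- FALSE
  if (config@model == "verdict")
    boundaryHit <- params$R >= config@rBounds[2] - 0.1
  structure(list(
    params = params, loglik = loglik,
    bic = log(ctx$nMeas) * k - 2 * loglik,
    k = k, nMeas = ctx$nMeas,
    converged = converged,
    nRestartsAgreeing = agree, boundaryHit = boundaryHit
  ), class = "VoxelFit")
}

## fold stick orientation into theta in [0, pi/2]..[0,pi], phi in [0, 2pi)
## (the stick is antipodally symmetric)
normalizeAngles <- function(params) {
  if (is.null(params$theta)) return(params)
  n <- c(sin(params$theta) * cos(params$phi),
         sin(params$theta) * sin(params$phi),
         cos(params$theta))
  if (n[3] < 0) n <- -n
  params$theta <- acos(pmin(pmax(n[3], -1), 1))
  params$phi <- atan2(n[2], n[1]) %% (2 * pi)
  params
}

#' @export
print.VoxelFit <- function(x, ...) {
  cat("VoxelFit:", x$nMeas, "measurements, k =", x$k, "\n")
  cat("  logLik =", format(x$loglik, digits = 6),
      " BIC =", format(x$bic, digits = 6), "\n")
  p <- unlist(x$params)
  cat("  ", paste(names(p), signif(p, 4), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
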