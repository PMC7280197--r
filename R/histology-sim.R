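#' Generate a synthetic H&E-like histology image with known stained fraction
#'
#' Draws non-overlapping dark discs (stained cells) on a bright background
#' and adds Gaussian texture noise. Disc radii are sampled from a lognormal
#' distribution; when the packing becomes tight, candidate radii are
#' progressively shrunk so that area fractions up to ~0.6 remain reachable.
#' The realised stained fraction (painted pixels / total pixels) is returned
#' as ground truth and is within 0.02 of the target.
#'
#' @param targetFraction desired stained area fraction, in (0, 0.9); values
#'   above ~0.6 may be unreachable for non-overlapping discs and then error.
#' @param shape image shape in pixels (rows, cols).
#' @param meanRadius mean disc radius in pixels.
#' @param radiusSd SD of the (lognormal) disc-radius distribution, pixels.
#' @param background,foreground background (unstained) and disc (stained)
#'   intensity levels.
#' @param noiseSd texture noise SD as a fraction of the intensity contrast.
#' @param seed integer seed.
#' @return list with `image` (2-D matrix), `trueFraction` (realised stained
#'   area fraction), `mask` (logical matrix of stained pixels) and `nDiscs`.
#' @examples
#' h <- generateHistologyImage(0.4, shape = c(96, 96), seed = 2)
#' h$trueFraction
#' @export
generateHistologyImage <- function(targetFraction, shape = c(256, 256),
                                   meanRadius = 6, radiusSd = 1.5,
                                   background = 220, foreground = 60,
                                   noiseSd = 0.05, seed = 1L) {
  if (targetFraction <= 0 || targetFraction >= 0.9)
    stop("targetFraction must lie in (0, 0.9)", call. = FALSE)
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  painted <- matrix(FALSE, nr, nc)
  centres <- matrix(numeric(0), ncol = 3)  # x, y, r
  total <- nr * nc
  frac <- 0
  minR <- 1.5
  curMean <- meanRadius
  fails <- 0L
  lmu <- function(m) log(m) - 0.5 * log(1 + (radiusSd / m)^2)
  lsd <- function(m) sqrt(log(1 + (radiusSd / m)^2))
  nDiscs <- 0L
  while (frac < targetFraction - 0.005) {
    r <- stats::rlnorm(1, lmu(curMean), lsd(curMean))
    r <- max(min(r, curMean * 2), minR)
    x <- stats::runif(1, r + 1, nc - r)
    y <- stats::runif(1, r + 1, nr - r)
    ok <- TRUE
    if (nrow(centres)) {
      d2 <- (centres[, 1] - x)^2 + (centres[, 2] - y)^2
      ok <- all(d2 > (centres[, 3] + r)^2)
    }
    if (!ok) {
      fails <- fails + 1L
      ## tight packing: shrink candidate discs so smaller ones fill the gaps
      if (fails %% 150L == 0L) curMean <- max(curMean * 0.85, minR)
      if (fails > 4000L && curMean <= minR)
        stop("unreachable packing fraction: ", targetFraction, call. = FALSE)
      next
    }
    fails <- 0L
    centres <- rbind(centres, c(x, y, r))
    nDiscs <- nDiscs + 1L
    xi <- pmax(1, floor(x - r)):pmin(nc, ceiling(x + r))
    yi <- pmax(1, floor(y - r)):pmin(nr, ceiling(y + r))
    sub <- outer(yi, xi, function(i, j) (j - x)^2 + (i - y)^2 <= r^2)
    painted[yi, xi] <- painted[yi, xi] | sub
    frac <- sum(painted) / total
  }
  img <- matrix(background, nr, nc)
  img[painted] <- foreground
  contrast <- abs(background - foreground)
  img <- img + matrix(stats::rnorm(total, 0, noiseSd * contrast), nr, nc)
  list(image = img, trueFraction = frac, mask = painted, nDiscs = nDiscs)
}
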