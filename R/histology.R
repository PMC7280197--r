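#' Estimate the stained-tissue fraction of a histology image
#'
#' Two-cluster k-means on the 1-D pixel-intensity distribution separates
#' stained (dark) from unstained (bright) tissue; the stained fraction is the
#' proportion of pixels assigned to the darker cluster. The split is
#' equivalent to thresholding at the midpoint of the two final cluster
#' centroids, making the estimate invariant to affine intensity rescaling.
#' Colour arrays (3-D with a channel dimension) are reduced to luminance
#' before clustering.
#'
#' @param image 2-D intensity matrix, or 3-D array with RGB channels last.
#' @param mask optional logical matrix restricting the analysed region.
#' @param invert set `TRUE` when stained tissue is brighter than background;
#'   the brighter cluster is then counted as stained.
#' @param nstart random restarts of the k-means clustering.
#' @param seed integer seed (k-means initialisation).
#' @return list with `fraction` (stained fraction in \[0, 1\]), `threshold`
#'   (centroid midpoint) and `centers` (sorted cluster means).
#' @examples
#' img <- rbind(matrix(50, 40, 100), matrix(200, 60, 100))
#' estimateStainedFraction(img)$fraction  # 0.4
#' @export
estimateStainedFraction <- function(image, mask = NULL, invert = FALSE,
                                    nstart = 10L, seed = 1L) {
  if (length(dim(image)) == 3L) {
    w <- c(0.299, 0.587, 0.114)[seq_len(dim(image)[3])]
    image <- apply(sweep(image, 3, w / sum(w), `*`), c(1, 2), sum)
  }
  if (is.null(mask)) mask <- !is.na(image) & is.finite(image)
  if (!identical(dim(mask), dim(image)))
    stop("mask shape must match the image", call. = FALSE)
  x <- image[mask]
  if (length(unique(x)) < 2L)
    stop("degenerate clusters: image has fewer than 2 distinct intensities",
         call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(x, centers = 2L, nstart = nstart, iter.max = 50L)
  centers <- sort(as.vector(km$centers))
  stainedCluster <- if (invert) which.max(km$centers) else which.min(km$centers)
  fraction <- mean(km$cluster == stainedCluster)
  list(fraction = fraction, threshold = mean(centers), centers = centers)
}

#' Compare histology-derived fractions with the VERDICT sphere fraction
#'
#' Matches per-subject stained-tissue fractions from histology against ROI
#' mean `fSphere` estimates, summarises both per arm, reports the
#' histology-to-MRI ratio, and tests the arm difference in the histology
#' fraction with a two-sample t-test.
#'
#' @param histology data.frame with columns `subject`, `arm`, `fraction`.
#' @param fsphere data.frame with columns `subject`, `fSphere`.
#' @param varEqual use the equal-variance t-test (default) or Welch.
#' @return list with `byArm` (per-arm means of both measures and their
#'   ratio), `ratio` (overall mean histology fraction / mean fSphere), and
#'   `armTest` (htest for the arm difference in histology fraction, `NULL`
#'   if fewer than two arms).
#' @export
compareFractionToFsphere <- function(histology, fsphere, varEqual = TRUE) {
  merged <- merge(histology, fsphere, by = "subject")
  if (!nrow(merged)) stop("no matched subjects", call. = FALSE)
  byArm <- do.call(rbind, lapply(split(merged, merged$arm), function(d) {
    data.frame(arm = d$arm[1], n = nrow(d),
               histologyFraction = mean(d$fraction),
               fSphere = mean(d$fSphere),
               ratio = mean(d$fraction) / mean(d$fSphere))
  }))
  rownames(byArm) <- NULL
  armTest <- NULL
  if (length(unique(merged$arm)) == 2L &&
      all(table(merged$arm) >= 2L)) {
    armTest <- stats::t.test(fraction ~ arm, data = merged, var.equal = varEqual)
  }
  list(byArm = byArm,
       ratio = mean(merged$fraction) / mean(merged$fSphere),
       armTest = armTest)
}
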