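#' Read and write DWI volumes and masks as NIfTI-1
#'
#' Thin wrappers around RNifti. `readDwiVolume` binds a 4-D NIfTI image to a
#' scheme file (measurement count must match the 4th dimension) and an
#' optional mask volume; `writeDwiVolume` writes the signal array (and the
#' scheme alongside when `schemePath` is given).
#'
#' @param imagePath path to a 4-D NIfTI (.nii/.nii.gz).
#' @param scheme an [AcquisitionScheme-class] or path to a scheme file.
#' @param maskPath optional path to a 3-D NIfTI mask (non-zero = inside).
#' @param normalized whether the image is already b0-normalised.
#' @return `readDwiVolume`: a [DwiVolume-class].
#' @export
readDwiVolume <- function(imagePath, scheme, maskPath = NULL,
                          normalized = FALSE) {
  if (is.character(scheme)) scheme <- readScheme(scheme)
  img <- RNifti::readNifti(imagePath)
  arr <- array(as.numeric(img), dim = dim(img))
  mask <- NULL
  if (!is.null(maskPath)) {
    m <- RNifti::readNifti(maskPath)
    mask <- array(as.numeric(m) != 0, dim = dim(m))
  }
  dwiVolume(arr, scheme, mask = mask, normalized = normalized)
}

#' @rdname readDwiVolume
#' @param volume a [DwiVolume-class].
#' @param path output NIfTI path.
#' @param schemePath optional path for the accompanying scheme file.
#' @export
writeDwiVolume <- function(volume, path, schemePath = NULL) {
  RNifti::writeNifti(volume@signal, path)
  if (!is.null(schemePath)) writeScheme(volume@scheme, schemePath)
  invisible(path)
}

#' Write parameter maps as one NIfTI per parameter plus a JSON report
#'
#' @param maps a [ParameterMaps-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeParameterMaps <- function(maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (p in names(maps@maps)) {
    f <- file.path(dir, paste0(p, ".nii.gz"))
    RNifti::writeNifti(maps@maps[[p]], f)
    paths <- c(paths, f)
  }
  for (nm in c("bic", "loglik")) {
    f <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(slot(maps, nm), f)
    paths <- c(paths, f)
  }
  summ <- summarizeRoi(maps)
  report <- list(
    model = maps@model,
    summary = summ,
    meanBIC = mean(maps@bic[maps@mask], na.rm = TRUE),
    boundaryHitFraction = mean(maps@boundaryHit[maps@mask]),
    provenance = maps@provenance
  )
  rf <- file.path(dir, "fit_report.json")
  jsonlite::write_json(report, rf, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(paths, rf))
}
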